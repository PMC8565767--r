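# Poisson-disk thinning of candidate training pixels, to limit spatial
# autocorrelation between training samples.

#' Poisson-disk sampling over a finite candidate lattice
#'
#' Dart-throwing over the candidate pixels: iterate the candidates in a
#' seeded random order and accept a pixel iff no previously accepted pixel
#' lies strictly within `min_distance_km` of it (distances between cell
#' centers). The result is maximal under the insertion order and
#' deterministic given the seed. `min_distance_km = 0` accepts every
#' candidate. A uniform bucket grid keeps neighbor checks O(1).
#'
#' @param candidate_pixels data.frame with columns `pixel_id`, `row`, `col`.
#' @param min_distance_km minimum pairwise distance between selected pixel
#'   centers (km, >= 0; default 5).
#' @param cell_km cell size in km.
#' @param seed integer seed for the insertion order.
#' @return Object of class `sample_set`: list with `pixels` (the selected
#'   rows), `min_distance_km`, `cell_km`, `seed`.
#' @export
poisson_disk_sample <- function(candidate_pixels, min_distance_km = 5,
                                cell_km = 1, seed = 1) {
  stopifnot(is.data.frame(candidate_pixels),
            all(c("pixel_id", "row", "col") %in% names(candidate_pixels)))
  if (nrow(candidate_pixels) == 0) stop_params("no candidate pixels")
  if (min_distance_km < 0) stop_params("min_distance_km must be >= 0")
  n <- nrow(candidate_pixels)
  ord <- with_seed(seed, sample.int(n))
  if (min_distance_km == 0) {
    sel <- candidate_pixels[ord, , drop = FALSE]
    rownames(sel) <- NULL
    return(structure(list(pixels = sel, min_distance_km = min_distance_km,
                          cell_km = cell_km, seed = seed),
                     class = "sample_set"))
  }
  x <- candidate_pixels$col[ord] * cell_km
  y <- candidate_pixels$row[ord] * cell_km
  d <- min_distance_km
  bx <- as.integer(floor(x / d))
  by <- as.integer(floor(y / d))
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  accepted <- logical(n)
  d2 <- d * d
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste0(bx[i] + dx, "_", by[i] + dy)
        js <- buckets[[key]]
        if (!is.null(js)) {
          if (any((x[js] - x[i])^2 + (y[js] - y[i])^2 < d2)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) break
    }
    if (ok) {
      accepted[i] <- TRUE
      key <- paste0(bx[i], "_", by[i])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  sel <- candidate_pixels[ord[accepted], , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(pixels = sel, min_distance_km = min_distance_km,
                 cell_km = cell_km, seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d pixels, min distance %g km (seed %d)\n",
              nrow(x$pixels), x$min_distance_km, x$seed))
  invisible(x)
}
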