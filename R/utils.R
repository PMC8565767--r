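# Internal helpers shared across modules.

#' The nine model covariates
#'
#' Character vector naming the covariates used to estimate annual fire
#' probability: long-term climate normals of actual evapotranspiration (AET)
#' and climatic water deficit (CWD), their mean three-year deviations, mean
#' housing density within a 25-km radius, the cultivated fraction of each
#' pixel, distances to roads and to electrical infrastructure, and the number
#' of years since the most recent fire.
#'
#' @export
fire_covariates <- c(
  "aet_normal", "cwd_normal", "aet_dev3", "cwd_dev3",
  "housing_density_25km", "cultivated_fraction",
  "dist_roads", "dist_electrical", "years_since_fire"
)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483587)
}

#' Pixel id / (row, col) conversions
#'
#' Pixels are indexed 1-based and row-major: `pixel_id = (row - 1) * n_cols + col`.
#'
#' @param row,col 1-based grid indices.
#' @param pixel_id row-major pixel id.
#' @param n_cols number of grid columns.
#' @return `pixel_id()` returns integer ids; `pixel_rc()` returns a data.frame
#'   with columns `row` and `col`.
#' @export
pixel_id <- function(row, col, n_cols) {
  (as.integer(row) - 1L) * as.integer(n_cols) + as.integer(col)
}

#' @rdname pixel_id
#' @export
pixel_rc <- function(pixel_id, n_cols) {
  pixel_id <- as.integer(pixel_id)
  n_cols <- as.integer(n_cols)
  data.frame(
    row = (pixel_id - 1L) %/% n_cols + 1L,
    col = (pixel_id - 1L) %% n_cols + 1L
  )
}

# Grid definition: list(n_rows, n_cols, cell_km).
grid_def <- function(n_rows, n_cols, cell_km = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_km > 0)
  list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
       cell_km = as.numeric(cell_km))
}

# Separable Gaussian smoothing of a matrix, edge-renormalized so borders are
# unbiased.  sigma in cell units.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    n <- length(v)
    full <- stats::convolve(v, rev(kern), type = "open")
    full[(half + 1):(half + n)]
  }
  ones_r <- smooth_vec(rep(1, nrow(mat)))
  ones_c <- smooth_vec(rep(1, ncol(mat)))
  out <- apply(mat, 2, smooth_vec)
  out <- out / ones_r
  out <- t(apply(out, 1, smooth_vec))
  out <- sweep(out, 2, ones_c, "/")
  out
}

# 2-D "same"-size convolution via FFT with zero padding.  Kernel dimensions
# must be odd.
conv2_same <- function(a, k) {
  stopifnot(nrow(k) %% 2 == 1, ncol(k) %% 2 == 1)
  nr <- nrow(a) + nrow(k) - 1L
  nc <- ncol(a) + ncol(k) - 1L
  A <- matrix(0, nr, nc); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  K <- matrix(0, nr, nc); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  R <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  ro <- (nrow(k) - 1L) / 2L
  co <- (ncol(k) - 1L) / 2L
  R[(1L + ro):(ro + nrow(a)), (1L + co):(co + ncol(a)), drop = FALSE]
}

stop_params <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
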