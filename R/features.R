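# Covariate engineering: turn raw gridded layers and the fire history into
# the nine per-pixel-year model covariates, apply the masking rules, and
# assemble the modelling table.

#' Long-term climate normal
#'
#' Per-pixel arithmetic mean of an annual layer series over a base period.
#'
#' @param annual_series 3-D array (rows x cols x years) with year dimnames.
#' @param base_period length-2 integer vector `c(first, last)` of years; must
#'   be fully contained in the series.
#' @return Numeric matrix.
#' @export
compute_normal <- function(annual_series, base_period) {
  yrs <- as.integer(dimnames(annual_series)[[3]])
  if (length(base_period) != 2 || base_period[1] > base_period[2]) {
    stop_params("base_period must be c(first, last) with first <= last")
  }
  want <- base_period[1]:base_period[2]
  if (!all(want %in% yrs)) {
    stop_params("base period years missing from series: %s",
                paste(setdiff(want, yrs), collapse = ", "))
  }
  sl <- annual_series[, , as.character(want), drop = FALSE]
  out <- apply(sl, c(1, 2), mean)
  dimnames(out) <- NULL
  out
}

#' Mean three-year deviation from normal
#'
#' Per-pixel mean of (annual value - normal) over the three years strictly
#' preceding the year of interest (`y - 3`, `y - 2`, `y - 1`); the year of
#' interest itself is excluded.
#'
#' @param annual_series 3-D array with year dimnames.
#' @param normal_raster matrix of per-pixel normals.
#' @param year year of interest; its three preceding years must be present.
#' @return Numeric matrix.
#' @export
compute_three_year_deviation <- function(annual_series, normal_raster, year) {
  yrs <- as.integer(dimnames(annual_series)[[3]])
  prev <- (year - 3):(year - 1)
  if (!all(prev %in% yrs)) {
    stop_params("cannot compute 3-year deviation for %d: missing years %s",
                year, paste(setdiff(prev, yrs), collapse = ", "))
  }
  sl <- annual_series[, , as.character(prev), drop = FALSE]
  out <- apply(sl, c(1, 2), mean) - normal_raster
  dimnames(out) <- NULL
  out
}

#' Years since the most recent fire
#'
#' Number of years between `year` and the latest recorded burn strictly
#' before `year`, capped at `cap`. Pixels with no recorded prior burn get the
#' cap (they are treated as having gone at most `cap` years without fire);
#' burns in the query year itself do not count.
#'
#' @param history a `fire_history`.
#' @param pixel pixel id (scalar or vector).
#' @param year query year (scalar).
#' @param cap maximum value (default 100).
#' @return Integer vector, same length as `pixel`, values in `[1, cap]`.
#' @export
years_since_fire <- function(history, pixel, year, cap = 100) {
  b <- history$burns
  out <- rep(as.integer(cap), length(pixel))
  for (i in seq_along(pixel)) {
    prior <- b$year[b$pixel_id == pixel[i] & b$year < year]
    if (length(prior)) out[i] <- min(as.integer(year - max(prior)), as.integer(cap))
  }
  out
}

# Years-since-fire matrices for an ordered run of years, computed
# incrementally (used by build_design_table; same rule as years_since_fire).
ysf_series <- function(history, years, cap = 100) {
  g <- history$grid
  nr <- g$n_rows; nc <- g$n_cols
  years <- sort(as.integer(years))
  b <- history$burns
  last_burn <- matrix(-Inf, nr, nc)
  pre <- b[b$year < years[1], , drop = FALSE]
  if (nrow(pre)) {
    agg <- tapply(pre$year, pre$pixel_id, max)
    rc <- pixel_rc(as.integer(names(agg)), nc)
    last_burn[cbind(rc$row, rc$col)] <- as.numeric(agg)
  }
  out <- vector("list", length(years))
  names(out) <- as.character(years)
  prev_y <- years[1] - 1L
  for (y in years) {
    # fold in burns between the previous processed year and y (exclusive of y)
    mid <- b[b$year >= prev_y & b$year < y, , drop = FALSE]
    if (nrow(mid)) {
      agg <- tapply(mid$year, mid$pixel_id, max)
      rc <- pixel_rc(as.integer(names(agg)), nc)
      idx <- cbind(rc$row, rc$col)
      last_burn[idx] <- pmax(last_burn[idx], as.numeric(agg))
    }
    out[[as.character(y)]] <- matrix(pmin(y - last_burn, cap), nr, nc)
    prev_y <- y
  }
  out
}

#' Focal mean within a radius
#'
#' Per-pixel mean of a raster over all valid cells whose center lies within
#' `radius_km` of the focal cell's center. At grid edges the mean is taken
#' over the in-grid portion of the disk (renormalized), and masked cells are
#' excluded from both numerator and denominator; a fully masked neighborhood
#' yields `NA`.
#'
#' @param density_raster numeric matrix (NA = missing).
#' @param radius_km disk radius in km (>= cell size).
#' @param cell_km cell size in km.
#' @param mask optional logical matrix of valid cells.
#' @return Numeric matrix.
#' @export
focal_mean_density <- function(density_raster, radius_km = 25, cell_km = 1,
                               mask = NULL) {
  if (radius_km < cell_km) {
    stop_params("radius_km (%g) must be at least the cell size (%g)",
                radius_km, cell_km)
  }
  valid <- !is.na(density_raster)
  if (!is.null(mask)) valid <- valid & mask
  half <- floor(radius_km / cell_km)
  off <- seq(-half, half)
  kern <- outer(off, off, function(i, j) (cell_km * sqrt(i^2 + j^2)) <= radius_km) * 1
  vals <- density_raster
  vals[!valid] <- 0
  num <- conv2_same(vals, kern)
  den <- conv2_same(valid * 1, kern)
  out <- ifelse(den > 0.5, num / pmax(den, 0.5), NA_real_)
  out
}

#' Linear interpolation of decadal snapshots
#'
#' Piecewise-linear interpolation between bracketing snapshots, exact at the
#' snapshot years. Queries outside the snapshot range are clamped to the
#' nearest snapshot with a warning.
#'
#' @param decadal_values named numeric vector (names = snapshot years) or a
#'   data.frame with columns `year` and `value`.
#' @param year query year(s).
#' @return Numeric vector of interpolated values.
#' @export
interpolate_decadal <- function(decadal_values, year) {
  if (is.data.frame(decadal_values)) {
    yrs <- decadal_values$year; vals <- decadal_values$value
  } else {
    yrs <- as.numeric(names(decadal_values)); vals <- as.numeric(decadal_values)
  }
  if (length(yrs) < 1 || anyNA(yrs)) stop_params("decadal snapshots need year labels")
  if (any(year < min(yrs) | year > max(yrs))) {
    warning("query year outside snapshot range; clamping to nearest snapshot",
            call. = FALSE)
  }
  if (length(yrs) == 1) return(rep(vals, length(year)))
  stats::approx(yrs, vals, xout = year, rule = 2)$y
}

#' Fractional cover of a class on a coarser grid
#'
#' Fraction of fine-grid cells belonging to `target_class` within each coarse
#' cell. The fine grid must nest integrally in the coarse grid.
#'
#' @param fine_class_grid matrix of class codes.
#' @param coarse_dims length-2 integer vector `c(n_rows, n_cols)` of the
#'   coarse grid.
#' @param target_class class code to tally.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
fractional_cover <- function(fine_class_grid, coarse_dims, target_class) {
  nrf <- nrow(fine_class_grid); ncf <- ncol(fine_class_grid)
  nrc <- coarse_dims[1]; ncc <- coarse_dims[2]
  if (nrf %% nrc != 0 || ncf %% ncc != 0) {
    stop_params("fine grid (%d x %d) does not nest integrally in coarse grid (%d x %d)",
                nrf, ncf, nrc, ncc)
  }
  f1 <- nrf %/% nrc; f2 <- ncf %/% ncc
  ind <- (fine_class_grid == target_class) * 1
  rs <- rowsum(ind, rep(seq_len(nrc), each = f1))
  cs <- t(rowsum(t(rs), rep(seq_len(ncc), each = f2)))
  matrix(cs / (f1 * f2), nrc, ncc)
}

#' Euclidean distance to the nearest feature cell
#'
#' Distance (km) from every cell center to the nearest cell flagged in the
#' feature mask; feature cells themselves get 0.
#'
#' @param feature_mask logical matrix; must contain at least one TRUE.
#' @param cell_km cell size in km.
#' @return Numeric matrix of distances.
#' @export
distance_to_features <- function(feature_mask, cell_km = 1) {
  idx <- which(feature_mask)
  if (length(idx) == 0) stop_params("feature mask is empty")
  nr <- nrow(feature_mask); nc <- ncol(feature_mask)
  fr <- ((idx - 1L) %% nr) + 1L
  fc <- ((idx - 1L) %/% nr) + 1L
  out <- matrix(NA_real_, nr, nc)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  # chunk cells to bound the distance-matrix size
  chunk <- max(1L, 2000000L %/% length(idx))
  for (s in seq(1L, nr * nc, by = chunk)) {
    e <- min(s + chunk - 1L, nr * nc)
    d2 <- outer(rows[s:e], fr, "-")^2 + outer(cols[s:e], fc, "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min)) * cell_km
  }
  out
}

#' Filter fire events by fuel-class size thresholds
#'
#' Retains only events whose area strictly exceeds the reporting threshold
#' for their fuel class — timber fires > 0.04 km^2 (10 acres), brush fires
#' > 0.12 km^2 (30 acres), grass fires > 1.21 km^2 (300 acres) — and merges
#' the retained events' burned cells into per-pixel burn years.
#'
#' @param events data.frame with one row per burned cell and columns
#'   `event_id`, `year`, `row`, `col`, `area_km2`, `fuel_class`
#'   (`fuel_class` in `timber`, `brush`, `grass`).
#' @param grid grid definition (list with `n_rows`, `n_cols`, `cell_km`).
#' @param thresholds named numeric vector of minimum areas (km^2) per class.
#' @return A `fire_history` of the retained burns, with the retained event
#'   table in `$events`.
#' @export
filter_fire_events <- function(events, grid,
                               thresholds = c(timber = 0.04, brush = 0.12,
                                              grass = 1.21)) {
  need <- c("event_id", "year", "row", "col", "area_km2", "fuel_class")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop_params("events missing columns: %s",
                                paste(miss, collapse = ", "))
  unknown <- setdiff(unique(events$fuel_class), names(thresholds))
  if (length(unknown)) {
    stop_params("unknown fuel class: %s", paste(unknown, collapse = ", "))
  }
  keep <- events$area_km2 > thresholds[events$fuel_class]
  kept <- events[keep, , drop = FALSE]
  burns <- unique(data.frame(
    pixel_id = pixel_id(kept$row, kept$col, grid$n_cols),
    row = kept$row, col = kept$col, year = kept$year
  ))
  yr_range <- if (nrow(events)) range(events$year) else c(NA_integer_, NA_integer_)
  fire_history(burns, grid, record_start = yr_range[1], year_end = yr_range[2],
               events = unique(kept[c("event_id", "year", "area_km2", "fuel_class")]))
}

#' Assemble the pixel-year modelling table
#'
#' One record per valid pixel and requested year, carrying the binary burned
#' label and the nine model covariates. Excluded are cells outside the
#' panel's validity mask and cells with 50% or more water cover. Climate
#' normals are computed from the panel's annual layers over its base period;
#' three-year deviations require the three preceding years to be present in
#' the panel. Housing density is interpolated between decadal snapshots and
#' averaged over a 25-km focal disk (focal smoothing is applied per snapshot
#' and interpolated, which is exact because both operations are linear).
#'
#' @param panel a `landscape_panel`.
#' @param history a `fire_history`.
#' @param years integer vector of years to emit.
#' @param ysf_cap cap for years since fire (default 100).
#' @param housing_radius_km focal radius for housing density (default 25).
#' @return data.frame with columns `pixel_id, row, col, year, burned` and the
#'   nine [fire_covariates], ordered by year then pixel id.
#' @export
build_design_table <- function(panel, history, years, ysf_cap = 100,
                               housing_radius_km = 25) {
  stopifnot(inherits(panel, "landscape_panel"))
  years <- sort(as.integer(years))
  if (!all(years %in% panel$years)) {
    stop_params("requested years outside panel: %s",
                paste(setdiff(years, panel$years), collapse = ", "))
  }
  g <- panel$grid
  nr <- g$n_rows; nc <- g$n_cols

  aet_normal <- compute_normal(panel$annual$aet, panel$normal_base_period)
  cwd_normal <- compute_normal(panel$annual$cwd, panel$normal_base_period)
  dist_roads <- distance_to_features(panel$static$road_mask, g$cell_km)
  dist_elec <- distance_to_features(panel$static$electrical_mask, g$cell_km)

  valid <- panel$mask & (panel$static$water_fraction < 0.5) &
    !is.na(aet_normal) & !is.na(cwd_normal)
  vidx <- which(valid)
  vrow <- ((vidx - 1L) %% nr) + 1L
  vcol <- ((vidx - 1L) %/% nr) + 1L
  vid <- pixel_id(vrow, vcol, nc)

  # focal housing per snapshot, then linear interpolation across snapshots
  hg <- panel$housing
  focal_snap <- lapply(seq_along(hg$years), function(j) {
    focal_mean_density(hg$density[, , j], housing_radius_km, g$cell_km,
                       mask = panel$mask)
  })
  housing_year <- function(y) {
    if (length(hg$years) == 1) return(focal_snap[[1]])
    w <- stats::approx(hg$years, seq_along(hg$years), xout = y, rule = 2)$y
    lo <- floor(w); hi <- ceiling(w)
    if (lo == hi) return(focal_snap[[lo]])
    (hi - w) * focal_snap[[lo]] + (w - lo) * focal_snap[[hi]]
  }

  ysf <- ysf_series(history, years, cap = ysf_cap)
  b <- history$burns

  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    aet_d3 <- compute_three_year_deviation(panel$annual$aet, aet_normal, y)
    cwd_d3 <- compute_three_year_deviation(panel$annual$cwd, cwd_normal, y)
    hh <- housing_year(y)
    burned <- rep(0L, length(vidx))
    by <- b$pixel_id[b$year == y]
    burned[vid %in% by] <- 1L
    rows[[i]] <- data.frame(
      pixel_id = vid, row = vrow, col = vcol, year = y, burned = burned,
      aet_normal = aet_normal[vidx], cwd_normal = cwd_normal[vidx],
      aet_dev3 = aet_d3[vidx], cwd_dev3 = cwd_d3[vidx],
      housing_density_25km = hh[vidx],
      cultivated_fraction = panel$static$cultivated_fraction[vidx],
      dist_roads = dist_roads[vidx], dist_electrical = dist_elec[vidx],
      years_since_fire = as.numeric(ysf[[as.character(y)]][vidx])
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$pixel_id), , drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out[fire_covariates])) {
    stop_params("internal error: missing covariates in emitted records")
  }
  out
}
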