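# Synthetic landscape and fire-history generator.
#
# Emulates, with a known additive ground truth, the statistical structure of
# the gridded covariates used for annual fire-probability modelling: smooth
# climate-normal surfaces with interannual anomalies, housing-density
# gradients with urban cores, scattered linear infrastructure, cultivated and
# water fractions, and a fire process whose per-pixel annual burn probability
# is inverse-logit of an additive function of the covariates (including a
# years-since-fire feedback).

#' Default ground-truth effect functions
#'
#' Returns the additive effect functions (log-odds scale) used by default to
#' simulate fire histories. Shapes follow the qualitative findings of
#' statewide fire-probability modelling: a hump-shaped effect of the AET
#' normal (fire peaks at intermediate productivity), a rise-then-fall effect
#' of the CWD normal (probability declines again under severe water deficit),
#' a years-since-fire effect that rises rapidly over the first ~20 years and
#' then saturates, a hump-shaped effect of housing density (moderate
#' development is most fire-prone), a strong negative effect of cultivation,
#' mild positive effects of dry three-year climate deviations, and mild
#' negative effects of distance from roads and electrical infrastructure.
#'
#' Each element is a vectorized function of the covariate, named after one of
#' [fire_covariates]. Effects are roughly centered near zero over the
#' generated covariate ranges so the intercept controls the marginal burn
#' rate.
#'
#' @return Named list of functions.
#' @export
default_true_effects <- function() {
  list(
    aet_normal = function(x) 1.6 * exp(-((x - 550) / 260)^2) - 0.8,
    cwd_normal = function(x) 1.1 * exp(-((x - 750) / 350)^2) - 0.6,
    aet_dev3 = function(x) -0.002 * x,
    cwd_dev3 = function(x) 0.004 * x,
    housing_density_25km = function(x) 1.0 * exp(-((x - 8) / 6)^2) - 0.4,
    cultivated_fraction = function(x) -2.5 * x,
    dist_roads = function(x) -0.015 * x,
    dist_electrical = function(x) -0.015 * x,
    years_since_fire = function(t) 1.8 * (1 - exp(-t / 8)) - 1.2
  )
}

#' Configuration for the synthetic landscape generator
#'
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param cell_km cell size in km (default 1, the modelling resolution).
#' @param year_start,year_end first and last calendar year with annual layers.
#' @param normal_base_period length-2 vector of years over which climate
#'   normals are computed (emulating a 1951-1980 style base period); must lie
#'   inside `[year_start, year_end]`.
#' @param field_correlation_range_km spatial correlation range of the static
#'   surfaces (km).
#' @param anomaly_correlation_range_km spatial correlation range of the
#'   interannual climate anomaly fields (km).
#' @param anomaly_sd standard deviation (mm) of annual AET/CWD anomalies
#'   about their normals.
#' @param true_effects named list of vectorized effect functions (log-odds
#'   scale), a subset of [fire_covariates]; see [default_true_effects()].
#' @param true_intercept log-odds intercept of the generating model. The
#'   default (-4.3) yields a marginal annual burn probability of roughly
#'   1-2%, a realistic statewide rate.
#' @param region_layout number of rectangular regions tiling the grid.
#' @param burn_in_years years of unrecorded simulation used to initialize the
#'   years-since-fire state (the recorded history is left-censored, like real
#'   fire perimeter archives).
#' @param ysf_cap maximum years-since-fire value (default 100).
#' @param seed integer seed; together with the config it fully determines the
#'   generated panel and history.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 64, n_cols = 64, cell_km = 1,
                             year_start = 1961, year_end = 2000,
                             normal_base_period = c(1961, 1980),
                             field_correlation_range_km = 15,
                             anomaly_correlation_range_km = 40,
                             anomaly_sd = 60,
                             true_effects = default_true_effects(),
                             true_intercept = -4.3,
                             region_layout = 4,
                             burn_in_years = 100,
                             ysf_cap = 100,
                             seed = 1) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_km = as.numeric(cell_km),
    year_start = as.integer(year_start), year_end = as.integer(year_end),
    normal_base_period = as.integer(normal_base_period),
    field_correlation_range_km = as.numeric(field_correlation_range_km),
    anomaly_correlation_range_km = as.numeric(anomaly_correlation_range_km),
    anomaly_sd = as.numeric(anomaly_sd),
    true_effects = true_effects,
    true_intercept = as.numeric(true_intercept),
    region_layout = as.integer(region_layout),
    burn_in_years = as.integer(burn_in_years),
    ysf_cap = as.integer(ysf_cap),
    seed = as.integer(seed)
  )
  errs <- character()
  if (cfg$n_rows < 8 || cfg$n_cols < 8) {
    errs <- c(errs, "n_rows and n_cols must both be >= 8")
  }
  if (cfg$year_end <= cfg$year_start) {
    errs <- c(errs, "year_end must be greater than year_start")
  }
  if (length(cfg$normal_base_period) != 2 ||
      cfg$normal_base_period[1] > cfg$normal_base_period[2] ||
      cfg$normal_base_period[1] < cfg$year_start ||
      cfg$normal_base_period[2] > cfg$year_end) {
    errs <- c(errs, "normal_base_period must be an increasing year range inside [year_start, year_end]")
  }
  if (cfg$field_correlation_range_km <= 0) {
    errs <- c(errs, "field_correlation_range_km must be positive")
  }
  if (cfg$anomaly_sd < 0) errs <- c(errs, "anomaly_sd must be non-negative")
  bad <- setdiff(names(cfg$true_effects), fire_covariates)
  if (length(bad)) {
    errs <- c(errs, paste0("unknown covariates in true_effects: ",
                           paste(bad, collapse = ", ")))
  }
  if (cfg$region_layout < 1) errs <- c(errs, "region_layout must be >= 1")
  if (length(errs)) stop_params("invalid synthetic_config: %s",
                                paste(errs, collapse = "; "))
  structure(cfg, class = "synthetic_config")
}

#' Generate a spatially autocorrelated Gaussian field
#'
#' White noise smoothed with a separable Gaussian kernel whose bandwidth is
#' set by the correlation range, then rescaled to the requested mean and
#' standard deviation (sample moments are matched exactly; `sd = 0` yields a
#' constant raster).
#'
#' @param grid list with `n_rows`, `n_cols`, `cell_km` (see details in
#'   [generate_landscape()]), or a `synthetic_config`.
#' @param correlation_range_km spatial correlation range (km, > 0).
#' @param mean,sd target sample mean and standard deviation.
#' @param seed integer seed; the field is reproducible given the seed.
#' @return Numeric matrix (`n_rows` x `n_cols`).
#' @export
generate_correlated_field <- function(grid, correlation_range_km, mean = 0,
                                      sd = 1, seed = 1) {
  if (correlation_range_km <= 0) {
    stop_params("correlation_range_km must be positive, got %g",
                correlation_range_km)
  }
  if (sd < 0) stop_params("sd must be non-negative, got %g", sd)
  nr <- grid$n_rows; nc <- grid$n_cols; cell <- grid$cell_km
  if (sd == 0) return(matrix(mean, nr, nc))
  sigma_cells <- correlation_range_km / (2 * cell)
  f <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  f <- gauss_smooth(f, sigma_cells)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(matrix(mean, nr, nc))
  mean + sd * (f - base::mean(f)) / s
}

# Rectangular region tiling: n_regions split into nearest-to-square factors.
region_tiling <- function(nr, nc, n_regions) {
  a <- floor(sqrt(n_regions))
  while (n_regions %% a != 0) a <- a - 1
  b <- n_regions %/% a
  # more bands along the longer axis
  if (nr >= nc) { rb <- max(a, b); cb <- min(a, b) } else { rb <- min(a, b); cb <- max(a, b) }
  row_band <- pmin(rb, ceiling(seq_len(nr) / (nr / rb)))
  col_band <- pmin(cb, ceiling(seq_len(nc) / (nc / cb)))
  outer(row_band, col_band, function(r, c) (r - 1L) * cb + c)
}

# A few straight lines (rows, columns or diagonals) as a logical mask.
line_mask <- function(nr, nc, n_lines, seed) {
  m <- matrix(FALSE, nr, nc)
  with_seed(seed, {
    for (i in seq_len(n_lines)) {
      kind <- sample(c("h", "v", "d"), 1)
      if (kind == "h") {
        m[sample(nr, 1), ] <- TRUE
      } else if (kind == "v") {
        m[, sample(nc, 1)] <- TRUE
      } else {
        off <- sample(seq(-nr %/% 2, nc %/% 2), 1)
        r <- seq_len(nr); c <- r + off
        ok <- c >= 1 & c <= nc
        m[cbind(r[ok], c[ok])] <- TRUE
      }
    }
  })
  m
}

#' Generate a synthetic landscape panel
#'
#' Builds all gridded layers the modelling pipeline consumes: annual AET and
#' CWD (a smooth normal surface plus a yearly anomaly field), decadal housing
#' density snapshots (a smooth background with a few urban cores, growing
#' monotonically across decades), cultivated and water fractions, road and
#' electrical-infrastructure masks, a rectangular region tiling, and a
#' validity mask. The generating normal surfaces are stored in `$truth` so
#' tests can compare derived quantities with the ground truth.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `landscape_panel`: a list with `grid`, `years`,
#'   `annual` (3-D arrays `aet`, `cwd` with year dimnames), `housing`
#'   (`years`, 3-D array `density`), `static` (cultivated_fraction,
#'   water_fraction, road_mask, electrical_mask, region_id), `mask`,
#'   `normal_base_period`, `truth`, and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- grid_def(config$n_rows, config$n_cols, config$cell_km)
  nr <- g$n_rows; nc <- g$n_cols
  years <- config$year_start:config$year_end
  rng <- config$field_correlation_range_km
  sd_seed <- config$seed

  aet_normal <- generate_correlated_field(g, rng, mean = 500, sd = 180,
                                          seed = derive_seed(sd_seed, 1))
  cwd_normal <- generate_correlated_field(g, rng, mean = 800, sd = 250,
                                          seed = derive_seed(sd_seed, 2))
  aet_normal <- pmax(aet_normal, 20)
  cwd_normal <- pmax(cwd_normal, 50)

  aet <- array(NA_real_, c(nr, nc, length(years)),
               dimnames = list(NULL, NULL, as.character(years)))
  cwd <- aet
  for (i in seq_along(years)) {
    aet[, , i] <- aet_normal + generate_correlated_field(
      g, config$anomaly_correlation_range_km, 0, config$anomaly_sd,
      seed = derive_seed(sd_seed, 100 + i))
    cwd[, , i] <- cwd_normal + generate_correlated_field(
      g, config$anomaly_correlation_range_km, 0, config$anomaly_sd,
      seed = derive_seed(sd_seed, 500 + i))
  }

  # Housing: smooth low background plus a few urban cores; decadal snapshots
  # grow monotonically from 60% to 100% of the final surface.
  background <- 2 * stats::plogis(generate_correlated_field(
    g, rng, 0, 1.2, seed = derive_seed(sd_seed, 3)))
  cores <- matrix(0, nr, nc)
  with_seed(derive_seed(sd_seed, 4), {
    n_cores <- max(2L, nr %/% 20L)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(n_cores)) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      amp <- stats::runif(1, 80, 300)
      wid <- stats::runif(1, nr / 20, nr / 8)
      cores <- cores + amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * wid^2))
    }
  })
  housing_final <- background + cores
  decades <- seq(10 * (config$year_start %/% 10),
                 10 * ((config$year_end + 9) %/% 10), by = 10)
  housing <- array(NA_real_, c(nr, nc, length(decades)),
                   dimnames = list(NULL, NULL, as.character(decades)))
  for (j in seq_along(decades)) {
    frac <- if (length(decades) == 1) 1 else 0.6 + 0.4 * (j - 1) / (length(decades) - 1)
    housing[, , j] <- housing_final * frac
  }

  cultivated <- stats::plogis(1.5 * generate_correlated_field(
    g, rng, 0, 1, seed = derive_seed(sd_seed, 5)) - 2)
  water <- stats::plogis(2 * generate_correlated_field(
    g, rng, 0, 1, seed = derive_seed(sd_seed, 6)) - 4)

  n_lines <- max(2L, (nr + nc) %/% 40L)
  road_mask <- line_mask(nr, nc, n_lines, derive_seed(sd_seed, 7))
  electrical_mask <- line_mask(nr, nc, max(1L, n_lines %/% 2L),
                               derive_seed(sd_seed, 8))

  structure(list(
    grid = g,
    years = years,
    annual = list(aet = aet, cwd = cwd),
    housing = list(years = decades, density = housing),
    static = list(
      cultivated_fraction = cultivated,
      water_fraction = water,
      road_mask = road_mask,
      electrical_mask = electrical_mask,
      region_id = region_tiling(nr, nc, config$region_layout)
    ),
    mask = matrix(TRUE, nr, nc),
    normal_base_period = config$normal_base_period,
    truth = list(aet_normal = aet_normal, cwd_normal = cwd_normal,
                 housing_final = housing_final),
    config = config
  ), class = "landscape_panel")
}

#' @export
print.landscape_panel <- function(x, ...) {
  cat(sprintf("landscape_panel: %d x %d grid (%g km cells), years %d-%d\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_km,
              min(x$years), max(x$years)))
  cat(sprintf("  %d housing snapshots, %d regions, %d valid cells\n",
              length(x$housing$years), length(unique(as.vector(x$static$region_id))),
              sum(x$mask)))
  invisible(x)
}

# Construct a fire_history object from a burns data.frame.
fire_history <- function(burns, grid, record_start, year_end, events = NULL) {
  burns <- burns[order(burns$year, burns$pixel_id), , drop = FALSE]
  rownames(burns) <- NULL
  structure(list(burns = burns, grid = grid,
                 record_start = as.integer(record_start),
                 year_end = as.integer(year_end),
                 events = events),
            class = "fire_history")
}

#' @export
print.fire_history <- function(x, ...) {
  cat(sprintf("fire_history: %d pixel-burns over %d-%d on a %d x %d grid\n",
              nrow(x$burns), x$record_start, x$year_end,
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Simulate a fire history from an additive ground truth
#'
#' For every simulation year, each pixel's burn probability is
#' `plogis(intercept + sum_j f_j(x_j))` evaluated at the current covariate
#' values (including the evolving years-since-fire state); an independent
#' Bernoulli draw decides whether the pixel burns, and the state is updated.
#' A burn-in period is simulated before the recorded window to initialize the
#' years-since-fire state, mirroring left-censored fire-perimeter archives;
#' burn-in burns are not recorded. Three-year climate deviations are taken as
#' the trailing mean anomaly about the generating normal surfaces (zero when
#' preceding years are unavailable), and the housing effect is evaluated at
#' the pixel's interpolated density.
#'
#' @param panel a [generate_landscape()] panel.
#' @param true_effects named list of effect functions; defaults to the
#'   panel config's.
#' @param true_intercept log-odds intercept; defaults to the panel config's.
#' @param burn_in_years unrecorded initialization years (default from config).
#' @param seed integer seed for the Bernoulli draws.
#' @return A `fire_history` with attributes `mean_probability` (named
#'   per-recorded-year mean of the generating probabilities) and
#'   `true_probability` (per-pixel mean generating probability over the
#'   recorded window).
#' @export
simulate_fire_history <- function(panel, true_effects = NULL,
                                  true_intercept = NULL,
                                  burn_in_years = NULL, seed = 1) {
  stopifnot(inherits(panel, "landscape_panel"))
  cfg <- panel$config
  if (is.null(true_effects)) true_effects <- cfg$true_effects
  if (is.null(true_intercept)) true_intercept <- cfg$true_intercept
  if (is.null(burn_in_years)) burn_in_years <- cfg$burn_in_years
  cap <- cfg$ysf_cap
  g <- panel$grid
  nr <- g$n_rows; nc <- g$n_cols; npix <- nr * nc
  years <- panel$years

  eff <- function(name, x) {
    f <- true_effects[[name]]
    if (is.null(f)) 0 else {
      v <- f(x)
      if (any(!is.finite(v))) {
        v[v == -Inf] <- -745  # hard-refractory sentinel stays finite post-link
        if (any(!is.finite(v))) {
          stop_params("effect '%s' is not finite over the generated range", name)
        }
      }
      v
    }
  }

  dist_roads <- distance_to_features(panel$static$road_mask, g$cell_km)
  dist_elec <- distance_to_features(panel$static$electrical_mask, g$cell_km)
  eta_static <- true_intercept +
    eff("aet_normal", panel$truth$aet_normal) +
    eff("cwd_normal", panel$truth$cwd_normal) +
    eff("cultivated_fraction", panel$static$cultivated_fraction) +
    eff("dist_roads", dist_roads) +
    eff("dist_electrical", dist_elec)
  if (length(eta_static) == 1) eta_static <- matrix(eta_static, nr, nc)

  aet_anom <- sweep(panel$annual$aet, c(1, 2), panel$truth$aet_normal)
  cwd_anom <- sweep(panel$annual$cwd, c(1, 2), panel$truth$cwd_normal)
  year_chr <- as.character(years)

  dev3 <- function(anom, y) {
    prev <- intersect(as.character((y - 3):(y - 1)), year_chr)
    if (length(prev) == 0) return(matrix(0, nr, nc))
    apply(anom[, , prev, drop = FALSE], c(1, 2), mean)
  }
  housing_at <- function(y) {
    hy <- panel$housing$years
    if (length(hy) == 1) return(panel$housing$density[, , 1])
    w <- stats::approx(hy, seq_along(hy), xout = y, rule = 2)$y
    lo <- floor(w); hi <- ceiling(w)
    if (lo == hi) return(panel$housing$density[, , lo])
    (hi - w) * panel$housing$density[, , lo] +
      (w - lo) * panel$housing$density[, , hi]
  }

  sim_years <- (min(years) - burn_in_years):max(years)
  ysf <- matrix(cap, nr, nc)
  burn_rows <- vector("list", length(sim_years))
  mean_p <- stats::setNames(numeric(length(years)), year_chr)
  p_sum <- matrix(0, nr, nc)
  ids <- matrix(pixel_id(row(matrix(0, nr, nc)), col(matrix(0, nr, nc)), nc), nr, nc)

  with_seed(seed, {
    for (y in sim_years) {
      recorded <- y >= min(years)
      eta <- eta_static + eff("years_since_fire", pmin(ysf, cap))
      if (recorded) {
        eta <- eta +
          eff("aet_dev3", dev3(aet_anom, y)) +
          eff("cwd_dev3", dev3(cwd_anom, y)) +
          eff("housing_density_25km", housing_at(y))
      } else {
        eta <- eta + eff("housing_density_25km",
                         panel$housing$density[, , 1])
      }
      p <- stats::plogis(eta)
      burned <- matrix(stats::runif(npix) < p, nr, nc)
      if (recorded) {
        mean_p[as.character(y)] <- mean(p)
        p_sum <- p_sum + p
        if (any(burned)) {
          idx <- which(burned)
          burn_rows[[y - min(sim_years) + 1L]] <- data.frame(
            pixel_id = ids[idx],
            row = ((idx - 1L) %% nr) + 1L,
            col = ((idx - 1L) %/% nr) + 1L,
            year = y
          )
        }
      }
      ysf <- ifelse(burned, 1L, pmin(ysf + 1L, cap))
    }
  })

  burns <- do.call(rbind, burn_rows[!vapply(burn_rows, is.null, logical(1))])
  if (is.null(burns)) {
    burns <- data.frame(pixel_id = integer(), row = integer(),
                        col = integer(), year = integer())
  }
  hist <- fire_history(burns, g, record_start = min(years),
                       year_end = max(years))
  attr(hist, "mean_probability") <- mean_p
  attr(hist, "true_probability") <- p_sum / length(years)
  hist
}
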