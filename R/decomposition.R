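# Counterfactual decomposition: isolate the contribution of covariate
# subsets to predicted fire probability by replacing the remaining
# covariates with null values, and correlate the resulting mean-probability
# maps with the full model's map and with observed fire frequency.

# Null rule per covariate: climate normals have no meaningful null, so use
# the training mean; zero is meaningful for housing density, cultivation and
# the short-term climate deviations; distances use the training maximum
# (zero distance is where their influence is strongest).  years_since_fire
# has no stated null value and is removed via the training mean — an
# extension, flagged in the report.
null_rules <- c(
  aet_normal = "training_mean", cwd_normal = "training_mean",
  aet_dev3 = "zero", cwd_dev3 = "zero",
  housing_density_25km = "zero", cultivated_fraction = "zero",
  dist_roads = "training_max", dist_electrical = "training_max",
  years_since_fire = "training_mean"
)

#' Null value of a covariate for counterfactual elimination
#'
#' Training mean for the climate normals (and, as a flagged extension, years
#' since fire); zero for housing density, cultivated fraction and the
#' three-year climate deviations; training maximum for the distance
#' covariates.
#'
#' @param covariate covariate name.
#' @param model fitted `fire_gam` carrying training summaries.
#' @return Numeric null value.
#' @export
null_value <- function(covariate, model) {
  rule <- null_rules[covariate]
  if (is.na(rule)) {
    stop_params("no null rule defined for covariate '%s'", covariate)
  }
  ts <- model$train_summary
  row <- ts[ts$covariate == covariate, , drop = FALSE]
  if (nrow(row) == 0) {
    stop_params("covariate '%s' has no training summary in the model", covariate)
  }
  switch(rule,
         training_mean = row$mean,
         zero = 0,
         training_max = row$max)
}

#' Predict with a covariate subset (counterfactual elimination)
#'
#' Uses the full model's coefficients while eliminating the effects of the
#' covariates not in `active`: each inactive model covariate is replaced by
#' its [null_value()] in every record before prediction; active covariates
#' are untouched.
#'
#' @param model fitted `fire_gam`.
#' @param records pixel-year records.
#' @param active character vector of active covariate names.
#' @return Numeric vector of probabilities.
#' @export
predict_with_subset <- function(model, records, active) {
  model_covs <- names(model$terms)
  unknown <- setdiff(active, model_covs)
  if (length(unknown)) {
    stop_params("active covariates not in model: %s",
                paste(unknown, collapse = ", "))
  }
  inactive <- setdiff(model_covs, active)
  for (nm in inactive) records[[nm]] <- null_value(nm, model)
  predict_probability(model, records)
}

#' Default covariate subsets for the decomposition report
#'
#' The standard subset ladder: all parameters; climate (normals plus
#' three-year deviations); climate normals only; human activity (housing
#' density, cultivation, distances); development (housing density plus
#' distances); cultivation only; time since fire only.
#'
#' @return Named list of character vectors.
#' @export
default_subsets <- function() {
  list(
    all = fire_covariates,
    climate = c("aet_normal", "cwd_normal", "aet_dev3", "cwd_dev3"),
    climate_normal = c("aet_normal", "cwd_normal"),
    human_activity = c("housing_density_25km", "cultivated_fraction",
                       "dist_roads", "dist_electrical"),
    development = c("housing_density_25km", "dist_roads", "dist_electrical"),
    cultivation = "cultivated_fraction",
    time_since_fire = "years_since_fire"
  )
}

#' Mean annual predicted probability per pixel
#'
#' Per-pixel arithmetic mean of annual predicted probabilities over a period;
#' every year of the period must be present.
#'
#' @param per_year_predictions data.frame with columns `pixel_id`, `year`,
#'   `prob`.
#' @param period integer vector of years.
#' @return data.frame with columns `pixel_id`, `mean_prob`.
#' @export
mean_annual_probability <- function(per_year_predictions, period) {
  period <- as.integer(period)
  have <- unique(per_year_predictions$year)
  miss <- setdiff(period, have)
  if (length(miss)) {
    stop_params("predictions missing for years: %s", paste(miss, collapse = ", "))
  }
  sub <- per_year_predictions[per_year_predictions$year %in% period, ,
                              drop = FALSE]
  agg <- tapply(sub$prob, sub$pixel_id, mean)
  data.frame(pixel_id = as.integer(names(agg)), mean_prob = as.numeric(agg))
}

#' Observed mean annual fire probability per pixel
#'
#' Number of recorded burn years within the period divided by the period
#' length, per pixel. The period may extend before the modelling window to
#' use the longer observational record on the observed side only.
#'
#' @param history a `fire_history`.
#' @param pixels vector of pixel ids to report.
#' @param period integer vector of years.
#' @return data.frame with columns `pixel_id`, `obs_prob`.
#' @export
observed_mean_annual_probability <- function(history, pixels, period) {
  period <- as.integer(period)
  if (length(period) == 0) stop_params("period must be nonempty")
  b <- history$burns
  b <- unique(b[b$year %in% period, c("pixel_id", "year")])
  counts <- table(factor(b$pixel_id, levels = pixels))
  data.frame(pixel_id = as.integer(pixels),
             obs_prob = as.numeric(counts) / length(period))
}

#' Pearson correlation between two pixel maps
#'
#' Pearson correlation over the common valid (non-NA) pixels, with p-value
#' and df = n - 2 from [stats::cor.test()]. A zero-variance map makes the
#' correlation undefined: NA is returned with a warning.
#'
#' @param map_a,map_b equal-length numeric vectors (or matrices) of per-pixel
#'   values.
#' @return List with `r`, `p_value`, `df`, `n`.
#' @export
correlate_maps <- function(map_a, map_b) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b)) stop_params("maps must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop_params("need at least 3 common valid pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance map: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, df = length(a) - 2,
                n = length(a)))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(a))
}

#' Counterfactual decomposition report
#'
#' For each covariate subset, predicts annual probabilities with the
#' remaining covariates eliminated, averages them per pixel over the period,
#' and correlates the resulting map with (a) the observed mean annual fire
#' probability and (b) the full model's mean-probability map. The identity
#' subset reproduces the full predictions, so its full-model correlation is
#' 1 by construction.
#'
#' @param model fitted `fire_gam`.
#' @param records pixel-year records covering every year of `period` for the
#'   pixels of interest (by default the sampled pixels; pass records for all
#'   valid pixels for statewide maps).
#' @param history a `fire_history` (the observed side may use a longer
#'   record via `observed_period`).
#' @param subsets named list of active-covariate vectors
#'   (default [default_subsets()], intersected with the model's covariates).
#' @param period integer vector of prediction years.
#' @param observed_period years for the observed frequency (default
#'   `period`).
#' @return data.frame with one row per subset: `subset`, `n_pixels`,
#'   `r_observed`, `p_observed`, `r_full`, `p_full`, `note`.
#' @export
decomposition_report <- function(model, records, history,
                                 subsets = default_subsets(), period,
                                 observed_period = period) {
  period <- as.integer(period)
  model_covs <- names(model$terms)
  recs <- records[records$year %in% period, , drop = FALSE]
  pixels <- sort(unique(recs$pixel_id))
  obs <- observed_mean_annual_probability(history, pixels, observed_period)

  subset_map <- function(active) {
    p <- predict_with_subset(model, recs, active)
    mp <- mean_annual_probability(
      data.frame(pixel_id = recs$pixel_id, year = recs$year, prob = p), period)
    mp[match(pixels, mp$pixel_id), "mean_prob"]
  }
  full_map <- subset_map(model_covs)

  rows <- lapply(names(subsets), function(nm) {
    active <- intersect(subsets[[nm]], model_covs)
    if (length(active) == 0) return(NULL)
    m <- subset_map(active)
    co <- correlate_maps(m, obs$obs_prob)
    cf <- correlate_maps(m, full_map)
    ysf_nulled <- "years_since_fire" %in% setdiff(model_covs, active)
    data.frame(subset = nm, n_pixels = length(pixels),
               r_observed = co$r, p_observed = co$p_value,
               r_full = cf$r, p_full = cf$p_value,
               note = if (ysf_nulled)
                 "years_since_fire eliminated at training mean (extension)"
               else "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
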