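# Experiment configuration, validation and the end-to-end runner tying
# simulate -> features -> sample -> fit -> cross-validate -> decompose into
# one reproducible experiment with a written manifest.

#' Build an experiment configuration
#'
#' Collects every stage's parameters with the standard defaults: 5-km
#' Poisson-disk minimum distance, 10 cross-validation groups per axis,
#' spline basis dimension 5, 100-year years-since-fire cap. The master seed
#' deterministically derives all stage seeds.
#'
#' @param synthetic a [synthetic_config()] describing the landscape.
#' @param min_dist_km Poisson-disk minimum distance (km).
#' @param n_cv_groups CV groups per axis.
#' @param basis_dim spline basis dimension per smooth term.
#' @param ysf_cap years-since-fire cap.
#' @param term_covariates covariates to smooth in the model.
#' @param lambda_rule smoothing-parameter rule for [fit_binomial_gam()].
#' @param subsets decomposition subsets (default [default_subsets()]).
#' @param period prediction period (default: all modelable years).
#' @param seed master seed.
#' @param out_dir output directory for [run_experiment()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              min_dist_km = 5, n_cv_groups = 10,
                              basis_dim = 5, ysf_cap = 100,
                              term_covariates = fire_covariates,
                              lambda_rule = "gcv",
                              subsets = default_subsets(),
                              period = NULL, seed = 1,
                              out_dir = tempfile("pyrogam_run_")) {
  structure(list(
    synthetic = synthetic,
    min_dist_km = min_dist_km, n_cv_groups = n_cv_groups,
    basis_dim = basis_dim, ysf_cap = ysf_cap,
    term_covariates = term_covariates, lambda_rule = lambda_rule,
    subsets = subsets, period = period, seed = seed, out_dir = out_dir
  ), class = "experiment_config")
}

#' Validate and normalize an experiment configuration
#'
#' Fills defaults and checks every field, reporting all violations at once
#' rather than stopping at the first.
#'
#' @param config an `experiment_config` (or plain list of its fields).
#' @return List with `valid` (logical), `errors` (character vector, empty
#'   when valid) and `config` (the normalized configuration when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  defaults <- experiment_config()
  cfg <- utils::modifyList(unclass(defaults), unclass(config)[!vapply(config, is.null, TRUE)])
  class(cfg) <- "experiment_config"
  sc <- cfg$synthetic
  if (!inherits(sc, "synthetic_config")) {
    sc <- tryCatch(do.call(synthetic_config, as.list(sc)),
                   error = function(e) {
                     errs <<- c(errs, conditionMessage(e))
                     NULL
                   })
    if (!is.null(sc)) cfg$synthetic <- sc
  }
  if (!is.null(sc)) {
    if (sc$n_rows < 8 || sc$n_cols < 8) {
      errs <- c(errs, "synthetic: n_rows and n_cols must be >= 8")
    }
  }
  if (!is.numeric(cfg$min_dist_km) || cfg$min_dist_km < 0) {
    errs <- c(errs, "min_dist_km must be >= 0")
  }
  if (!is.numeric(cfg$n_cv_groups) || cfg$n_cv_groups < 2) {
    errs <- c(errs, "n_cv_groups must be >= 2")
  }
  if (!is.numeric(cfg$basis_dim) || cfg$basis_dim < 3) {
    errs <- c(errs, "basis_dim must be >= 3 (cubic regression splines need at least 3 knots)")
  }
  if (!is.numeric(cfg$ysf_cap) || cfg$ysf_cap < 1) {
    errs <- c(errs, "ysf_cap must be >= 1")
  }
  bad <- setdiff(cfg$term_covariates, fire_covariates)
  if (length(bad)) {
    errs <- c(errs, paste0("unknown term covariates: ", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    errs <- c(errs, "seed must be a single integer")
  }
  if (!is.null(cfg$period) && !is.null(sc)) {
    if (any(cfg$period < sc$year_start + 3 | cfg$period > sc$year_end)) {
      errs <- c(errs, "period must lie within the modelable years (year_start + 3 .. year_end)")
    }
  }
  list(valid = length(errs) == 0, errors = errs,
       config = if (length(errs) == 0) cfg else NULL)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run a full experiment end to end
#'
#' Generates the synthetic landscape and fire history, builds the modelling
#' table, thins training pixels by Poisson-disk sampling, fits the pooled
#' GAM, runs statewide, regional and leave-one-region-out cross-validation,
#' computes the counterfactual decomposition report, and writes every
#' artifact plus a manifest (file, stage, md5 checksum, seed) to the output
#' directory. Rerunning with the same configuration reproduces identical
#' checksums for all deterministic stages.
#'
#' @param config an [experiment_config()]; validated first, with all
#'   violations reported together.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with the manifest data.frame and the in-memory
#'   stage results.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  chk <- validate_config(config)
  if (!chk$valid) {
    stop_params("invalid experiment config:\n- %s",
                paste(chk$errors, collapse = "\n- "))
  }
  cfg <- chk$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character(), seed = integer())
  say <- function(...) if (!quiet) message(sprintf(...))
  add <- function(path, stage, seed) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)), seed = as.integer(seed)))
  }
  stage <- "simulate"
  t0 <- proc.time()["elapsed"]
  tryCatch({
    sc <- cfg$synthetic
    sc$seed <- derive_seed(cfg$seed, 1)
    say("[simulate] landscape %dx%d, years %d-%d (seed %d)",
        sc$n_rows, sc$n_cols, sc$year_start, sc$year_end, sc$seed)
    panel <- generate_landscape(sc)
    history <- simulate_fire_history(panel, seed = derive_seed(cfg$seed, 2))
    p_hist <- file.path(cfg$out_dir, "fire_history.csv")
    write_stage_csv(history$burns, p_hist)
    add(p_hist, stage, sc$seed)
    for (nm in c("cultivated_fraction", "water_fraction", "region_id")) {
      p <- file.path(cfg$out_dir, paste0(nm, ".csv"))
      m <- panel$static[[nm]]
      write_stage_csv(data.frame(row = as.vector(row(m)),
                                 col = as.vector(col(m)),
                                 value = as.vector(m)), p)
      add(p, stage, sc$seed)
    }

    stage <- "features"
    years <- (sc$year_start + 3):sc$year_end
    period <- if (is.null(cfg$period)) years else cfg$period
    say("[features] design table for %d years", length(years))
    table <- build_design_table(panel, history, years, ysf_cap = cfg$ysf_cap)
    p_tab <- file.path(cfg$out_dir, "design_table.csv")
    write_stage_csv(table, p_tab)
    add(p_tab, stage, sc$seed)

    stage <- "sample"
    cand <- unique(table[c("pixel_id", "row", "col")])
    samp <- poisson_disk_sample(cand, cfg$min_dist_km,
                                cell_km = panel$grid$cell_km,
                                seed = derive_seed(cfg$seed, 3))
    say("[sample] %d of %d pixels kept at min distance %g km",
        nrow(samp$pixels), nrow(cand), cfg$min_dist_km)
    p_samp <- file.path(cfg$out_dir, "sample_set.csv")
    write_stage_csv(samp$pixels[order(samp$pixels$pixel_id), ], p_samp)
    add(p_samp, stage, samp$seed)
    train <- table[table$pixel_id %in% samp$pixels$pixel_id, , drop = FALSE]

    stage <- "fit"
    specs <- smooth_terms(cfg$term_covariates, cfg$basis_dim)
    say("[fit] pooled GAM on %d records, %d smooth terms",
        nrow(train), length(specs))
    model <- fit_binomial_gam(train, specs, lambda_rule = cfg$lambda_rule)
    p_mod <- file.path(cfg$out_dir, "model.json")
    write_fitted_gam(model, p_mod)
    add(p_mod, stage, cfg$seed)
    p_eff <- file.path(cfg$out_dir, "partial_effects.csv")
    eff <- do.call(rbind, lapply(names(model$terms), function(nm) {
      pe <- partial_effect(model, nm)
      cbind(term = nm, pe)
    }))
    write_stage_csv(eff, p_eff)
    add(p_eff, stage, cfg$seed)

    stage <- "cv"
    plan <- assign_cv_groups(unique(train$year), unique(train$pixel_id),
                             n_groups = cfg$n_cv_groups,
                             seed = derive_seed(cfg$seed, 4))
    say("[cv] statewide spatiotemporal CV, %d iterations", cfg$n_cv_groups)
    cv <- run_spatiotemporal_cv(train, plan, specs,
                                lambda_rule = cfg$lambda_rule)
    p_cv <- file.path(cfg$out_dir, "cv_statewide.csv")
    write_stage_csv(as.data.frame(cv), p_cv)
    add(p_cv, stage, plan$seed)

    stage <- "regional-cv"
    rc <- pixel_rc(cand$pixel_id, panel$grid$n_cols)
    region_ids <- data.frame(
      pixel_id = cand$pixel_id,
      region = panel$static$region_id[cbind(rc$row, rc$col)])
    say("[regional-cv] %d regions", length(unique(region_ids$region)))
    rcv <- run_regional_cv(train, region_ids, plan, specs,
                           lambda_rule = cfg$lambda_rule)
    rcv_df <- do.call(rbind, lapply(names(rcv), function(r) {
      cbind(region = r, as.data.frame(rcv[[r]]))
    }))
    p_rcv <- file.path(cfg$out_dir, "cv_regional.csv")
    write_stage_csv(if (is.null(rcv_df)) data.frame() else rcv_df, p_rcv)
    add(p_rcv, stage, plan$seed)

    stage <- "loro-cv"
    loro <- run_leave_one_region_out(train, region_ids, specs,
                                     lambda_rule = cfg$lambda_rule)
    p_loro <- file.path(cfg$out_dir, "cv_leave_one_region_out.csv")
    write_stage_csv(loro, p_loro)
    add(p_loro, stage, cfg$seed)

    stage <- "decompose"
    say("[decompose] %d subsets over %d-%d", length(cfg$subsets),
        min(period), max(period))
    report <- decomposition_report(model, train, history,
                                   subsets = cfg$subsets, period = period)
    p_dec <- file.path(cfg$out_dir, "decomposition.csv")
    write_stage_csv(report, p_dec)
    add(p_dec, stage, cfg$seed)

    p_man <- file.path(cfg$out_dir, "manifest.csv")
    write_stage_csv(manifest, p_man)
    say("done in %.1f s; %d artifacts in %s",
        proc.time()["elapsed"] - t0, nrow(manifest), cfg$out_dir)
    invisible(list(manifest = manifest, panel = panel, history = history,
                   table = table, sample = samp, model = model, cv = cv,
                   regional_cv = rcv, loro = loro, decomposition = report))
  }, error = function(e) {
    p_man <- file.path(cfg$out_dir, "manifest.csv")
    write_stage_csv(manifest, p_man)
    stop_params("experiment failed in stage '%s': %s (partial manifest written)",
                stage, conditionMessage(e))
  })
}

#' Write an experiment configuration as YAML
#'
#' Serializes the scalar fields of the configuration (effect functions are
#' recorded by name only) so a run can be reproduced from the file.
#'
#' @param config an `experiment_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  sc <- config$synthetic
  obj <- list(
    synthetic = list(
      n_rows = sc$n_rows, n_cols = sc$n_cols, cell_km = sc$cell_km,
      year_start = sc$year_start, year_end = sc$year_end,
      normal_base_period = sc$normal_base_period,
      field_correlation_range_km = sc$field_correlation_range_km,
      anomaly_correlation_range_km = sc$anomaly_correlation_range_km,
      anomaly_sd = sc$anomaly_sd,
      true_effects = names(sc$true_effects),
      true_intercept = sc$true_intercept,
      region_layout = sc$region_layout,
      burn_in_years = sc$burn_in_years,
      ysf_cap = sc$ysf_cap, seed = sc$seed
    ),
    min_dist_km = config$min_dist_km, n_cv_groups = config$n_cv_groups,
    basis_dim = config$basis_dim, ysf_cap = config$ysf_cap,
    term_covariates = config$term_covariates,
    subsets = config$subsets, seed = config$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}
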