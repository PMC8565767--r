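# Predictive-skill evaluation under novel spatial and temporal conditions:
# multidimensional (spatiotemporal) blocked cross-validation, ROC/AUC
# scoring, regional vs statewide comparison, leave-one-region-out, and
# paired t-tests between model variants.

#' ROC/AUC by the Mann-Whitney convention
#'
#' Probability that a randomly chosen positive receives a higher score than
#' a randomly chosen negative, with ties counted one half. Scores <= 0.5
#' indicate no separation between classes; 1.0 indicates perfect separation.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) {
    stop_params("labels and scores must have equal length")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_params("AUC undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Assign spatiotemporal cross-validation groups
#'
#' Seeded random partition of the study years into `n_groups` temporal
#' groups and of the (sampled) pixels into `n_groups` spatial groups, each
#' with sizes differing by at most one.
#'
#' @param years integer vector of study years (>= `n_groups` of them).
#' @param pixels vector of pixel ids (>= `n_groups` of them).
#' @param n_groups number of groups per axis (default 10).
#' @param seed integer seed.
#' @return Object of class `cv_plan`: `year_groups` (named integer vector by
#'   year), `pixel_groups` (named by pixel id), `n_groups`, `seed`.
#' @export
assign_cv_groups <- function(years, pixels, n_groups = 10, seed = 1) {
  years <- unique(as.integer(years))
  pixels <- unique(pixels)
  if (length(years) < n_groups) {
    stop_params("need at least %d years, got %d", n_groups, length(years))
  }
  if (length(pixels) < n_groups) {
    stop_params("need at least %d pixels, got %d", n_groups, length(pixels))
  }
  balanced <- function(items, sd) {
    with_seed(sd, {
      ord <- sample(seq_along(items))
      g <- integer(length(items))
      g[ord] <- rep(seq_len(n_groups), length.out = length(items))
      stats::setNames(g, as.character(items))
    })
  }
  structure(list(
    year_groups = balanced(years, derive_seed(seed, 11)),
    pixel_groups = balanced(pixels, derive_seed(seed, 12)),
    n_groups = as.integer(n_groups),
    seed = as.integer(seed)
  ), class = "cv_plan")
}

auc_or_na <- function(labels, scores, what) {
  tryCatch(roc_auc(labels, scores), error = function(e) {
    warning(sprintf("%s: AUC undefined (single class); recorded as NA", what),
            call. = FALSE)
    NA_real_
  })
}

#' Run multidimensional spatiotemporal blocked cross-validation
#'
#' For iteration i the model is trained on records whose year is outside
#' temporal group i AND whose pixel is outside spatial group i, then scored
#' by ROC/AUC on three disjoint test cells: `novel_locations` (held-out
#' pixels, training years), `novel_years` (training pixels, held-out years)
#' and `novel_both` (held-out pixels in held-out years). By default the ten
#' temporal and spatial groups are paired (iteration i holds out T_i and
#' S_i); `pairing = "full"` runs all `n_groups^2` combinations. Test cells
#' containing a single class get an NA AUC with a warning.
#'
#' @param records pixel-year records (columns `pixel_id`, `year`, response
#'   and covariates).
#' @param plan a [assign_cv_groups()] plan covering the records.
#' @param term_specs,lambda_rule,... passed to [fit_binomial_gam()].
#' @param pairing `"paired"` (default) or `"full"`.
#' @return Object of class `cv_result`: data.frame with one row per
#'   iteration (`iteration`, `temporal_group`, `spatial_group`, `n_train`,
#'   per-cell AUCs and sizes).
#' @export
run_spatiotemporal_cv <- function(records, plan, term_specs,
                                  lambda_rule = "gcv", pairing = c("paired", "full"),
                                  ...) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(plan, "cv_plan"))
  yg <- plan$year_groups[as.character(records$year)]
  pg <- plan$pixel_groups[as.character(records$pixel_id)]
  if (anyNA(yg) || anyNA(pg)) {
    stop_params("plan does not cover all record years/pixels")
  }
  combos <- if (pairing == "paired") {
    data.frame(t = seq_len(plan$n_groups), s = seq_len(plan$n_groups))
  } else {
    expand.grid(t = seq_len(plan$n_groups), s = seq_len(plan$n_groups))
  }
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ti <- combos$t[i]; si <- combos$s[i]
    in_t <- yg == ti
    in_s <- pg == si
    train <- records[!in_t & !in_s, , drop = FALSE]
    if (length(unique(train[["burned"]])) < 2) {
      warning(sprintf(
        "iteration %d: single-class training fold; AUCs recorded as NA", i),
        call. = FALSE)
      rows[[i]] <- data.frame(
        iteration = i, temporal_group = ti, spatial_group = si,
        n_train = nrow(train),
        auc_novel_locations = NA_real_, n_novel_locations = sum(in_s & !in_t),
        auc_novel_years = NA_real_, n_novel_years = sum(!in_s & in_t),
        auc_novel_both = NA_real_, n_novel_both = sum(in_s & in_t)
      )
      next
    }
    fit <- fit_binomial_gam(train, term_specs, lambda_rule = lambda_rule, ...)
    score_cell <- function(sel, what) {
      cell <- records[sel, , drop = FALSE]
      if (nrow(cell) == 0) return(c(NA_real_, 0))
      p <- predict_probability(fit, cell)
      c(auc_or_na(cell[[fit$response]], p, what), nrow(cell))
    }
    nl <- score_cell(in_s & !in_t, sprintf("iteration %d novel_locations", i))
    ny <- score_cell(!in_s & in_t, sprintf("iteration %d novel_years", i))
    nb <- score_cell(in_s & in_t, sprintf("iteration %d novel_both", i))
    rows[[i]] <- data.frame(
      iteration = i, temporal_group = ti, spatial_group = si,
      n_train = nrow(train),
      auc_novel_locations = nl[1], n_novel_locations = nl[2],
      auc_novel_years = ny[1], n_novel_years = ny[2],
      auc_novel_both = nb[1], n_novel_both = nb[2]
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarize a cross-validation result
#'
#' Mean AUC per novelty type, with NA iterations dropped and their counts
#' reported.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with columns `novelty`, `mean_auc`, `n_iterations`,
#'   `n_missing`.
#' @export
summary.cv_result <- function(object, ...) {
  cols <- c(novel_locations = "auc_novel_locations",
            novel_years = "auc_novel_years",
            novel_both = "auc_novel_both")
  out <- do.call(rbind, lapply(names(cols), function(nm) {
    v <- object[[cols[[nm]]]]
    data.frame(novelty = nm, mean_auc = mean(v, na.rm = TRUE),
               n_iterations = sum(!is.na(v)), n_missing = sum(is.na(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Regional spatiotemporal cross-validation
#'
#' Runs an independent spatiotemporal CV inside each region: training and
#' testing data are restricted to the region's pixels before spatial groups
#' are (re)assigned within it; the temporal grouping is shared across
#' regions so folds are matched. Regions whose records contain a single
#' class (too few observed fires) are skipped with a logged reason.
#'
#' @param records pixel-year records.
#' @param region_ids data.frame with columns `pixel_id`, `region`.
#' @param plan a `cv_plan` (its temporal groups are reused; spatial groups
#'   are re-drawn within each region from the plan's seed).
#' @param term_specs,lambda_rule,... passed to [fit_binomial_gam()].
#' @return Named list of `cv_result`s, one per evaluated region, with a
#'   `skipped` attribute naming regions left out and why.
#' @export
run_regional_cv <- function(records, region_ids, plan, term_specs,
                            lambda_rule = "gcv", ...) {
  stopifnot(all(c("pixel_id", "region") %in% names(region_ids)))
  reg_of <- stats::setNames(region_ids$region,
                            as.character(region_ids$pixel_id))
  rec_region <- reg_of[as.character(records$pixel_id)]
  if (anyNA(rec_region)) stop_params("region_ids does not cover all record pixels")
  regions <- sort(unique(region_ids$region))
  if (length(regions) < 1) stop_params("need at least 1 region")
  results <- list()
  skipped <- character()
  for (k in seq_along(regions)) {
    r <- regions[k]
    sub <- records[rec_region == r, , drop = FALSE]
    if (length(unique(sub[["burned"]])) < 2) {
      skipped <- c(skipped, sprintf(
        "region %s: insufficient fires observed (single class)", r))
      message(sprintf("skipping region %s: insufficient fires observed", r))
      next
    }
    # a region spanning the whole plan reuses it verbatim, so a one-region
    # landscape reproduces the statewide CV exactly
    if (setequal(unique(sub$pixel_id), names(plan$pixel_groups)) ||
        setequal(as.character(unique(sub$pixel_id)),
                 names(plan$pixel_groups))) {
      rplan <- plan
    } else {
      rplan <- tryCatch(
        assign_cv_groups(unique(sub$year), unique(sub$pixel_id),
                         n_groups = plan$n_groups,
                         seed = derive_seed(plan$seed, 1000 + k)),
        error = function(e) NULL
      )
      if (is.null(rplan)) {
        skipped <- c(skipped, sprintf("region %s: too few pixels or years", r))
        message(sprintf("skipping region %s: too few pixels or years", r))
        next
      }
      rplan$year_groups <- plan$year_groups[names(rplan$year_groups)]
    }
    results[[as.character(r)]] <- run_spatiotemporal_cv(
      sub, rplan, term_specs, lambda_rule = lambda_rule, ...)
  }
  attr(results, "skipped") <- skipped
  results
}

#' Leave-one-region-out evaluation
#'
#' For each region, trains on all other regions' records and scores ROC/AUC
#' on the held-out region — model performance in a region entirely novel to
#' training.
#'
#' @param records pixel-year records.
#' @param region_ids data.frame with columns `pixel_id`, `region`.
#' @param term_specs,lambda_rule,... passed to [fit_binomial_gam()].
#' @return data.frame with columns `region`, `auc`, `n_train`, `n_test`.
#' @export
run_leave_one_region_out <- function(records, region_ids, term_specs,
                                     lambda_rule = "gcv", ...) {
  stopifnot(all(c("pixel_id", "region") %in% names(region_ids)))
  reg_of <- stats::setNames(region_ids$region,
                            as.character(region_ids$pixel_id))
  rec_region <- reg_of[as.character(records$pixel_id)]
  regions <- sort(unique(region_ids$region))
  if (length(regions) < 2) stop_params("need at least 2 regions")
  rows <- lapply(regions, function(r) {
    train <- records[rec_region != r, , drop = FALSE]
    test <- records[rec_region == r, , drop = FALSE]
    if (length(unique(train[["burned"]])) < 2) {
      warning(sprintf(
        "region %s: single-class training data; AUC recorded as NA", r),
        call. = FALSE)
      return(data.frame(region = r, auc = NA_real_,
                        n_train = nrow(train), n_test = nrow(test)))
    }
    fit <- fit_binomial_gam(train, term_specs, lambda_rule = lambda_rule, ...)
    p <- predict_probability(fit, test)
    data.frame(region = r,
               auc = auc_or_na(test[[fit$response]], p,
                               sprintf("held-out region %s", r)),
               n_train = nrow(train), n_test = nrow(test))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test on per-iteration AUC scores
#'
#' Two-sided paired t-test on the per-iteration differences between two
#' matched AUC vectors (e.g. statewide vs regional models on matched folds).
#' Zero-variance differences are flagged as degenerate: identical vectors
#' give t = 0, p = 1; constant nonzero differences give an infinite
#' statistic.
#'
#' @param auc_a,auc_b equal-length paired vectors (n >= 2 after NA removal).
#' @return List with `t`, `p_value`, `df`, `mean_difference`, `degenerate`.
#' @export
paired_ttest <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b)) {
    stop_params("paired vectors must have equal length")
  }
  ok <- !is.na(auc_a) & !is.na(auc_b)
  a <- auc_a[ok]; b <- auc_b[ok]
  if (length(a) < 2) stop_params("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p_value = 1, df = length(d) - 1,
                  mean_difference = 0, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = length(d) - 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}
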