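# Binomial additive model with penalized cubic regression splines, fitted by
# penalized iteratively reweighted least squares (P-IRLS) with GCV
# smoothness selection.

#' Smooth and linear term specifications
#'
#' `smooth_terms()` builds penalized cubic-regression-spline term specs (one
#' per covariate, basis dimension `basis_dim`); `linear_terms()` builds
#' unpenalized single-column linear terms (mainly useful for oracle checks
#' against plain logistic regression).
#'
#' @param covariates character vector of covariate names.
#' @param basis_dim spline basis dimension per term (>= 3, default 5: at most
#'   five smoothing terms per parameter).
#' @return List of term specs (name, basis_dim, type).
#' @export
smooth_terms <- function(covariates, basis_dim = 5) {
  if (basis_dim < 3) {
    stop_params("basis_dim must be >= 3 for a cubic regression spline, got %d",
                basis_dim)
  }
  lapply(covariates, function(nm) list(name = nm, basis_dim = as.integer(basis_dim),
                                       type = "smooth"))
}

#' @rdname smooth_terms
#' @export
linear_terms <- function(covariates) {
  lapply(covariates, function(nm) list(name = nm, basis_dim = 1L,
                                       type = "linear"))
}

# Binomial deviance with clamped probabilities.
binomial_deviance <- function(y, mu) {
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# One P-IRLS fit at fixed per-term lambdas.  Returns coefficients, EDFs,
# deviance, GCV and the penalized-deviance trace.
pirls_fit <- function(Xm, y, S_blocks, col_idx, lambdas,
                      epsilon = 1e-8, maxit = 200, beta_init = NULL) {
  n <- length(y)
  p <- ncol(Xm)
  S_lam <- matrix(0, p, p)
  for (j in seq_along(S_blocks)) {
    if (!is.null(S_blocks[[j]])) {
      S_lam[col_idx[[j]], col_idx[[j]]] <-
        S_lam[col_idx[[j]], col_idx[[j]]] + lambdas[j] * S_blocks[[j]]
    }
  }
  beta <- if (is.null(beta_init)) {
    b <- numeric(p)
    pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
    b[1] <- stats::qlogis(pbar)
    b
  } else beta_init
  pen <- function(b) as.numeric(t(b) %*% S_lam %*% b)
  eta <- as.vector(Xm %*% beta)
  mu <- stats::plogis(eta)
  pdev <- binomial_deviance(y, mu) + pen(beta)
  trace <- pdev
  converged <- FALSE
  iter <- 0L
  XtWX <- NULL
  for (it in seq_len(maxit)) {
    iter <- it
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xs <- Xm * sw
    XtWX <- crossprod(Xs)
    XtWz <- crossprod(Xm, w * z)
    H <- XtWX + S_lam
    beta_new <- tryCatch(
      solve(H, XtWz),
      error = function(e) solve(H + diag(1e-10 * max(diag(H)), p), XtWz)
    )
    # step halving guarantees the penalized deviance never increases
    step <- 1
    repeat {
      b_try <- beta + step * (beta_new - beta)
      eta_try <- as.vector(Xm %*% b_try)
      mu_try <- stats::plogis(eta_try)
      pdev_try <- binomial_deviance(y, mu_try) + pen(b_try)
      if (pdev_try <= pdev + 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    beta <- as.vector(b_try)
    eta <- eta_try
    mu <- mu_try
    delta <- pdev - pdev_try
    pdev <- pdev_try
    trace <- c(trace, pdev)
    if (abs(delta) < epsilon * (abs(pdev) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  # influence matrix F = (X'WX + S)^-1 X'WX evaluated at convergence
  w <- pmax(mu * (1 - mu), 1e-10)
  Xs <- Xm * sqrt(w)
  XtWX <- crossprod(Xs)
  H <- XtWX + S_lam
  Hi <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-10 * max(diag(H)), p)))
  Fm <- Hi %*% XtWX
  edf <- diag(Fm)
  dev <- binomial_deviance(y, mu)
  total_edf <- sum(edf)
  list(beta = beta, eta = eta, mu = mu, deviance = dev,
       penalized_deviance = pdev, edf = edf, total_edf = total_edf,
       gcv = n * dev / (n - total_edf)^2, Vp = Hi,
       converged = converged, iterations = iter, trace = trace,
       influence_trace = sum(diag(Fm)))
}

#' Fit a binomial GAM with penalized cubic regression splines
#'
#' Maximizes the Bernoulli log-likelihood minus the curvature penalties
#' `sum_j lambda_j b_j' S_j b_j` by penalized IRLS (with step halving, so the
#' penalized deviance is non-increasing across iterations; convergence when
#' the penalized-deviance change falls below `epsilon`, relative, or after
#' `maxit` iterations). The smoothing parameter is chosen by generalized
#' cross-validation over a log-spaced grid shared across terms
#' (`lambda_rule = "gcv"`, the default), or fixed by passing a single number
#' (shared) or one number per term. Each term's effective degrees of freedom
#' (EDF) is the trace of its block of the influence matrix.
#'
#' @param records data.frame of pixel-year records (or any data.frame)
#'   containing `response` and every term covariate; both classes must be
#'   present.
#' @param term_specs list of term specs from [smooth_terms()] /
#'   [linear_terms()]; an empty list fits an intercept-only model.
#' @param lambda_rule `"gcv"`, or a numeric smoothing parameter (length 1 or
#'   one per term).
#' @param response name of the 0/1 response column (default `"burned"`).
#' @param gcv_grid candidate smoothing parameters for the GCV search.
#' @param epsilon,maxit P-IRLS convergence tolerance and iteration cap.
#' @return Object of class `fire_gam`: intercept, per-term bases,
#'   coefficients, penalties, smoothing parameters and EDFs, coefficient
#'   covariance `Vp`, training covariate summaries (mean, min, max), fitted
#'   values, deviance, GCV table and convergence diagnostics.
#' @export
fit_binomial_gam <- function(records, term_specs = list(),
                             lambda_rule = "gcv", response = "burned",
                             gcv_grid = 10^seq(-3, 7, length.out = 11),
                             epsilon = 1e-8, maxit = 200) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_params("records must be a nonempty data.frame")
  }
  if (!response %in% names(records)) {
    stop_params("response column '%s' not found", response)
  }
  y <- as.numeric(records[[response]])
  if (length(unique(y)) < 2) {
    stop_params("response has a single class; cannot fit a binomial model")
  }
  n <- length(y)

  terms <- list()
  Xm <- matrix(1, n, 1)
  col_idx <- list()
  S_blocks <- list()
  for (j in seq_along(term_specs)) {
    sp <- term_specs[[j]]
    if (!sp$name %in% names(records)) {
      stop_params("covariate '%s' not found in records", sp$name)
    }
    x <- as.numeric(records[[sp$name]])
    n_unique <- length(unique(x))
    if (!identical(sp$type, "linear") && n_unique < sp$basis_dim) {
      # not enough distinct values to place the requested knots: shrink the
      # basis, or fall back to a linear term
      if (n_unique >= 3) {
        warning(sprintf("'%s' has %d unique values; basis_dim reduced to %d",
                        sp$name, n_unique, n_unique), call. = FALSE)
        sp$basis_dim <- n_unique
      } else {
        warning(sprintf("'%s' has %d unique values; using a linear term",
                        sp$name, n_unique), call. = FALSE)
        sp$type <- "linear"
      }
    }
    if (identical(sp$type, "linear")) {
      block <- matrix(x, ncol = 1)
      basis <- NULL
      S <- matrix(0, 1, 1)
    } else {
      basis <- build_spline_basis(x, sp$basis_dim)
      block <- basis$X
      S <- basis$S
    }
    idx <- ncol(Xm) + seq_len(ncol(block))
    Xm <- cbind(Xm, block)
    col_idx[[j]] <- idx
    S_blocks[[j]] <- S
    terms[[j]] <- list(name = sp$name, type = sp$type,
                       basis = if (is.null(basis)) NULL else
                         basis[c("knots", "Z", "S", "range", "basis_dim")],
                       train_range = range(x), col_idx = idx)
  }
  names(terms) <- vapply(term_specs, `[[`, "", "name")

  n_terms <- length(term_specs)
  has_penalty <- n_terms > 0 &&
    any(vapply(term_specs, function(s) !identical(s$type, "linear"), TRUE))

  gcv_table <- NULL
  if (n_terms == 0 || !has_penalty) {
    lambdas <- rep(0, max(n_terms, 1))
    fit <- pirls_fit(Xm, y, S_blocks, col_idx, lambdas[seq_len(n_terms)],
                     epsilon, maxit)
  } else if (is.numeric(lambda_rule)) {
    lambdas <- if (length(lambda_rule) == 1) rep(lambda_rule, n_terms)
               else if (length(lambda_rule) == n_terms) lambda_rule
               else stop_params("lambda_rule must have length 1 or %d", n_terms)
    fit <- pirls_fit(Xm, y, S_blocks, col_idx, lambdas, epsilon, maxit)
  } else if (identical(lambda_rule, "gcv")) {
    best <- NULL
    gcv_table <- data.frame(lambda = gcv_grid, gcv = NA_real_,
                            edf = NA_real_)
    beta_ws <- NULL
    for (i in seq_along(gcv_grid)) {
      f <- pirls_fit(Xm, y, S_blocks, col_idx, rep(gcv_grid[i], n_terms),
                     epsilon, maxit, beta_init = beta_ws)
      beta_ws <- f$beta
      gcv_table$gcv[i] <- f$gcv
      gcv_table$edf[i] <- f$total_edf
      if (is.null(best) || f$gcv < best$gcv) {
        best <- f
        best_lambda <- gcv_grid[i]
      }
    }
    fit <- best
    lambdas <- rep(best_lambda, n_terms)
  } else {
    stop_params("unknown lambda_rule")
  }

  # perfect-separation guard: an unpenalized fit that drives the deviance to
  # zero has diverging coefficients; refit with a small ridge
  if (!has_penalty && n_terms > 0 &&
      (fit$deviance < 1e-6 || max(abs(fit$beta)) > 1e3)) {
    warning("possible perfect separation; refitting with a small ridge",
            call. = FALSE)
    S_blocks <- lapply(col_idx, function(idx) diag(1e-6, length(idx)))
    fit <- pirls_fit(Xm, y, S_blocks, col_idx, rep(1, n_terms),
                     epsilon, maxit)
  }

  for (j in seq_len(n_terms)) {
    terms[[j]]$coef <- fit$beta[col_idx[[j]]]
    terms[[j]]$lambda <- lambdas[j]
    terms[[j]]$edf <- sum(fit$edf[col_idx[[j]]])
  }

  cov_names <- vapply(term_specs, `[[`, "", "name")
  train_summary <- if (n_terms > 0) {
    data.frame(
      covariate = cov_names,
      mean = vapply(cov_names, function(nm) mean(records[[nm]]), 0),
      min = vapply(cov_names, function(nm) min(records[[nm]]), 0),
      max = vapply(cov_names, function(nm) max(records[[nm]]), 0),
      row.names = NULL
    )
  } else {
    data.frame(covariate = character(), mean = numeric(),
               min = numeric(), max = numeric())
  }

  structure(list(
    intercept = fit$beta[1],
    coefficients = fit$beta,
    terms = terms,
    Vp = fit$Vp,
    fitted = fit$mu,
    deviance = fit$deviance,
    null_deviance = binomial_deviance(y, rep(mean(y), n)),
    penalized_deviance_trace = fit$trace,
    edf_by_coef = fit$edf,
    total_edf = fit$total_edf,
    influence_trace = fit$influence_trace,
    gcv = fit$gcv,
    gcv_table = gcv_table,
    n_train = n,
    response = response,
    converged = fit$converged,
    iterations = fit$iterations,
    train_summary = train_summary
  ), class = "fire_gam")
}

#' @export
print.fire_gam <- function(x, ...) {
  cat(sprintf("Binomial GAM (penalized cubic regression splines), n = %d\n",
              x$n_train))
  cat(sprintf("  intercept %.4f; deviance %.2f (null %.2f); total EDF %.2f\n",
              x$intercept, x$deviance, x$null_deviance, x$total_edf))
  if (length(x$terms)) {
    cat("  terms:\n")
    for (tm in x$terms) {
      cat(sprintf("    s(%s): EDF %.3f, lambda %.3g\n", tm$name, tm$edf,
                  tm$lambda))
    }
  }
  invisible(x)
}

#' Summarize a fitted fire-probability GAM
#'
#' Reports the intercept and, per smooth term, the effective degrees of
#' freedom, reference degrees of freedom (the centered basis dimension), an
#' approximate Wald chi-squared statistic on the term's coefficients, and its
#' approximate p-value (reference df = rounded EDF, at least 1). The Wald
#' test is labelled approximate: it conditions on the selected smoothing
#' parameters.
#'
#' @param object a `fire_gam`.
#' @param ... unused.
#' @return data.frame with one row per term.
#' @export
summary.fire_gam <- function(object, ...) {
  if (!length(object$terms)) {
    return(data.frame(term = "(intercept)", edf = 1, ref_df = 1,
                      chi_sq = NA_real_, p_value = NA_real_))
  }
  rows <- lapply(object$terms, function(tm) {
    idx <- tm$col_idx
    V <- object$Vp[idx, idx, drop = FALSE]
    b <- object$coefficients[idx]
    chi <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    df <- max(1, round(tm$edf))
    data.frame(term = tm$name, edf = tm$edf, ref_df = length(idx),
               chi_sq = chi,
               p_value = if (is.na(chi)) NA_real_ else
                 stats::pchisq(chi, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "intercept") <- object$intercept
  attr(out, "note") <- "term chi-squared tests are approximate (Wald, EDF-based df)"
  out
}

# Linear predictor for new records.
gam_linear_predictor <- function(model, records) {
  miss <- setdiff(names(model$terms), names(records))
  if (length(miss)) {
    stop_params("missing covariate%s in records: %s",
                if (length(miss) > 1) "s" else "", paste(miss, collapse = ", "))
  }
  eta <- rep(model$intercept, nrow(records))
  for (tm in model$terms) {
    x <- as.numeric(records[[tm$name]])
    if (identical(tm$type, "linear")) {
      x <- pmin(pmax(x, tm$train_range[1]), tm$train_range[2])
      eta <- eta + x * tm$coef
    } else {
      basis <- structure(tm$basis, class = "crs_basis")
      Xn <- eval_spline_basis(basis, x)
      eta <- eta + as.vector(Xn %*% tm$coef)
    }
  }
  eta
}

#' Predict annual fire probability
#'
#' `plogis(intercept + sum_j s_j(x_j))` for each record. Covariates beyond
#' the training range are clamped to it (conservative behavior for
#' prediction in novel regions or years).
#'
#' @param model a fitted `fire_gam`.
#' @param records data.frame carrying all model covariates.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, records) {
  stopifnot(inherits(model, "fire_gam"))
  stats::plogis(gam_linear_predictor(model, records))
}

#' @export
predict.fire_gam <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- gam_linear_predictor(object, newdata)
  if (type == "response") stats::plogis(eta) else eta
}

#' Partial effect curve of a smooth term
#'
#' The centered smooth contribution of one term on the log-odds scale over a
#' grid of covariate values, with a pointwise standard-error band from the
#' coefficient covariance. The curve sums to approximately zero over the
#' training values (centering constraint). Grid values outside the training
#' span are evaluated under the clamping rule and flagged.
#'
#' @param model a fitted `fire_gam`.
#' @param term covariate name of a model term.
#' @param x_grid grid of covariate values (default: 200 points over the
#'   training range).
#' @return data.frame with columns `x`, `fit`, `se`, `clamped`.
#' @export
partial_effect <- function(model, term, x_grid = NULL) {
  stopifnot(inherits(model, "fire_gam"))
  tm <- model$terms[[term]]
  if (is.null(tm)) stop_params("term '%s' is not in the model", term)
  if (is.null(x_grid)) {
    x_grid <- seq(tm$train_range[1], tm$train_range[2], length.out = 200)
  }
  if (identical(tm$type, "linear")) {
    xc <- pmin(pmax(x_grid, tm$train_range[1]), tm$train_range[2])
    V <- model$Vp[tm$col_idx, tm$col_idx, drop = FALSE]
    return(data.frame(x = x_grid, fit = xc * tm$coef,
                      se = abs(xc) * sqrt(as.numeric(V)),
                      clamped = x_grid < tm$train_range[1] |
                        x_grid > tm$train_range[2]))
  }
  basis <- structure(tm$basis, class = "crs_basis")
  Xg <- eval_spline_basis(basis, x_grid)
  V <- model$Vp[tm$col_idx, tm$col_idx, drop = FALSE]
  data.frame(
    x = x_grid,
    fit = as.vector(Xg %*% tm$coef),
    se = sqrt(pmax(rowSums((Xg %*% V) * Xg), 0)),
    clamped = attr(Xg, "clamped")
  )
}

#' Map a smooth term's contribution over a covariate raster
#'
#' Evaluates one term's partial effect (log-odds contribution) at each cell
#' of a covariate raster; masked (NA) cells stay masked.
#'
#' @param model a fitted `fire_gam`.
#' @param term covariate name of a model term.
#' @param covariate_raster numeric matrix of covariate values.
#' @return Numeric matrix of log-odds contributions.
#' @export
coefficient_surface <- function(model, term, covariate_raster) {
  out <- covariate_raster
  valid <- !is.na(covariate_raster)
  if (any(valid)) {
    pe <- partial_effect(model, term, x_grid = covariate_raster[valid])
    out[valid] <- pe$fit
  }
  out
}

#' Leave-one-year-out model fits
#'
#' Fits one GAM per year of interest, each trained on all records except
#' those of that year (so predictions for a year never use that year's
#' outcomes), alongside the plain pooled fit provided by
#' [fit_binomial_gam()].
#'
#' @param records pixel-year records with a `year` column.
#' @param term_specs,lambda_rule,... passed to [fit_binomial_gam()].
#' @param years years of interest (default: all years present).
#' @return Named list of `fire_gam` fits, one per year.
#' @export
fit_annual_gams <- function(records, term_specs, years = NULL,
                            lambda_rule = "gcv", ...) {
  if (is.null(years)) years <- sort(unique(records$year))
  fits <- lapply(years, function(y) {
    fit_binomial_gam(records[records$year != y, , drop = FALSE],
                     term_specs, lambda_rule = lambda_rule, ...)
  })
  names(fits) <- as.character(years)
  fits
}

#' Serialize / restore a fitted GAM as JSON
#'
#' Writes knot locations, coefficients, penalties, smoothing parameters,
#' EDFs, training summaries and the coefficient covariance to a JSON file;
#' `read_fitted_gam()` restores an equivalent `fire_gam` whose predictions
#' reproduce the original's.
#'
#' @param model a `fire_gam`.
#' @param path output JSON path.
#' @return `write_fitted_gam()` returns `path` invisibly; `read_fitted_gam()`
#'   returns a `fire_gam`.
#' @export
write_fitted_gam <- function(model, path) {
  stopifnot(inherits(model, "fire_gam"))
  terms <- lapply(model$terms, function(tm) {
    list(name = tm$name, type = tm$type,
         knots = if (is.null(tm$basis)) NULL else tm$basis$knots,
         Z = if (is.null(tm$basis)) NULL else tm$basis$Z,
         S = if (is.null(tm$basis)) NULL else tm$basis$S,
         basis_dim = if (is.null(tm$basis)) 1L else tm$basis$basis_dim,
         basis_range = if (is.null(tm$basis)) tm$train_range else tm$basis$range,
         train_range = tm$train_range, col_idx = tm$col_idx,
         coef = tm$coef, lambda = tm$lambda, edf = tm$edf)
  })
  obj <- list(
    package = "pyrogam",
    r_version = as.character(getRversion()),
    intercept = model$intercept,
    coefficients = model$coefficients,
    terms = terms,
    Vp = model$Vp,
    n_train = model$n_train,
    deviance = model$deviance,
    null_deviance = model$null_deviance,
    total_edf = model$total_edf,
    gcv = model$gcv,
    converged = model$converged,
    train_summary = model$train_summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fitted_gam
#' @export
read_fitted_gam <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- lapply(seq_len(if (is.data.frame(obj$terms)) nrow(obj$terms)
                          else length(obj$terms)), function(j) {
    tm <- if (is.data.frame(obj$terms)) lapply(obj$terms, `[[`, j)
          else obj$terms[[j]]
    basis <- if (identical(tm$type, "linear")) NULL else
      list(knots = as.numeric(tm$knots),
           Z = matrix(unlist(tm$Z), nrow = length(tm$knots)),
           S = matrix(unlist(tm$S), nrow = length(tm$knots) - 1),
           range = as.numeric(tm$basis_range),
           basis_dim = as.integer(tm$basis_dim))
    list(name = tm$name, type = tm$type, basis = basis,
         train_range = as.numeric(tm$train_range),
         col_idx = as.integer(unlist(tm$col_idx)),
         coef = as.numeric(unlist(tm$coef)),
         lambda = as.numeric(tm$lambda), edf = as.numeric(tm$edf))
  })
  names(terms) <- vapply(terms, `[[`, "", "name")
  p <- length(obj$coefficients)
  structure(list(
    intercept = obj$intercept,
    coefficients = as.numeric(obj$coefficients),
    terms = terms,
    Vp = matrix(unlist(obj$Vp), nrow = p),
    fitted = NULL,
    deviance = obj$deviance,
    null_deviance = obj$null_deviance,
    total_edf = obj$total_edf,
    gcv = obj$gcv,
    n_train = obj$n_train,
    response = "burned",
    converged = obj$converged,
    train_summary = as.data.frame(obj$train_summary)
  ), class = "fire_gam")
}
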