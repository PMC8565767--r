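test_that("intercept-only fit returns the closed-form MLE", {
  df <- data.frame(burned = rep(c(1, 0), times = c(30, 70)))
  fit <- fit_binomial_gam(df, term_specs = list())
  expect_equal(fit$intercept, qlogis(0.3), tolerance = 1e-8)
  expect_equal(unique(round(fit$fitted, 10)), 0.3)
})

test_that("single-class input errors", {
  expect_error(fit_binomial_gam(data.frame(burned = rep(0, 50)), list()),
               "single class")
})

test_that("unpenalized linear fits match the Newton logistic oracle", {
  for (seed in 1:5) {
    df <- make_logistic_data(400, p = 2, seed = seed)
    fit <- fit_binomial_gam(df, linear_terms(c("x1", "x2")), lambda_rule = 0)
    oracle <- newton_logistic(cbind(1, df$x1, df$x2), df$burned)
    expect_equal(fit$coefficients, oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # and agreement with the standard GLM fitter as a second route
    gl <- glm(burned ~ x1 + x2, binomial, df)
    expect_equal(fit$coefficients, unname(coef(gl)), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("infinite smoothing degenerates each term to its penalty null space", {
  set.seed(31)
  n <- 800
  df <- data.frame(x1 = runif(n, 0, 10))
  df$burned <- rbinom(n, 1, plogis(-1 + 0.5 * sin(df$x1)))
  fit <- fit_binomial_gam(df, smooth_terms("x1", 5), lambda_rule = 1e9)
  pe <- partial_effect(fit, "x1")
  # the curvature penalty's null space (after centering) is straight lines
  line <- lm(fit ~ x, data = pe)
  expect_lt(max(abs(resid(line))), 1e-4 * max(1, diff(range(pe$fit))))
  expect_lt(fit$terms$x1$edf, 1.05)
})

test_that("the training mean probability matches the positive fraction", {
  set.seed(32)
  n <- 1500
  df <- data.frame(x1 = runif(n), x2 = rnorm(n))
  df$burned <- rbinom(n, 1, plogis(-2 + 2 * df$x1))
  fit <- fit_binomial_gam(df, smooth_terms(c("x1", "x2"), 5),
                          lambda_rule = 1)
  expect_equal(mean(fit$fitted), mean(df$burned), tolerance = 1e-6)
  # all covariates at training means with centered smooths: approximately
  # the intercept alone
  at_mean <- data.frame(x1 = mean(df$x1), x2 = mean(df$x2))
  expect_lt(abs(predict_probability(fit, at_mean) - plogis(fit$intercept)),
            0.05)
})

test_that("penalized deviance is non-increasing across P-IRLS iterations", {
  set.seed(33)
  df <- make_logistic_data(600, p = 2, seed = 33)
  fit <- fit_binomial_gam(df, smooth_terms(c("x1", "x2"), 5),
                          lambda_rule = 0.1)
  tr <- fit$penalized_deviance_trace
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("term EDFs plus the intercept add up to the influence-matrix trace", {
  set.seed(34)
  df <- make_logistic_data(800, p = 3, seed = 34)
  fit <- fit_binomial_gam(df, smooth_terms(c("x1", "x2", "x3"), 5),
                          lambda_rule = 2)
  term_edf <- sum(vapply(fit$terms, `[[`, 0, "edf"))
  expect_equal(term_edf + fit$edf_by_coef[1], fit$influence_trace,
               tolerance = 1e-8)
  for (tm in fit$terms) {
    expect_gt(tm$edf, 0)
    expect_lte(tm$edf, 5)
  }
})

test_that("stored fields alone reproduce the stored fitted values", {
  set.seed(35)
  df <- make_logistic_data(500, p = 2, seed = 35)
  fit <- fit_binomial_gam(df, smooth_terms(c("x1", "x2"), 5))
  expect_equal(predict_probability(fit, df), fit$fitted, tolerance = 1e-10)
  # JSON round trip preserves predictions
  path <- tempfile(fileext = ".json")
  write_fitted_gam(fit, path)
  back <- read_fitted_gam(path)
  expect_equal(predict_probability(back, df), fit$fitted, tolerance = 1e-8)
})

test_that("a smooth truth is recovered and predictions follow its gradient", {
  set.seed(36)
  n <- 6000
  truth <- function(x) 1.3 * exp(-((x - 5) / 2)^2)
  df <- data.frame(x1 = runif(n, 0, 10), x2 = rnorm(n))
  df$burned <- rbinom(n, 1, plogis(-2.5 + truth(df$x1)))
  fit <- fit_binomial_gam(df, smooth_terms(c("x1", "x2"), 5))
  pe <- partial_effect(fit, "x1")
  expect_gt(cor(pe$fit, truth(pe$x)), 0.95)
  # argmax within the central 20% of the grid around the true peak
  expect_lt(abs(pe$x[which.max(pe$fit)] - 5), 1)
  # centering: the curve sums to ~0 over the training covariate
  at_train <- partial_effect(fit, "x1", x_grid = df$x1)
  expect_lt(abs(sum(at_train$fit)), 1e-6 * n)
  # standard errors are positive and finite
  expect_true(all(pe$se > 0 & is.finite(pe$se)))
  # monotone section: predictions increase along the rising limb (away
  # from the data-sparse boundary, where the spline may wiggle slightly)
  grid <- data.frame(x1 = seq(2, 5, length.out = 20), x2 = 0)
  expect_true(all(diff(predict_probability(fit, grid)) > 0))
})

test_that("predictions agree with an independent GAM implementation", {
  set.seed(37)
  n <- 3000
  df <- data.frame(x1 = runif(n, 0, 10))
  df$burned <- rbinom(n, 1, plogis(-2 + sin(df$x1 / 1.6)))
  fit <- fit_binomial_gam(df, smooth_terms("x1", 5))
  mg <- mgcv::gam(burned ~ s(x1, k = 5, bs = "cr"), binomial, data = df)
  expect_gt(cor(fit$fitted, fitted(mg)), 0.99)
  expect_lt(mean(abs(fit$fitted - fitted(mg))), 0.01)
})

test_that("prediction clamps covariates outside the training range", {
  set.seed(38)
  df <- make_logistic_data(500, p = 1, seed = 38)
  fit <- fit_binomial_gam(df, smooth_terms("x1", 4))
  lo <- data.frame(x1 = min(df$x1) - 100)
  at_lo <- data.frame(x1 = min(df$x1))
  expect_equal(predict_probability(fit, lo), predict_probability(fit, at_lo))
  expect_error(predict_probability(fit, data.frame(z = 1)), "x1")
})

test_that("missing covariates and unknown terms are reported by name", {
  df <- make_logistic_data(200, p = 1, seed = 39)
  expect_error(fit_binomial_gam(df, smooth_terms("nope", 4)), "nope")
  fit <- fit_binomial_gam(df, smooth_terms("x1", 4))
  expect_error(partial_effect(fit, "nope"), "nope")
})

test_that("coefficient surfaces agree pointwise with the partial-effect curve", {
  set.seed(40)
  df <- make_logistic_data(800, p = 1, seed = 40)
  fit <- fit_binomial_gam(df, smooth_terms("x1", 5))
  r <- matrix(runif(100, min(df$x1), max(df$x1)), 10, 10)
  r[3, 4] <- NA
  surf <- coefficient_surface(fit, "x1", r)
  expect_true(is.na(surf[3, 4]))
  idx <- which(!is.na(r))
  pe <- partial_effect(fit, "x1", x_grid = r[idx])
  expect_equal(surf[idx], pe$fit, tolerance = 1e-12)
  # constant raster: constant surface at that partial-effect value
  const <- coefficient_surface(fit, "x1", matrix(1, 3, 3))
  expect_equal(unique(as.vector(const)),
               partial_effect(fit, "x1", x_grid = 1)$fit)
})

test_that("leave-one-year-out fits exclude the year under prediction", {
  study <- make_small_study(seed = 41, n = 16, years = 12)
  tab <- study$table
  yrs <- sort(unique(tab$year))[1:3]
  fits <- fit_annual_gams(tab, smooth_terms("aet_normal", 4),
                          years = yrs, lambda_rule = 1)
  for (y in yrs) {
    expect_equal(fits[[as.character(y)]]$n_train, sum(tab$year != y))
  }
})

test_that("GCV selects against both extremes on a wiggly truth", {
  set.seed(42)
  n <- 4000
  df <- data.frame(x1 = runif(n, 0, 10))
  df$burned <- rbinom(n, 1, plogis(-1.5 + 1.2 * sin(df$x1)))
  fit <- fit_binomial_gam(df, smooth_terms("x1", 5))
  # the selected fit is at least as good (by GCV) as every grid candidate
  expect_lte(fit$gcv, min(fit$gcv_table$gcv) + 1e-12)
  expect_gt(fit$terms$x1$edf, 1.5)
})
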