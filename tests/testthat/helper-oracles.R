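# Independent oracles and small fixture builders used across the suite.

# Unpenalized logistic regression by Newton-Raphson, written from first
# principles as an oracle for the P-IRLS fitter.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- crossprod(X, y - mu)
    H <- crossprod(X * w, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

# Brute-force AUC over all positive-negative pairs (ties count one half).
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Random logistic-regression dataset with linear effects.
make_logistic_data <- function(n, p = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p, sd = 0.8)
  eta <- -1 + X %*% beta
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  df <- as.data.frame(X)
  df$burned <- y
  df
}

# Small synthetic landscape + history + design table, for CV/decomposition
# tests.  Higher intercept than the statewide default so that held-out folds
# at these small grid sizes keep both classes represented.
make_small_study <- function(seed = 1, n = 32, years = 20, effects = NULL,
                             intercept = -3.2, regions = 4) {
  y0 <- 1981
  if (is.null(effects)) {
    effects <- default_true_effects()[c("aet_normal", "cwd_normal",
                                        "years_since_fire")]
  }
  cfg <- synthetic_config(
    n_rows = n, n_cols = n, year_start = y0, year_end = y0 + years - 1,
    normal_base_period = c(y0, y0 + min(15, years - 1)),
    true_effects = effects, true_intercept = intercept,
    region_layout = regions, seed = seed
  )
  panel <- generate_landscape(cfg)
  history <- simulate_fire_history(panel, seed = seed + 500)
  table <- build_design_table(panel, history, years = (y0 + 3):(y0 + years - 1))
  list(cfg = cfg, panel = panel, history = history, table = table)
}

# Region lookup for a panel's pixels.
panel_regions <- function(panel, pixel_ids) {
  rc <- pixel_rc(pixel_ids, panel$grid$n_cols)
  data.frame(pixel_id = pixel_ids,
             region = panel$static$region_id[cbind(rc$row, rc$col)])
}
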