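test_that("AUC matches brute-force pairwise enumeration", {
  # worked case: 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")
  # randomized instances against the oracle, including ties
  set.seed(50)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(labels, scores), brute_auc(labels, scores))
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(51)
  labels <- rbinom(60, 1, 0.3)
  labels[1:2] <- c(0, 1)
  scores <- runif(60)
  base <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, qlogis(scores)), base)
  expect_equal(roc_auc(labels, 100 * scores - 3), base)
  expect_equal(roc_auc(labels, exp(scores)), base)
})

test_that("CV groups partition both axes into near-equal groups", {
  plan <- assign_cv_groups(1961:2000, 1:137, n_groups = 10, seed = 5)
  expect_equal(unname(table(plan$year_groups)), rep(4L, 10),
               ignore_attr = TRUE)
  sz <- table(plan$pixel_groups)
  expect_lte(max(sz) - min(sz), 1)
  expect_setequal(names(plan$year_groups), as.character(1961:2000))
  plan2 <- assign_cv_groups(1961:2000, 1:137, n_groups = 10, seed = 5)
  expect_identical(plan, plan2)
  expect_error(assign_cv_groups(1:5, 1:100, n_groups = 10), "years")
})

test_that("spatiotemporal CV never leaks test records into training", {
  study <- make_small_study(seed = 52, n = 16, years = 14)
  tab <- study$table
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 5, seed = 3)
  cv <- run_spatiotemporal_cv(tab, plan, smooth_terms("aet_normal", 4),
                              lambda_rule = 1)
  expect_equal(nrow(cv), 5)
  for (i in 1:5) {
    yg <- plan$year_groups[as.character(tab$year)]
    pg <- plan$pixel_groups[as.character(tab$pixel_id)]
    train_keys <- paste(tab$pixel_id, tab$year)[yg != i & pg != i]
    test_keys <- paste(tab$pixel_id, tab$year)[yg == i | pg == i]
    expect_length(intersect(train_keys, test_keys), 0)
    expect_equal(cv$n_train[i], sum(yg != i & pg != i))
    # the three test cells are disjoint and cover the held-out records
    expect_equal(cv$n_novel_locations[i] + cv$n_novel_years[i] +
                   cv$n_novel_both[i], sum(yg == i | pg == i))
  }
})

test_that("a covariate-driven model beats the intercept-only model on novel folds", {
  study <- make_small_study(seed = 53, n = 24, years = 16)
  tab <- study$table
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 5, seed = 7)
  specs <- smooth_terms(c("aet_normal", "cwd_normal", "years_since_fire"), 5)
  cv_fit <- run_spatiotemporal_cv(tab, plan, specs, lambda_rule = 1)
  cv_null <- run_spatiotemporal_cv(tab, plan, list())
  m_fit <- mean(cv_fit$auc_novel_both, na.rm = TRUE)
  m_null <- mean(cv_null$auc_novel_both, na.rm = TRUE)
  expect_gt(m_fit, m_null)
  expect_gt(m_fit, 0.55)
  # intercept-only scores are constant, so every pair is tied
  expect_true(all(abs(na.omit(cv_null$auc_novel_both) - 0.5) < 1e-12))
})

test_that("permuted labels give chance-level AUC", {
  study <- make_small_study(seed = 54, n = 24, years = 16)
  tab <- study$table
  set.seed(99)
  tab$burned <- sample(tab$burned)
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 5, seed = 11)
  cv <- run_spatiotemporal_cv(tab, plan,
                              smooth_terms(c("aet_normal", "cwd_normal"), 4),
                              lambda_rule = 1)
  auc <- na.omit(cv$auc_novel_both)
  se <- sd(auc) / sqrt(length(auc))
  expect_lt(abs(mean(auc) - 0.5), 3 * max(se, 0.02))
})

test_that("regional CV on a single-region landscape reduces to statewide CV", {
  study <- make_small_study(seed = 55, n = 16, years = 14, regions = 1)
  tab <- study$table
  regions <- panel_regions(study$panel, unique(tab$pixel_id))
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 4, seed = 13)
  rcv <- run_regional_cv(tab, regions, plan,
                         smooth_terms("aet_normal", 4), lambda_rule = 1)
  statewide <- run_spatiotemporal_cv(tab, plan, smooth_terms("aet_normal", 4),
                                     lambda_rule = 1)
  expect_length(rcv, 1)
  expect_equal(as.data.frame(rcv[["1"]]), as.data.frame(statewide))
})

test_that("regions with too few burns are skipped with a logged reason", {
  study <- make_small_study(seed = 56, n = 16, years = 14)
  tab <- study$table
  regions <- panel_regions(study$panel, unique(tab$pixel_id))
  # silence one region's fires entirely
  dead <- regions$pixel_id[regions$region == 1]
  tab$burned[tab$pixel_id %in% dead] <- 0L
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 4, seed = 17)
  expect_message(
    rcv <- run_regional_cv(tab, regions, plan,
                           smooth_terms("aet_normal", 4), lambda_rule = 1),
    "insufficient fires"
  )
  expect_false("1" %in% names(rcv))
  expect_match(attr(rcv, "skipped"), "region 1", all = FALSE)
})

test_that("leave-one-region-out returns one AUC per region without leakage", {
  study <- make_small_study(seed = 57, n = 16, years = 14)
  tab <- study$table
  regions <- panel_regions(study$panel, unique(tab$pixel_id))
  loro <- run_leave_one_region_out(tab, regions,
                                   smooth_terms("aet_normal", 4),
                                   lambda_rule = 1)
  expect_equal(nrow(loro), 4)
  expect_setequal(loro$region, 1:4)
  n_by_region <- table(regions$region)
  years_n <- length(unique(tab$year))
  for (i in seq_len(nrow(loro))) {
    expect_equal(loro$n_test[i],
                 unname(n_by_region[as.character(loro$region[i])]) * years_n)
    expect_equal(loro$n_train[i] + loro$n_test[i], nrow(tab))
  }
})

test_that("identically generated regions score similar held-out and within AUC", {
  # two-region landscape with a homogeneous truth: symmetry implies the
  # held-out-region AUC tracks the within-region novel-both AUC
  study <- make_small_study(seed = 58, n = 24, years = 16, regions = 2)
  tab <- study$table
  regions <- panel_regions(study$panel, unique(tab$pixel_id))
  specs <- smooth_terms(c("aet_normal", "cwd_normal"), 4)
  loro <- run_leave_one_region_out(tab, regions, specs, lambda_rule = 1)
  plan <- assign_cv_groups(unique(tab$year), unique(tab$pixel_id),
                           n_groups = 4, seed = 19)
  rcv <- run_regional_cv(tab, regions, plan, specs, lambda_rule = 1)
  within <- mean(vapply(rcv, function(r) mean(r$auc_novel_both, na.rm = TRUE),
                        0), na.rm = TRUE)
  held_out <- mean(loro$auc, na.rm = TRUE)
  expect_lt(abs(held_out - within), 0.15)
})

test_that("paired t-test handles worked, identical and degenerate cases", {
  # closed form: diffs (0.1, 0.2, 0.3), t = 0.2 / (0.1 / sqrt(3))
  a <- c(0.8, 0.9, 1.0); b <- c(0.7, 0.7, 0.7)
  out <- paired_ttest(a, b)
  expect_equal(out$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(out$p_value, 2 * pt(-out$t, df = 2), tolerance = 1e-10)
  expect_false(out$degenerate)

  same <- paired_ttest(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  flat <- paired_ttest(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(flat$degenerate)
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})
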