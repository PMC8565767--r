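make_series <- function(values_by_year, nr = 2, nc = 2) {
  yrs <- names(values_by_year)
  arr <- array(NA_real_, c(nr, nc, length(yrs)),
               dimnames = list(NULL, NULL, yrs))
  for (y in yrs) arr[, , y] <- values_by_year[[y]]
  arr
}

test_that("climate normal is the base-period mean", {
  s <- make_series(list(`1951` = 100, `1952` = 200, `1953` = 300))
  expect_equal(compute_normal(s, c(1951, 1953)),
               matrix(200, 2, 2))
  s2 <- make_series(list(`1951` = 7, `1952` = 7, `1953` = 7))
  expect_equal(compute_normal(s2, c(1951, 1953)), matrix(7, 2, 2))
  expect_error(compute_normal(s, c(1950, 1953)), "missing")
  expect_error(compute_normal(s, c(1953, 1951)), "first <= last")
})

test_that("three-year deviation uses the preceding years, excluding the year itself", {
  s <- make_series(list(`1977` = 310, `1978` = 320, `1979` = 330,
                        `1980` = 999))
  normal <- matrix(300, 2, 2)
  expect_equal(compute_three_year_deviation(s, normal, 1980),
               matrix(20, 2, 2))
  s0 <- make_series(list(`1977` = 300, `1978` = 300, `1979` = 300,
                         `1980` = 55))
  expect_equal(compute_three_year_deviation(s0, normal, 1980),
               matrix(0, 2, 2))
  expect_error(compute_three_year_deviation(s, normal, 1982), "1982")
})

test_that("deviation is shift-equivariant", {
  set.seed(1)
  vals <- lapply(1:5, function(i) matrix(rnorm(4, 300, 30), 2, 2))
  names(vals) <- as.character(1975:1979)
  s <- make_series(vals)
  normal <- matrix(300, 2, 2)
  base <- compute_three_year_deviation(s, normal, 1979)
  shifted <- compute_three_year_deviation(s + 12.5, normal, 1979)
  expect_equal(shifted, base + 12.5)
})

test_that("years since fire follows the prior-burn rule with a cap", {
  g <- list(n_rows = 4, n_cols = 4, cell_km = 1)
  burns <- data.frame(pixel_id = c(1L, 1L, 2L), row = c(1L, 1L, 1L),
                      col = c(1L, 1L, 2L), year = c(1950L, 1980L, 1980L))
  h <- pyrogam:::fire_history(burns, g, 1878, 2016)
  expect_equal(years_since_fire(h, 1, 1985), 5L)
  # burns in the query year itself are not "prior"
  expect_equal(years_since_fire(h, 1, 1980), 30L)
  # no recorded burn: treated as having gone the maximum years without fire
  expect_equal(years_since_fire(h, 9, 1990), 100L)
  expect_equal(years_since_fire(h, 9, 1990, cap = 40), 40L)
  # capped even with a recorded ancient burn
  expect_equal(years_since_fire(h, 1, 2016, cap = 100), 36L)
  expect_equal(years_since_fire(h, 2, 2016), 36L)
})

test_that("focal mean matches brute-force disk enumeration", {
  # uniform field: focal mean is the field value everywhere
  u <- matrix(3.5, 9, 9)
  expect_equal(focal_mean_density(u, radius_km = 2), u, tolerance = 1e-9)

  # single nonzero cell: zero beyond the radius, 1/13 at the center for a
  # 2-km disk on a 1-km grid (13 cells within 2 km, by enumeration)
  m <- matrix(0, 11, 11)
  m[6, 6] <- 1
  fm <- focal_mean_density(m, radius_km = 2)
  n_disk <- sum(outer(-2:2, -2:2, function(i, j) sqrt(i^2 + j^2) <= 2))
  expect_equal(n_disk, 13)
  expect_equal(fm[6, 6], 1 / 13, tolerance = 1e-9)
  expect_equal(fm[1, 1], 0, tolerance = 1e-9)

  # full brute-force oracle on a random field with a mask and edges
  set.seed(7)
  v <- matrix(runif(64), 8, 8)
  mask <- matrix(TRUE, 8, 8); mask[3, 5] <- FALSE
  fm <- focal_mean_density(v, radius_km = 2, mask = mask)
  oracle <- matrix(NA_real_, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    acc <- c();
    for (r2 in 1:8) for (c2 in 1:8) {
      if (sqrt((r - r2)^2 + (c - c2)^2) <= 2 && mask[r2, c2]) {
        acc <- c(acc, v[r2, c2])
      }
    }
    oracle[r, c] <- mean(acc)
  }
  expect_equal(fm, oracle, tolerance = 1e-9)
  expect_error(focal_mean_density(v, radius_km = 0.5), "cell size")
})

test_that("decadal interpolation is linear, exact at knots, clamped outside", {
  snaps <- c(`1970` = 10, `1980` = 20)
  expect_equal(interpolate_decadal(snaps, 1975), 15)
  expect_equal(interpolate_decadal(snaps, 1970), 10)
  expect_equal(interpolate_decadal(snaps, 1973), 13)
  expect_warning(out <- interpolate_decadal(snaps, 1965), "clamp")
  expect_equal(out, 10)
})

test_that("fractional cover counts fine cells per coarse cell", {
  fine <- matrix(1L, 8, 8)
  expect_equal(fractional_cover(fine, c(2, 2), 1L), matrix(1, 2, 2))
  expect_equal(fractional_cover(fine, c(2, 2), 2L), matrix(0, 2, 2))
  fine2 <- matrix(0L, 4, 4)
  fine2[1:2, 1:2] <- 1L  # 4 of 16 cells in the single coarse cell
  expect_equal(fractional_cover(fine2, c(1, 1), 1L),
               matrix(0.25, 1, 1))
  expect_error(fractional_cover(matrix(0, 5, 5), c(2, 2), 1), "nest")
})

test_that("distance to features is Euclidean between cell centers", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE
  d <- distance_to_features(m, cell_km = 1)
  expect_equal(d[2, 2], 0)
  expect_equal(d[2, 5], 3)
  expect_equal(d[5, 6], 5)  # offset (3, 4) cells
  expect_error(distance_to_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("fire events are filtered by strict per-class size thresholds", {
  g <- list(n_rows = 10, n_cols = 10, cell_km = 1)
  ev <- data.frame(
    event_id = c(1, 2, 3, 4),
    year = c(1990, 1991, 1992, 1993),
    row = c(1, 2, 3, 4), col = c(1, 2, 3, 4),
    area_km2 = c(1.0, 0.05, 0.12, 1.22),
    fuel_class = c("grass", "timber", "brush", "grass")
  )
  h <- filter_fire_events(ev, g)
  kept <- sort(unique(h$events$event_id))
  # grass 1.0 <= 1.21 dropped; timber 0.05 > 0.04 kept;
  # brush exactly 0.12 dropped (strict inequality); grass 1.22 kept
  expect_equal(kept, c(2, 4))
  expect_equal(sort(h$burns$year), c(1991, 1993))
  ev$fuel_class[1] <- "peat"
  expect_error(filter_fire_events(ev, g), "unknown fuel class")
})

test_that("design table applies the masking rules and counts pixel-years", {
  study <- make_small_study(seed = 21, n = 8, years = 8)
  panel <- study$panel
  # force one water-dominated and one masked cell
  panel$static$water_fraction <- matrix(0.1, 8, 8)
  panel$static$water_fraction[2, 2] <- 0.6
  panel$static$water_fraction[3, 3] <- 0.4
  panel$mask[5, 5] <- FALSE
  years <- (study$cfg$year_start + 3):(study$cfg$year_start + 4)
  tab <- build_design_table(panel, study$history, years)
  expect_equal(nrow(tab), (64 - 2) * 2)
  wet <- pixel_id(2, 2, 8)
  damp <- pixel_id(3, 3, 8)
  expect_false(wet %in% tab$pixel_id)
  expect_equal(sum(tab$pixel_id == damp), 2)
  expect_false(pixel_id(5, 5, 8) %in% tab$pixel_id)
  expect_false(any(duplicated(tab[c("pixel_id", "year")])))
  expect_true(all(tab$years_since_fire >= 1 & tab$years_since_fire <= 100))
  expect_true(all(tab$burned %in% 0:1))
})

test_that("years-since-fire sequences advance by one and reset after burns", {
  study <- make_small_study(seed = 22, n = 16, years = 16)
  tab <- study$table
  burns <- study$history$burns
  for (pid in sample(unique(tab$pixel_id), 25)) {
    sub <- tab[tab$pixel_id == pid, ]
    sub <- sub[order(sub$year), ]
    by <- burns$year[burns$pixel_id == pid]
    for (i in 2:nrow(sub)) {
      if ((sub$year[i] - 1) %in% by) {
        expect_equal(sub$years_since_fire[i], 1)
      } else if (sub$years_since_fire[i - 1] < 100) {
        expect_equal(sub$years_since_fire[i], sub$years_since_fire[i - 1] + 1)
      } else {
        expect_equal(sub$years_since_fire[i], 100)
      }
    }
  }
})

test_that("rebuilding the table from the same inputs is bit-identical", {
  study <- make_small_study(seed = 23, n = 8, years = 8)
  years <- (study$cfg$year_start + 3):study$cfg$year_end
  t1 <- build_design_table(study$panel, study$history, years)
  t2 <- build_design_table(study$panel, study$history, years)
  expect_identical(t1, t2)
})
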