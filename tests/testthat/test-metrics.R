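test_that("peak metrics report the printed peaks and their range", {
  # curve whose extrema equal the reported radial peaks
  cv <- make_curve(biphasic_waveform(21, 40, 2.90, -5.03), dt = 0.01)
  pk <- peak_metrics(cv)
  expect_equal(pk$v_p_sys, 2.90, tolerance = 1e-3)
  expect_equal(pk$v_p_dias, -5.03, tolerance = 1e-3)
  expect_equal(pk$delta_v, 7.93, tolerance = 2e-3)
  expect_equal(pk$t_dias, 520, tolerance = 5)
  lg <- peak_metrics(make_curve(biphasic_waveform(21, 40, 6.08, -8.58),
                                dt = 0.01))
  expect_equal(lg$delta_v, 14.66, tolerance = 2e-3)
  # flat curve: zero range, earliest minimum, flagged
  flat <- make_curve(rep(0, 10))
  pf <- peak_metrics(flat)
  expect_identical(c(pf$v_p_sys, pf$v_p_dias, pf$delta_v), c(0, 0, 0))
  expect_identical(pf$t_dias, 0)
  expect_true(isTRUE(attr(pf, "flat")))
})

test_that("peak factor is the range ratio with reciprocal symmetry", {
  expect_identical(peak_factor(8, 8), 1)
  expect_equal(peak_factor(8.0, 7.76), 0.97, tolerance = 1e-12)
  expect_identical(peak_factor(7.93, 7.93), 1)
  expect_error(peak_factor(0, 1), "> 0")
  set.seed(3)
  for (i in 1:5) {
    a <- runif(1, 1, 10); b <- runif(1, 1, 10)
    expect_equal(peak_factor(a, b) * peak_factor(b, a), 1, tolerance = 1e-12)
  }
})

test_that("nRMSD matches its closed form and a brute-force oracle", {
  t <- seq(0, 800, by = 40)
  base <- sin(t / 120)
  c1 <- make_curve(base, t, dt = 0.5)
  expect_identical(nrmsd(c1, c1), 0)
  # constant offset: 100 * delta / range
  c2 <- c1; c2$values <- c2$values + 0.05; c2$dense_values <- c2$dense_values + 0.05
  rng <- diff(range(c1$dense_values))
  expect_equal(nrmsd(c1, c2), 100 * 0.05 / rng, tolerance = 1e-12)
  # brute-force oracle on different shapes
  c3 <- make_curve(sin(t / 120 + 0.3) * 1.05, t, dt = 0.5)
  x <- c1$dense_values; y <- c3$dense_values
  oracle <- 100 * sqrt(sum((x - y)^2) / length(x)) / (max(x) - min(x))
  expect_equal(nrmsd(c1, c3), oracle, tolerance = 1e-12)
  expect_error(nrmsd(make_curve(rep(1, length(t)), t, dt = 0.5), c1), "flat")
  # invariant under a common additive constant
  c1s <- c1; c1s$values <- c1s$values + 2; c1s$dense_values <- c1s$dense_values + 2
  c3s <- c3; c3s$values <- c3s$values + 2; c3s$dense_values <- c3s$dense_values + 2
  expect_equal(nrmsd(c1s, c3s), nrmsd(c1, c3), tolerance = 1e-12)
})

test_that("curve correlation is the Pearson coefficient of the dense samples", {
  t <- seq(0, 800, by = 40)
  c1 <- make_curve(sin(t / 120), t, dt = 0.5)
  c2 <- make_curve(cos(t / 95), t, dt = 0.5)
  expect_equal(curve_correlation(c1, c1), 1, tolerance = 1e-12)
  neg <- c1; neg$values <- -neg$values; neg$dense_values <- -neg$dense_values
  expect_equal(curve_correlation(c1, neg), -1, tolerance = 1e-12)
  expect_equal(curve_correlation(c1, c2),
               cor(c1$dense_values, c2$dense_values), tolerance = 1e-12)
  # invariances: common constant, common positive scaling
  sc <- function(cv, a, b) {
    cv$values <- a * cv$values + b
    cv$dense_values <- a * cv$dense_values + b
    cv
  }
  expect_equal(curve_correlation(sc(c1, 3, 2), sc(c2, 3, 2)),
               curve_correlation(c1, c2), tolerance = 1e-12)
  expect_error(curve_correlation(make_curve(rep(1, 5)), make_curve(rep(1, 5))),
               "variance")
})

test_that("Bland-Altman agreement follows the hand-computed formulas", {
  out <- bland_altman(c(1, 2), c(2, 1))   # differences {1, -1}
  expect_equal(out$mean_diff, 0)
  expect_equal(out$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(out$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(out$loa_high, 2.7719, tolerance = 1e-4)
  same <- bland_altman(1:4, 1:4)
  expect_identical(unlist(same), c(mean_diff = 0, sd_diff = 0,
                                   loa_low = 0, loa_high = 0))
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20)
  out <- bland_altman(a, b)
  d <- b - a
  expect_equal(out$mean_diff, sum(d) / 20, tolerance = 1e-12)
  expect_equal(out$sd_diff, sqrt(sum((d - mean(d))^2) / 19), tolerance = 1e-12)
  expect_true(out$loa_low <= out$mean_diff && out$mean_diff <= out$loa_high)
  # antisymmetry of the difference direction
  rev <- bland_altman(b, a)
  expect_equal(rev$mean_diff, -out$mean_diff, tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  out <- paired_ttest(c(0, 0, 0), c(1, 2, 3))   # d = {1,2,3}
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_identical(out$df, 2)
  expect_equal(out$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-10)
  expect_equal(out$p, 0.0742, tolerance = 1e-3)
  expect_false(out$significant)
  # brute-force oracle on random pairs
  set.seed(5)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  out <- paired_ttest(a, b)
  d <- b - a
  t_ref <- mean(d) / (sd(d) / sqrt(15))
  expect_equal(out$t, t_ref, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-abs(t_ref), 14), tolerance = 1e-10)
  # degenerate: identical pairs, and constant nonzero differences
  eq <- paired_ttest(1:3, 1:3)
  expect_identical(c(eq$t, eq$p), c(0, 1))
  shift <- paired_ttest(1:3, 2:4)
  expect_identical(shift$p, 0)
  expect_true(shift$significant)
})

test_that("comparison tables are identity for self-comparison and tidy otherwise", {
  t <- seq(0, 440, by = 40)
  cs <- list(
    global.radial = make_curve(biphasic_waveform(12, 40, 3, -5), t, dt = 0.5,
                               direction = "radial", region = "global"),
    global.longitudinal = make_curve(biphasic_waveform(12, 40, 6, -8), t,
                                     dt = 0.5, direction = "longitudinal",
                                     region = "global"))
  cmp <- compare_acquisitions(list(ref = cs, other = cs), ref = "ref")
  expect_identical(nrow(cmp), 2L)
  expect_true(all(cmp$pf == 1))
  expect_true(all(cmp$nrmsd_pct == 0))
  expect_true(all(abs(cmp$c - 1) < 1e-12))
  expect_true(all(cmp$dt_dias_ms == 0))
  # a missing counterpart yields a flagged NA row
  expect_warning(
    cmp2 <- compare_acquisitions(list(ref = cs, other = cs[1]), ref = "ref"),
    "lacks")
  expect_true(is.na(cmp2$pf[cmp2$direction == "longitudinal"]))
  # cohort mode: per-subject tables aggregated with agreement statistics
  subj <- lapply(1:4, function(i) {
    mod <- cs
    mod$global.radial$values <- mod$global.radial$values * (1 + 0.01 * i)
    mod$global.radial$dense_values <-
      mod$global.radial$dense_values * (1 + 0.01 * i)
    list(ref = cs, acc = mod)
  })
  coh <- compare_acquisitions(NULL, ref = "ref", subjects = subj)
  r <- coh[coh$direction == "radial", ]
  expect_equal(r$pf, mean(1 + 0.01 * (1:4)), tolerance = 1e-6)
  expect_true(all(c("dv_mean_diff", "dv_p") %in% names(coh)))
  expect_gt(r$dv_mean_diff, 0)
})
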