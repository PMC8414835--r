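# TAWSS, OSI, pressure scaling, spatial differences, percentiles, corrected
# displacement and the paired Wilcoxon machinery.

test_that("TAWSS closed forms: constant, rectified sinusoid, homogeneity", {
  t <- seq(0, 0.8, length.out = 1001)
  expect_equal(tawss(rep(2.5, 1001), t), 2.5, tolerance = 1e-12)
  A <- 1.7
  w <- A * sin(2 * pi * t / 0.8)
  expect_equal(tawss(w, t), 2 * A / pi, tolerance = 1e-5)
  expect_equal(tawss(2 * w, t), 2 * tawss(w, t), tolerance = 1e-12)
})

test_that("OSI anchors: unidirectional 0, zero-mean 0.5, ratio case, degenerate NA", {
  t <- seq(0, 0.8, length.out = 1001)
  expect_equal(osi(1 + 0.5 * sin(2 * pi * t / 0.8), t), 0, tolerance = 1e-12)
  expect_equal(osi(sin(2 * pi * t / 0.8), t), 0.5, tolerance = 1e-6)
  # |int WSS| = M, int |WSS| = 2M -> OSI = 0.25: 3/4 duty +1, 1/4 duty -1
  w <- ifelse(t / 0.8 %% 1 < 0.75, 1, -1)
  expect_equal(osi(w, t), 0.25, tolerance = 2e-3)
  expect_true(is.na(osi(rep(0, 1001), t)))
})

test_that("OSI stays in [0, 0.5] for random signals and matches TAWSS at 0.5", {
  t <- seq(0, 1, length.out = 64)
  set.seed(99)
  for (i in 1:1000) {
    w <- rnorm(64, mean = runif(1, -1, 1))
    o <- osi(w, t)
    expect_gte(o, 0)
    expect_lte(o, 0.5)
  }
  # OSI = 0.5 implies the time-mean WSS vanishes to quadrature tolerance
  w <- sin(2 * pi * t)
  expect_lt(abs(osi(w, t) - 0.5), 1e-9)
  expect_lt(abs(sum(diff(t) * (w[-1] + w[-64]) / 2)), 1e-9)
})

test_that("systolic-pressure scaling is a plain ratio", {
  expect_equal(scale_to_measured_sbp(10, 148.05, 148.05), 10)
  expect_equal(scale_to_measured_sbp(10, 2 * 148.05, 148.05), 20)
  expect_equal(scale_to_measured_sbp(10, 148.05, 145.0), 10 * 148.05 / 145,
               tolerance = 1e-12)
  expect_equal(round(scale_to_measured_sbp(10, 148.05, 145.0), 2), 10.21)
})

test_that("spatial difference fields follow the normalized-difference contract", {
  pse <- c(1, 2, 3, 4)
  sd0 <- spatial_difference(pse, pse)
  expect_equal(sd0$delta, rep(0, 4))
  expect_equal(sd0$mean_abs, 0)
  sd2 <- spatial_difference(2 * pse, pse)
  expect_equal(sd2$delta, pse / mean(pse) * 100)
  sd_neg <- spatial_difference(pse - 0.5, pse)
  expect_true(all(sd_neg$delta < 0))
  expect_error(spatial_difference(pse, rep(0, 4)), "zero")
  # invariant under common scaling (the systolic-pressure factor)
  f <- 148.05 / 145
  expect_equal(spatial_difference(f * 2 * pse, f * pse)$mean_abs,
               sd2$mean_abs, tolerance = 1e-12)
})

test_that("extreme percentiles use linear order-statistic interpolation", {
  expect_equal(percentile_extreme(1:100, "p99"), 99.01)
  expect_equal(percentile_extreme(1:100, "p1"), 1.99)
  expect_equal(percentile_extreme(rep(7, 50), "p99"), 7)
  expect_equal(percentile_extreme(rep(7, 50), "p1"), 7)
  expect_error(percentile_extreme(numeric(0), "p99"), "empty")
})

test_that("corrected displacement subtracts the diastolic vector field", {
  sys <- matrix(c(3, 0, 0, 0, 3, 0), 2, 3, byrow = TRUE)
  dia <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(corrected_displacement(sys, dia), c(2, 2))
  expect_equal(corrected_displacement(sys, sys), c(0, 0))
  expect_equal(corrected_displacement(sys, 0 * sys), c(3, 3))
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  set.seed(7)
  for (n in c(6, 8, 10, 12)) {
    a <- round(rnorm(n, 1, 2), 2)
    b <- round(rnorm(n, 0, 2), 2)
    # avoid zeros and ties so the exact distribution applies
    d <- a - b
    if (any(d == 0) || any(duplicated(abs(d)))) {
      a <- a + seq_len(n) * 1e-3
    }
    ours <- wilcoxon_signed_rank(a, b)
    oracle <- wilcoxon_enumeration(a, b)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p, oracle$p, tolerance = 1e-12)
    # two-sided p unchanged when the samples are swapped
    swapped <- wilcoxon_signed_rank(b, a)
    expect_equal(swapped$p, ours$p, tolerance = 1e-12)
  }
  deg <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("arm comparison reproduces the pre-stress displacement signature", {
  cmp <- default_comparison()
  rep <- cmp$report
  # omitting pre-stress inflates the systolic displacement ...
  expect_gt(rep$percentile_diff$displacement, 0)
  expect_gt(mean(rep$spatial_fields$displacement, na.rm = TRUE), 0)
  # ... while the corrected displacement (relative to diastole) decreases
  expect_lt(rep$nopse$p99_cdisp, rep$pse$p99_cdisp)
  # paired tests flag the displacement difference
  expect_lt(rep$tests$displacement$p, 0.05)
  # OSI bounded
  expect_lte(rep$pse$p99_osi, 0.5)
  expect_gte(rep$nopse$p99_osi, 0)
})
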