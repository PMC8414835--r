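# Interface quasi-Newton update, periodicity check, and the coupled
# wall/lumen driver in its verifiable limits.

test_that("IQN-ILS bootstrap, zero-residual and linear fixed-point behavior", {
  # residual exactly zero: guess unchanged
  x <- c(1, 2, 3)
  out <- iqn_ils_update(matrix(0, 3, 1), matrix(x, 3, 1))
  expect_equal(out, x)
  # first iteration: plain relaxation x + omega r
  r <- c(0.5, -0.5, 1)
  out <- iqn_ils_update(matrix(r, 3, 1), matrix(x + r, 3, 1), omega = 0.25)
  expect_equal(out, x + 0.25 * r)

  # scalar linear fixed point g(x) = 0.9 x + 1, x* = 10: converges to
  # machine precision once one secant column exists
  g <- function(x) 0.9 * x + 1
  x_k <- 0
  r_hist <- NULL; xt_hist <- NULL
  for (k in 1:3) {
    xt <- g(x_k)
    r_hist <- cbind(r_hist, xt - x_k)
    xt_hist <- cbind(xt_hist, xt)
    x_k <- iqn_ils_update(r_hist, xt_hist, omega = 0.5)
  }
  expect_equal(x_k, 10, tolerance = 1e-12)
})

test_that("quasi-Newton coupling converges where plain relaxation diverges", {
  # strongly coupled linear interface map: spectral radius of the
  # fixed-point iteration > 1, so x_{k+1} = H(x_k) (omega = 1) diverges
  set.seed(42)
  n <- 8
  M <- diag(-1.6, n) + matrix(rnorm(n * n, sd = 0.05), n)
  b <- rnorm(n)
  H <- function(x) as.numeric(M %*% x + b)
  x_star <- solve(diag(n) - M, b)
  # plain relaxation with omega = 1
  x <- rep(0, n)
  for (k in 1:25) x <- H(x)
  expect_gt(sqrt(sum((x - x_star)^2)), 1e3)   # diverged
  # IQN-ILS
  x <- rep(0, n)
  r_hist <- NULL; xt_hist <- NULL
  for (k in 1:(n + 3)) {
    xt <- H(x)
    r_hist <- cbind(r_hist, xt - x)
    xt_hist <- cbind(xt_hist, xt)
    x <- iqn_ils_update(r_hist, xt_hist, omega = 0.1)
  }
  expect_lt(sqrt(sum((x - x_star)^2)), 1e-8)
})

test_that("rank-deficient secant histories are handled by column dropping", {
  r_hist <- cbind(c(1, 0), c(0.5, 0), c(0.25, 0), c(0.25, 0))  # duplicate col
  xt_hist <- cbind(c(2, 1), c(1.5, 1), c(1.25, 1), c(1.25, 1))
  expect_silent(out <- iqn_ils_update(r_hist, xt_hist))
  expect_true(all(is.finite(out)))
})

test_that("periodicity check is the max absolute pointwise difference", {
  a <- sin(seq(0, 2 * pi, length.out = 50))
  expect_equal(check_periodicity(a, a), 0)
  expect_equal(check_periodicity(a, a + 1), 1)
  expect_error(check_periodicity(a, a[-1]))
})

test_that("rigid-wall limit reproduces the decoupled lumen solution", {
  case <- aaa_case(default_aaa_profile(), seed = 1, target_edge = 6,
                   material = wall_material(2000))   # ~rigid, MPa
  bp <- case$bp
  wk <- tune_windkessel(case$waveform, bp,
                        C_A = 0.5)  # tiny sac compliance at this stiffness
  cfg <- coupling_config(dt = 0.02, n_cycles = 2, prestress = FALSE)
  res <- run_fsi(case$mesh, case$material, bp, wk, case$waveform, config = cfg)
  rigid <- simulate_1d_rigid(case$mesh, case$waveform, wk, dt = 0.02,
                             n_cycles = 2, p_init = bp$aa_dia)
  scale <- diff(range(rigid$p))
  expect_lt(max(abs(res$p - rigid$p)) / max(scale, 1), 0.005)
})

test_that("mass is conserved segment-by-segment in the lumen model", {
  cmp <- default_comparison()
  res <- cmp$pse
  # inflow - outflow over the cycle equals the stored-volume change, which
  # vanishes for a periodic solution: compare cycle-mean inflow and outflow
  q_in <- res$q[1, ]
  q_out <- res$q[nrow(res$q), ]
  expect_lt(abs(mean(q_out) - mean(q_in)) / abs(mean(q_in)), 0.02)
})

test_that("interface areas agree between wall and fluid at convergence", {
  cmp <- default_comparison()
  expect_true(all(cmp$pse$convergence$residual < 1e-4))
  expect_true(all(cmp$nopse$convergence$residual < 1e-4))
})

test_that("the pre-stressed arm settles to a periodic solution much faster", {
  cmp <- default_comparison()
  # PSE: periodic within half a mmHg after one cycle; no-PSE: still in its
  # initialization transient after three cycles
  expect_lt(cmp$pse$periodicity, 0.5)
  expect_gt(cmp$nopse$periodicity, cmp$pse$periodicity)
})
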