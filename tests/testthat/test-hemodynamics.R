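# Pressure conversion, Carreau rheology, inlet waveform, Windkessel
# construction, 0D circuit dynamics and patient-specific tuning.

test_that("brachial-to-aortic conversion applies the 0.88/1.05 factors", {
  bp <- convert_brachial_to_aa(80, 141)
  expect_equal(bp$aa_dia, 70.40, tolerance = 1e-12)
  expect_equal(bp$aa_sys, 148.05, tolerance = 1e-12)
  id <- convert_brachial_to_aa(80, 141, dia_factor = 1, sys_factor = 1)
  expect_equal(id$aa_dia, 80)
  expect_equal(id$aa_sys, 141)
  expect_error(convert_brachial_to_aa(120, 80), "sys > dia")
})

test_that("cohort conversion reproduces the printed systolic range", {
  tab <- read_patient_table()
  bp <- convert_brachial_to_aa(tab$p_dia, tab$p_sys)
  expect_equal(round(min(bp$aa_sys), 1), 108.2)
  expect_equal(round(max(bp$aa_sys), 1), 188.0)
})

test_that("mean arterial pressure is the 2:1 weighted mean", {
  expect_equal(mean_arterial_pressure(90, 120), 100)
  expect_equal(mean_arterial_pressure(77, 77), 77)
  expect_equal(mean_arterial_pressure(70.40, 148.05), 96.28, tolerance = 1e-3)
})

test_that("Carreau viscosity hits its limits and decreases monotonically", {
  cp <- carreau_params()
  expect_equal(carreau_viscosity(0, cp), 0.056)
  expect_lt(carreau_viscosity(1e9, cp) - 0.00345, 1e-6)
  expect_gt(carreau_viscosity(1e9, cp), 0.00345)
  # closed form at the Carreau time-constant shear rate
  expect_equal(carreau_viscosity(1 / cp$lam, cp),
               0.00345 + 0.05255 * 2^((0.3568 - 1) / 2), tolerance = 1e-12)
  g <- 10^seq(-3, 5, length.out = 200)
  expect_true(all(diff(carreau_viscosity(g, cp)) < 0))
})

test_that("characteristic impedance follows its power laws", {
  Z1 <- characteristic_impedance(1040, h = 2e-3, E = 1e6, nu = 0.5, a = 0.01)
  expect_equal(characteristic_impedance(1040, 2e-3, 1e6, 0.5, 0.02) / Z1,
               2^(-5 / 2), tolerance = 1e-12)
  expect_equal(characteristic_impedance(1040, 2e-3, 4e6, 0.5, 0.01) / Z1, 2,
               tolerance = 1e-12)
  # direct evaluation of the formula as oracle
  expect_equal(Z1, sqrt(1040 * 2e-3 * 1e6 / (2 * pi^2 * 0.75 * 0.01^5)),
               tolerance = 1e-12)
})

test_that("initial Windkessel splits resistance and fixes the RC time", {
  wk <- initial_windkessel(96.28, 16, Z = 0)
  expect_equal(wk$R, mmHg_to_Pa(96.28) / 16e-6, tolerance = 1e-9)
  wk2 <- initial_windkessel(96.28, 16, Z = 6e7)
  expect_equal(wk2$R * wk2$C, 0.6, tolerance = 1e-12)
  expect_equal(wk2$Z + wk2$R, mmHg_to_Pa(96.28) / 16e-6, tolerance = 1e-6)
  expect_error(initial_windkessel(96.28, 16, Z = 9e8), "exceeds")
})

test_that("AAA compliance estimation is the finite-difference dV/dP", {
  expect_equal(estimate_aaa_compliance(1e5, 1e5, 70, 148), 0)
  expect_equal(estimate_aaa_compliance(1e5, 1e5 + 2000, 70, 124), 2000 / 54,
               tolerance = 1e-12)
  expect_equal(estimate_aaa_compliance(1e5, 1e5 + 2000, 70, 124), 37.0,
               tolerance = 0.05)
  expect_warning(estimate_aaa_compliance(1e5, 9e4, 70, 148), "non-physical")
})

test_that("generic inlet waveform has the contracted period and mean flow", {
  wf <- generic_inlet_waveform(heart_rate = 75, mean_flow = 0.96)
  expect_equal(wf$period, 0.8)
  s <- waveform_samples(wf, 1000)
  m <- sum(diff(s$time) * (s$q[-1] + s$q[-length(s$q)]) / 2) / wf$period
  expect_lt(abs(m * 60 / 1000 / 0.96 - 1), 1e-6)
  # linear in mean flow
  wf2 <- generic_inlet_waveform(mean_flow = 1.92)
  t <- seq(0, 0.8, by = 0.004)
  expect_equal(wf2$q_fun(t), 2 * wf$q_fun(t), tolerance = 1e-12)
  # triphasic: forward peak, reverse phase, low diastolic forward flow
  expect_gt(max(wf$q_fun(t)), 0)
  expect_lt(min(wf$q_fun(t)), 0)
})

test_that("Poiseuille centerline velocity and wall shear stress closed forms", {
  expect_equal(inlet_centerline_velocity(16, 10), 2 * 16e3 / (pi * 100),
               tolerance = 1e-12)
  expect_equal(inlet_centerline_velocity(0, 10), 0)
  expect_equal(poiseuille_wss(0, 10), 0)
  gw <- 4 * 16e-6 / (pi * 0.01^3)
  expect_equal(poiseuille_wss(16, 10), carreau_viscosity(gw) * gw,
               tolerance = 1e-12)
  expect_equal(poiseuille_wss(-16, 10), -poiseuille_wss(16, 10))
})

test_that("0D circuit reproduces steady state, RC decay and the 3-element response", {
  wf <- generic_inlet_waveform()
  wk <- initial_windkessel(96.28, 16, Z = 6e7, C_A = 30)
  # constant inflow: steady pressure (Z+R) qbar
  wfc <- wf; wfc$q_fun <- function(t) rep(16, length(t))
  sim <- simulate_0d_circuit(wfc, wk, n_cycles = 14)
  expect_equal(sim$mean, Pa_to_mmHg((wk$Z + wk$R) * 16e-6), tolerance = 1e-3)

  # zero-inflow decay: time constant ~ R (C + C_A) by log-linear fit
  wf0 <- wf; wf0$q_fun <- function(t) rep(0, length(t))
  dec <- deSolve::lsoda(
    c(pA = mmHg_to_Pa(90), pB = mmHg_to_Pa(90)),
    seq(0, 1.2, by = 0.01),
    function(t, y, p) {
      qz <- (y[1] - y[2]) / wk$Z
      list(c(-qz / wk$C_A, (qz - y[2] / wk$R) / wk$C))
    }, NULL, rtol = 1e-10, atol = 1e-4)
  fit <- stats::lm(log(dec[, "pB"]) ~ dec[, "time"])
  tau_fit <- -1 / stats::coef(fit)[2]
  expect_lt(abs(tau_fit / (wk$R * (wk$C + wk$C_A)) - 1), 0.05)

  # C_A = 0, sinusoidal inflow: match the analytic 3-element WK response
  wk0 <- initial_windkessel(96.28, 16, Z = 6e7, C_A = 0)
  om <- 2 * pi / 0.8
  wfs <- wf
  wfs$q_fun <- function(t) 16 + 4 * sin(om * t)
  sims <- simulate_0d_circuit(wfs, wk0, n_cycles = 16)
  H <- wk0$Z + wk0$R / (1 + 1i * om * wk0$R * wk0$C)   # transfer function
  p_pred <- Pa_to_mmHg((wk0$Z + wk0$R) * 16e-6 +
                         Mod(H) * 4e-6 * sin(om * sims$time + Arg(H)))
  expect_lt(max(abs(sims$p - p_pred)) / diff(range(p_pred)), 0.01)
})

test_that("Windkessel tuning converges for single patients and the full cohort", {
  wf <- generic_inlet_waveform()
  # a tuned model re-fed as init converges immediately
  bp <- convert_brachial_to_aa(77, 122)   # patient L8
  wk <- tune_windkessel(wf, bp, C_A = 37)
  wk2 <- tune_windkessel(wf, bp, C_A = 37, init = wk)
  expect_equal(attr(wk2, "iterations"), 1)
  sim <- simulate_0d_circuit(wf, wk, n_cycles = 20)
  expect_lte(abs(sim$dia - bp$aa_dia), 0.5)
  expect_lte(abs(sim$sys - bp$aa_sys), 0.5)
})
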