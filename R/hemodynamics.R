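# Reduced-order pulsatile hemodynamics: brachial-to-aortic pressure
# conversion, Carreau blood rheology, a generic triphasic inlet waveform,
# three-element Windkessel construction and patient tuning with an added
# AAA compliance, a lumped-circuit pressure solver, and Poiseuille-based
# wall shear stress recovery.
#
# Clinical units at the interface (mmHg, mL/s, L/min, mm); the circuit
# integration runs in SI.

#' Convert brachial to abdominal-aortic blood pressure
#'
#' Brachial cuff measurements overestimate diastolic and underestimate
#' systolic pressure in AAA patients; the abdominal-aortic (AA) values are
#' obtained as `aa_dia = 0.88 * brachial_dia` and
#' `aa_sys = 1.05 * brachial_sys`.
#'
#' @param brachial_dia,brachial_sys brachial pressures, mmHg (`sys > dia > 0`).
#' @param dia_factor,sys_factor conversion factors (defaults 0.88 and 1.05;
#'   set both to 1 for the identity).
#' @return a `blood_pressure` list with `brachial_dia`, `brachial_sys`,
#'   `aa_dia`, `aa_sys` (mmHg). Vectorized over patients.
#' @export
#' @examples
#' convert_brachial_to_aa(80, 141)  # 70.40 / 148.05 mmHg
convert_brachial_to_aa <- function(brachial_dia, brachial_sys,
                                   dia_factor = 0.88, sys_factor = 1.05) {
  if (any(!(brachial_sys > brachial_dia)) || any(brachial_dia <= 0)) {
    stop("need brachial sys > dia > 0")
  }
  structure(list(brachial_dia = brachial_dia, brachial_sys = brachial_sys,
                 aa_dia = dia_factor * brachial_dia,
                 aa_sys = sys_factor * brachial_sys),
            class = "blood_pressure")
}

#' Mean arterial pressure
#'
#' `(2/3) * dia + (1/3) * sys`.
#'
#' @param dia,sys pressures, mmHg (`sys >= dia`).
#' @return mean arterial pressure, mmHg.
#' @export
mean_arterial_pressure <- function(dia, sys) {
  if (any(sys < dia)) stop("need sys >= dia")
  (2 / 3) * dia + (1 / 3) * sys
}

#' Carreau blood rheology parameters
#'
#' Defaults are the standard shear-thinning blood fit: zero-shear viscosity
#' 0.056 Pa.s, infinite-shear viscosity 0.00345 Pa.s, time constant
#' 3.313 s, power index 0.3568.
#'
#' @param eta0,eta_inf viscosities, Pa.s (`eta0 > eta_inf > 0`).
#' @param lam time constant, s.
#' @param n power index in (0, 1).
#' @return a `carreau_params` list.
#' @export
carreau_params <- function(eta0 = 0.056, eta_inf = 0.00345,
                           lam = 3.313, n = 0.3568) {
  stopifnot(eta0 > eta_inf, eta_inf > 0, lam > 0, n > 0, n < 1)
  structure(list(eta0 = eta0, eta_inf = eta_inf, lam = lam, n = n),
            class = "carreau_params")
}

#' Carreau viscosity
#'
#' `eta(g) = eta_inf + (eta0 - eta_inf) * (1 + (lam*g)^2)^((n-1)/2)`,
#' strictly decreasing in the shear rate.
#'
#' @param shear_rate shear rate, 1/s (>= 0, vectorized).
#' @param params a [carreau_params()] list.
#' @return viscosity, Pa.s.
#' @export
carreau_viscosity <- function(shear_rate, params = carreau_params()) {
  if (any(shear_rate < 0)) stop("shear rate must be >= 0")
  params$eta_inf + (params$eta0 - params$eta_inf) *
    (1 + (params$lam * shear_rate)^2)^((params$n - 1) / 2)
}

#' Characteristic impedance of a distensible outlet
#'
#' Minimal-reflection impedance
#' `Z = sqrt(rho * h * E / (2 * pi^2 * (1 - nu^2) * a^5))` (SI throughout).
#'
#' @param rho fluid density, kg/m^3 (default 1040).
#' @param h wall thickness, m.
#' @param E Young modulus, Pa.
#' @param nu Poisson ratio (< 1).
#' @param a outlet radius, m.
#' @return impedance, Pa.s/m^3.
#' @export
characteristic_impedance <- function(rho = 1040, h, E, nu = 0.5, a) {
  stopifnot(rho > 0, h > 0, E > 0, a > 0, nu < 1)
  sqrt(rho * h * E / (2 * pi^2 * (1 - nu^2) * a^5))
}

#' Initial three-element Windkessel model
#'
#' Splits the total resistance `R_T = p_mean / q_mean` into the
#' characteristic impedance `Z` and the peripheral resistance `R = R_T - Z`,
#' and sets the compliance from the RC-time: `C = tau / R`.
#'
#' @param p_mean mean arterial pressure, mmHg.
#' @param q_mean mean flow, mL/s.
#' @param Z characteristic impedance, Pa.s/m^3 (SI).
#' @param tau RC-time, s (default 0.6).
#' @param C_A added AAA compliance, mm^3/mmHg (stored in SI).
#' @return a `windkessel_model` with SI fields `Z`, `R`, `C`, `C_A`, `tau`,
#'   `rho`.
#' @export
initial_windkessel <- function(p_mean, q_mean, Z, tau = 0.6, C_A = 0) {
  R_T <- mmHg_to_Pa(p_mean) / mls_to_m3s(q_mean)
  R <- R_T - Z
  if (R <= 0) stop("characteristic impedance exceeds total resistance (R <= 0)")
  structure(list(Z = Z, R = R, C = tau / R,
                 C_A = C_A * 1e-9 / MMHG_PA, tau = tau, rho = 1040),
            class = "windkessel_model")
}

#' @export
print.windkessel_model <- function(x, ...) {
  to_clin_R <- function(r) r * 1e-6 * MMHG_PA  # mmHg.s/mL
  cat(sprintf("3-element Windkessel: Z = %.3f, R = %.3f mmHg.s/mL, C = %.4f, C_A = %.4f mL/mmHg\n",
              to_clin_R(x$Z), to_clin_R(x$R),
              x$C * MMHG_PA * 1e6, x$C_A * MMHG_PA * 1e6))
  invisible(x)
}

#' Added compliance of the AAA sac
#'
#' `C_A = (V_sys - V_dia) / (P_sys - P_dia)` from the enclosed lumen volumes
#' of the diastolic and systolic wall configurations.
#'
#' @param V_dia,V_sys volumes, mm^3.
#' @param P_dia,P_sys pressures, mmHg (`P_sys > P_dia`).
#' @return compliance, mm^3/mmHg. Negative values are returned with a
#'   warning (non-physical).
#' @export
estimate_aaa_compliance <- function(V_dia, V_sys, P_dia, P_sys) {
  if (!(P_sys > P_dia)) stop("need P_sys > P_dia")
  C_A <- (V_sys - V_dia) / (P_sys - P_dia)
  if (C_A < 0) warning("negative AAA compliance (V_sys < V_dia) is non-physical")
  C_A
}

#' Generic triphasic inlet flow waveform
#'
#' Piecewise sin^2 template of abdominal-aortic flow: a systolic forward
#' peak, an early-diastolic reverse-flow phase and a low diastolic forward
#' phase, C1-periodic, analytically normalized so its time average equals
#' `mean_flow` exactly.
#'
#' @param heart_rate beats per minute (default 75, i.e. period 0.8 s).
#' @param mean_flow time-averaged flow, L/min (default 0.96).
#' @param shape list with `sys_end`, `rev_end` (phase fractions of the
#'   period) and `rev_frac`, `dia_frac` (amplitudes of the reverse and
#'   diastolic phases relative to the systolic peak).
#' @return an `inlet_waveform` with `period` (s), `mean_flow` (L/min),
#'   `q_fun(t)` returning flow in mL/s (periodic in t), and the shape.
#' @export
generic_inlet_waveform <- function(heart_rate = 75, mean_flow = 0.96,
                                   shape = list(sys_end = 0.35, rev_end = 0.55,
                                                rev_frac = 0.25, dia_frac = 0.10)) {
  stopifnot(mean_flow > 0, heart_rate > 0)
  s1 <- shape$sys_end; s2 <- shape$rev_end
  stopifnot(0 < s1, s1 < s2, s2 < 1)
  Tp <- 60 / heart_rate
  # mean of each sin^2 piece is half its width
  mean_b <- (s1 - shape$rev_frac * (s2 - s1) + shape$dia_frac * (1 - s2)) / 2
  stopifnot(mean_b > 0)
  peak <- m3s_to_mls(lmin_to_m3s(mean_flow)) / mean_b
  q_fun <- function(t) {
    s <- (t / Tp) %% 1
    q <- numeric(length(s))
    i1 <- s < s1
    i2 <- !i1 & s < s2
    i3 <- !(i1 | i2)
    q[i1] <- sin(pi * s[i1] / s1)^2
    q[i2] <- -shape$rev_frac * sin(pi * (s[i2] - s1) / (s2 - s1))^2
    q[i3] <- shape$dia_frac * sin(pi * (s[i3] - s2) / (1 - s2))^2
    peak * q
  }
  structure(list(period = Tp, mean_flow = mean_flow, heart_rate = heart_rate,
                 shape = shape, peak = peak, q_fun = q_fun),
            class = "inlet_waveform")
}

#' Sample an inlet waveform on a uniform grid over one period
#'
#' @param wf an `inlet_waveform`.
#' @param n number of samples (default 1000; the closed endpoint is
#'   included, so `n + 1` points span one period).
#' @return data.frame with `time` (s) and `q` (mL/s).
#' @export
waveform_samples <- function(wf, n = 1000L) {
  t <- seq(0, wf$period, length.out = n + 1L)
  data.frame(time = t, q = wf$q_fun(t))
}

#' Poiseuille centerline velocity at the inlet
#'
#' `v_max = 2 q / (pi a^2)` for a parabolic profile.
#'
#' @param q flow, mL/s.
#' @param a_in inlet radius, mm.
#' @return centerline velocity, mm/s.
#' @export
inlet_centerline_velocity <- function(q, a_in) {
  stopifnot(a_in > 0)
  2 * (q * 1e3) / (pi * a_in^2)
}

#' Poiseuille wall shear stress with Carreau viscosity
#'
#' Recovers the wall shear rate `4 q / (pi a^3)` of a Poiseuille profile and
#' evaluates the shear stress with the Carreau viscosity at that rate. The
#' sign follows the flow direction.
#'
#' @param q flow, mL/s (signed, vectorized).
#' @param a lumen radius, mm.
#' @param params a [carreau_params()] list.
#' @return wall shear stress, Pa (signed).
#' @export
poiseuille_wss <- function(q, a, params = carreau_params()) {
  stopifnot(all(a > 0))
  gw <- 4 * abs(q) * 1e-6 / (pi * (a * 1e-3)^3)  # 1/s
  sign(q) * carreau_viscosity(gw, params) * gw
}

#' Simulate the lumped outlet circuit
#'
#' Integrates the 0D circuit used for Windkessel tuning: the inlet flow
#' feeds a node with the added AAA compliance `C_A` to ground, followed by
#' the three-element Windkessel (Z in series, then R parallel C). Uses a
#' stiff-capable ODE solver and returns the last (periodic) cycle of the
#' pressure at the AAA node.
#'
#' @param waveform an `inlet_waveform`.
#' @param wk a `windkessel_model`.
#' @param n_cycles number of cycles to integrate (default 10).
#' @param n_per_cycle output samples per cycle.
#' @param periodicity_tol max cycle-to-cycle pressure change, mmHg; exceeded
#'   after `n_cycles` raises an error.
#' @param p0 initial pressures, mmHg (default the circuit's steady value).
#' @return list with `time` (s, one cycle starting at 0), `p` (mmHg at the
#'   AAA node), `dia`, `sys`, `mean` (mmHg), `periodicity` (mmHg) and the
#'   full trace in `full`.
#' @export
simulate_0d_circuit <- function(waveform, wk, n_cycles = 10L,
                                n_per_cycle = 200L, periodicity_tol = 0.1,
                                p0 = NULL) {
  Tp <- waveform$period
  q_si <- function(t) mls_to_m3s(waveform$q_fun(t))
  qbar <- lmin_to_m3s(waveform$mean_flow)
  p_init <- if (is.null(p0)) Pa_to_mmHg((wk$Z + wk$R) * qbar) else p0
  pA0 <- mmHg_to_Pa(p_init[1])
  pB0 <- mmHg_to_Pa(if (length(p_init) > 1) p_init[2] else p_init[1])

  times <- seq(0, n_cycles * Tp, by = Tp / n_per_cycle)
  if (wk$C_A > 0) {
    deriv <- function(t, y, parms) {
      qz <- (y[1] - y[2]) / wk$Z
      list(c((q_si(t) - qz) / wk$C_A,
             (qz - y[2] / wk$R) / wk$C))
    }
    sol <- deSolve::lsoda(c(pA = pA0, pB = pB0), times, deriv, NULL,
                          rtol = 1e-8, atol = 1e-2)
    pA <- Pa_to_mmHg(sol[, "pA"])
    pB <- Pa_to_mmHg(sol[, "pB"])
  } else {
    deriv <- function(t, y, parms) {
      list((q_si(t) - y[1] / wk$R) / wk$C)
    }
    sol <- deSolve::lsoda(c(pB = pB0), times, deriv, NULL,
                          rtol = 1e-8, atol = 1e-2)
    pB <- Pa_to_mmHg(sol[, "pB"])
    pA <- pB + Pa_to_mmHg(wk$Z * q_si(times))
  }
  idx_last <- seq(length(times) - n_per_cycle, length(times))
  idx_prev <- idx_last - n_per_cycle
  periodicity <- if (min(idx_prev) >= 1) max(abs(pA[idx_last] - pA[idx_prev])) else Inf
  if (periodicity > periodicity_tol) {
    stop(sprintf("circuit not periodic after %d cycles (max cycle-to-cycle dp = %.3f mmHg)",
                 n_cycles, periodicity))
  }
  p_last <- pA[idx_last]
  list(time = times[idx_last] - times[idx_last[1]], p = p_last,
       dia = min(p_last), sys = max(p_last),
       mean = mean(p_last[-length(p_last)]),
       periodicity = periodicity,
       state_end = c(pA[length(pA)], pB[length(pB)]),
       full = data.frame(time = times, p = pA))
}

#' Tune the Windkessel to patient-specific pressures
#'
#' Fixed-point tuning of the peripheral resistance and compliance: the total
#' resistance is scaled by the ratio of target to simulated mean pressure
#' and the compliance by the ratio of simulated to target pulse pressure,
#' until the simulated diastolic and systolic pressures at the AAA node
#' match the converted abdominal-aortic targets within `tol`.
#'
#' @param waveform an `inlet_waveform`.
#' @param targets a `blood_pressure` (uses `aa_dia`, `aa_sys`).
#' @param C_A added AAA compliance, mm^3/mmHg.
#' @param init initial `windkessel_model` (default from [initial_windkessel()]
#'   with the targets' mean pressure).
#' @param tol convergence tolerance on both pressures, mmHg (default 0.5).
#' @param max_iter iteration cap (default 100).
#' @return the tuned `windkessel_model` with an `iterations` attribute and a
#'   `log` attribute (per-iteration simulated dia/sys).
#' @export
tune_windkessel <- function(waveform, targets, C_A = 0, init = NULL,
                            tol = 0.5, max_iter = 100L) {
  p_mean <- mean_arterial_pressure(targets$aa_dia, targets$aa_sys)
  q_mean <- m3s_to_mls(lmin_to_m3s(waveform$mean_flow))
  wk <- if (is.null(init)) {
    # seed impedance: generic 2 cm outlet, 2 mm wall, moderate-group modulus
    Zs <- characteristic_impedance(h = 2e-3, E = 2 * 1.02e6 * 1.5, nu = 0.5,
                                   a = 0.01)
    initial_windkessel(p_mean, q_mean, Zs, C_A = C_A)
  } else {
    init$C_A <- C_A * 1e-9 / MMHG_PA
    init
  }
  target_pulse <- targets$aa_sys - targets$aa_dia
  log <- data.frame(iter = integer(0), dia = numeric(0), sys = numeric(0),
                    R = numeric(0), C = numeric(0))
  p0 <- NULL
  for (it in seq_len(max_iter)) {
    sim <- simulate_0d_circuit(waveform, wk, n_cycles = 12L, p0 = p0)
    p0 <- sim$state_end
    log <- rbind(log, data.frame(iter = it, dia = sim$dia, sys = sim$sys,
                                 R = wk$R, C = wk$C))
    if (abs(sim$dia - targets$aa_dia) <= tol &&
        abs(sim$sys - targets$aa_sys) <= tol) {
      attr(wk, "iterations") <- it
      attr(wk, "log") <- log
      return(wk)
    }
    sim_mean <- mean_arterial_pressure(sim$dia, sim$sys)
    sim_pulse <- sim$sys - sim$dia
    f_R <- min(2, max(0.5, p_mean / sim_mean))
    f_C <- min(2, max(0.5, sim_pulse / target_pulse))
    R_T <- (wk$Z + wk$R) * f_R
    if (R_T <= wk$Z) stop("tuning drove total resistance below the impedance")
    wk$R <- R_T - wk$Z
    wk$C <- wk$C * f_C
  }
  stop(sprintf(
    "Windkessel tuning did not converge in %d iterations (last dia/sys = %.2f/%.2f vs targets %.2f/%.2f)",
    max_iter, log$dia[nrow(log)], log$sys[nrow(log)],
    targets$aa_dia, targets$aa_sys))
}
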