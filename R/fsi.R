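# Partitioned FSI: at every time step the 3D wall solver (areas given
# pressures) and a reduced-order distensible-lumen flow model (pressures
# given areas) are iterated to convergence on the interface field -- the
# axial profile of luminal pressure -- with interface quasi-Newton (IQN-ILS)
# stabilization against the added-mass effect. The lumen flow model is a 1D
# axial discretization: mass conservation distributes the inlet flow along
# the vessel against the wall's volume storage, a Poiseuille/Carreau
# friction and fluid inertia set the axial pressure gradient, and the tuned
# three-element Windkessel closes the outlet.

#' Coupling configuration
#'
#' @param dt time step, s (default 0.004, i.e. 200 steps per 0.8 s cycle).
#' @param n_cycles cardiac cycles to simulate (default 3; the last one is
#'   evaluated).
#' @param tol relative interface residual tolerance (default 1e-5).
#' @param qn_depth number of previous time steps whose quasi-Newton columns
#'   are reused (default 8).
#' @param omega fallback relaxation factor for the bootstrap iteration.
#' @param max_coupling_iter per-step coupling iteration cap.
#' @param wall_tol relative residual tolerance of the wall solves inside the
#'   coupling loop (default 1e-6; an order below the interface tolerance, so
#'   the structural error never limits interface convergence).
#' @param prestress logical: run the pre-stressed (PSE) arm.
#' @return a `coupling_config` list.
#' @export
coupling_config <- function(dt = 0.004, n_cycles = 3L, tol = 1e-5,
                            qn_depth = 8L, omega = 0.5,
                            max_coupling_iter = 50L, wall_tol = 1e-6,
                            prestress = TRUE) {
  stopifnot(n_cycles >= 1, omega > 0, omega <= 1, dt > 0, tol > 0)
  structure(list(dt = dt, n_cycles = n_cycles, tol = tol,
                 qn_depth = qn_depth, omega = omega,
                 max_coupling_iter = max_coupling_iter, wall_tol = wall_tol,
                 prestress = prestress),
            class = "coupling_config")
}

#' Interface quasi-Newton (IQN-ILS) update
#'
#' Given the history of interface iterates `x_i` and fixed-point outputs
#' `xt_i = H(x_i)` (residuals `r_i = xt_i - x_i`), returns the next
#' interface guess. The first iteration applies plain relaxation
#' `x + omega * r`; later iterations solve the least-squares secant system
#' on residual differences to approximate the inverse Jacobian action:
#' `alpha = argmin || V alpha + r_k ||`, `x_next = xt_k + W alpha`, with
#' `V`/`W` the residual/output difference columns (newest first). Columns
#' that make the system rank-deficient are dropped oldest-first.
#'
#' @param r_hist matrix of residual columns of the current coupling loop,
#'   oldest to newest (the last column is the current residual).
#' @param xt_hist matrix of fixed-point output columns, same layout.
#' @param omega relaxation for the bootstrap iteration.
#' @param rank_tol relative tolerance for dropping rank-deficient columns.
#' @param V_extra,W_extra optional secant difference columns reused from
#'   previous time steps (newest first); differences are never taken across
#'   the seam between time steps.
#' @return next interface guess (numeric vector).
#' @export
iqn_ils_update <- function(r_hist, xt_hist, omega = 0.5, rank_tol = 1e-10,
                           V_extra = NULL, W_extra = NULL) {
  r_hist <- as.matrix(r_hist); xt_hist <- as.matrix(xt_hist)
  k <- ncol(r_hist)
  r <- r_hist[, k]
  xt <- xt_hist[, k]
  if (all(r == 0)) return(xt)               # converged: guess unchanged
  V <- W <- NULL
  if (k >= 2) {
    V <- r_hist[, k:2, drop = FALSE] - r_hist[, (k - 1):1, drop = FALSE]
    W <- xt_hist[, k:2, drop = FALSE] - xt_hist[, (k - 1):1, drop = FALSE]
  }
  if (!is.null(V_extra) && NCOL(V_extra) > 0) {
    V <- cbind(V, V_extra); W <- cbind(W, W_extra)
  }
  if (is.null(V) || ncol(V) == 0) {
    return((xt - r) + omega * r)            # bootstrap relaxation
  }
  # drop rank-deficient columns, oldest (rightmost) first
  repeat {
    qrV <- qr(V)
    dR <- abs(diag(qr.R(qrV)))
    if (ncol(V) == 1 || all(dR > rank_tol * max(dR))) break
    V <- V[, -ncol(V), drop = FALSE]
    W <- W[, -ncol(W), drop = FALSE]
  }
  alpha <- qr.coef(qr(V), -r)
  alpha[is.na(alpha)] <- 0
  as.numeric(xt + W %*% alpha)
}

#' Cycle-to-cycle periodicity of a pressure trace
#'
#' @param cycle_a,cycle_b equal-length pressure traces of consecutive
#'   cycles, mmHg.
#' @return maximum absolute pointwise difference, mmHg.
#' @export
check_periodicity <- function(cycle_a, cycle_b) {
  stopifnot(length(cycle_a) == length(cycle_b))
  max(abs(cycle_a - cycle_b))
}

# One reduced-order fluid solve: given luminal areas (m^2) on the axial
# stations, their previous-step values, the inlet flow and the Windkessel
# state, returns the axial pressure profile (Pa), flows (m^3/s), signed WSS
# (Pa) and the updated Windkessel capacitor pressure.
fluid_solve_1d <- function(A, A_prev, q_prev, q_in, dt, z, wk, pB_prev,
                           carreau, rho = 1040) {
  nz <- length(A)
  dz <- diff(z)
  # mass conservation: segment storage rates reduce the downstream flow
  seg_store <- dz * ((A[-nz] + A[-1]) - (A_prev[-nz] + A_prev[-1])) / 2 / dt
  q <- q_in - c(0, cumsum(seg_store))
  q_out <- q[nz]
  # implicit Euler on the Windkessel capacitor
  pB <- (pB_prev + dt * q_out / wk$C) / (1 + dt / (wk$R * wk$C))
  p_out <- pB + wk$Z * q_out
  a <- sqrt(A / pi)
  gw <- 4 * abs(q) / (pi * a^3)
  eta <- carreau_viscosity(gw, carreau)
  dpdz <- 8 * pi * eta * q / A^2 + (rho / A) * (q - q_prev) / dt
  p <- p_out + rev(c(0, cumsum(rev((dpdz[-nz] + dpdz[-1]) / 2 * dz))))
  list(p = p, q = q, wss = sign(q) * eta * gw, pB = pB, q_out = q_out)
}

#' Rigid-wall reference solution of the reduced-order lumen model
#'
#' Runs the 1D fluid model with the luminal areas frozen at the measured
#' geometry -- the decoupled limit a very stiff wall should reproduce.
#'
#' @param mesh a `wall_mesh`.
#' @param waveform an `inlet_waveform`.
#' @param wk a tuned `windkessel_model`.
#' @param dt,n_cycles time stepping controls.
#' @param p_init initial pressure, mmHg.
#' @param carreau a [carreau_params()] list.
#' @return list with `time` (s, last cycle), `p` (mmHg, stations x steps),
#'   `q` (mL/s), `wss` (Pa), `stations` (mm).
#' @export
simulate_1d_rigid <- function(mesh, waveform, wk, dt = 0.004, n_cycles = 3L,
                              p_init = 70, carreau = carreau_params()) {
  A <- luminal_areas(mesh) * 1e-6
  z <- mesh$fine_stations * 1e-3
  nz <- length(A)
  n_steps <- round(n_cycles * waveform$period / dt)
  per_cycle <- round(waveform$period / dt)
  q_prev <- rep(0, nz)
  pB <- mmHg_to_Pa(p_init)
  keep <- (n_steps - per_cycle + 1):n_steps
  P <- matrix(NA_real_, nz, length(keep))
  Q <- P; WSS <- P
  for (s in seq_len(n_steps)) {
    fl <- fluid_solve_1d(A, A, q_prev, mls_to_m3s(waveform$q_fun(s * dt)),
                         dt, z, wk, pB, carreau)
    q_prev <- fl$q; pB <- fl$pB
    if (s %in% keep) {
      j <- s - keep[1] + 1L
      P[, j] <- Pa_to_mmHg(fl$p); Q[, j] <- m3s_to_mls(fl$q); WSS[, j] <- fl$wss
    }
  }
  list(time = (seq_along(keep) - 1) * dt, p = P, q = Q, wss = WSS,
       stations = mesh$fine_stations)
}

#' Run one partitioned FSI simulation arm
#'
#' Time-marches the coupled wall/lumen system over `config$n_cycles` cardiac
#' cycles starting from the abdominal-aortic diastolic pressure. With
#' pre-stress (`config$prestress`), the starting state is the
#' BIM-equilibrated measured geometry (stress field `prestress_state`);
#' without it the measured geometry starts unstressed and inflates during
#' the first steps, the out-of-equilibrium initialization whose consequences
#' the arm comparison quantifies. Each step alternates wall and fluid solves
#' with IQN-ILS acceleration on the interface pressure profile until the
#' relative interface residual falls below `config$tol`. The last cycle is
#' returned for evaluation.
#'
#' @param mesh a `wall_mesh`.
#' @param material an `aaa_material`.
#' @param bp a `blood_pressure` (uses `aa_dia`).
#' @param wk tuned `windkessel_model`.
#' @param waveform an `inlet_waveform`.
#' @param config a [coupling_config()].
#' @param prestress_state the `aaa_wall_state` from [bim_prestress()]
#'   (required when `config$prestress`).
#' @param setup optional precomputed [wall_fem_setup()].
#' @param carreau a [carreau_params()] list.
#' @param verbose print per-cycle progress.
#' @return an `aaa_fsi_result`: last-cycle `time` (s), station grid (mm),
#'   pressure/flow/WSS/area matrices (stations x steps, clinical units),
#'   last-cycle wall displacement (list of n x 3 mm matrices) and
#'   quadrature-point von Mises stress (kPa), per-cycle mid-sac pressure
#'   traces, periodicity, and the coupling convergence log.
#' @export
run_fsi <- function(mesh, material, bp, wk, waveform,
                    config = coupling_config(), prestress_state = NULL,
                    setup = NULL, carreau = carreau_params(),
                    verbose = FALSE) {
  if (config$prestress && is.null(prestress_state)) {
    stop("prestress arm requires the BIM state (prestress_state)")
  }
  if (is.null(setup)) setup <- wall_fem_setup(mesh, material)
  sigma0 <- if (config$prestress) prestress_state$cauchy_stress * 1e3 else NULL

  z <- mesh$fine_stations * 1e-3
  nz <- length(z)
  dt <- config$dt
  per_cycle <- round(waveform$period / dt)
  n_steps <- config$n_cycles * per_cycle
  native_st <- mesh$fine_native

  p_dia <- mmHg_to_Pa(bp$aa_dia)
  A_meas <- luminal_areas(mesh) * 1e-6
  A_prev <- A_meas
  q_prev <- rep(0, nz)
  pB <- p_dia
  p_profile <- rep(p_dia, nz)
  u_prev <- matrix(0, setup$n, 3)
  if (!config$prestress) {
    # robust Newton warm start for the large first-step inflation, at the
    # coupling's wall tolerance
    ws <- solve_static_inflation(mesh, material, bp$aa_dia, setup = setup,
                                 tol = config$wall_tol)
    u_warm <- ws$displacement * 1e-3
  } else {
    u_warm <- u_prev
  }

  face_p <- function(p) p[mesh$face_level]
  mid_native <- which(native_st)
  keep <- (n_steps - per_cycle + 1):n_steps
  P <- matrix(NA_real_, nz, length(keep)); Q <- P; WSS <- P; AR <- P
  disp_hist <- vector("list", length(keep))
  vm_hist <- vector("list", length(keep))
  cycle_mid <- matrix(NA_real_, config$n_cycles, per_cycle)
  conv_log <- data.frame(step = integer(0), iterations = integer(0),
                         residual = numeric(0))
  Vc <- list(); Wc <- list()   # quasi-Newton columns carried across steps

  p_profile_prev <- p_profile
  u_prev2 <- u_prev
  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    q_in <- mls_to_m3s(waveform$q_fun(t_now))
    r_cols <- NULL; xt_cols <- NULL
    # second-order predictors: start the coupling (and the wall Newton)
    # near the new solution
    x <- if (s >= 3) 2 * p_profile - p_profile_prev else p_profile
    u_pred <- if (s >= 3) 2 * u_prev - u_prev2 else u_prev
    u_iter <- if (s == 1) u_warm else u_pred
    res_prev <- Inf; grow <- 0L
    sol <- NULL
    for (it in seq_len(config$max_coupling_iter)) {
      sol <- solve_wall_static(setup, face_p(x), sigma0 = sigma0,
                               u0 = u_iter, tol = config$wall_tol,
                               max_iter = 40, reuse_tangent = TRUE)
      if (!sol$converged) {
        stop(sprintf("wall solve failed at step %d, coupling iteration %d", s, it))
      }
      u_iter <- sol$u
      A <- luminal_areas(mesh, sol$u * 1e3) * 1e-6
      fl <- fluid_solve_1d(A, A_prev, q_prev, q_in, dt, z, wk, pB, carreau)
      r <- fl$p - x
      rnorm <- sqrt(sum(r^2)) / max(sqrt(sum(fl$p^2)), 1e-30)
      if (rnorm < config$tol) { x <- fl$p; break }
      # divergence guard: sustained genuine growth well above the tolerance
      if (rnorm > 1.5 * res_prev && rnorm > 50 * config$tol) {
        grow <- grow + 1L
      } else {
        grow <- 0L
      }
      if (grow >= 3L && it > 2L) {
        stop(sprintf("coupling diverged at step %d (residuals growing; last %.3e)",
                     s, rnorm))
      }
      res_prev <- rnorm
      r_cols <- cbind(r_cols, r); xt_cols <- cbind(xt_cols, fl$p)
      x_new <- iqn_ils_update(
        r_cols, xt_cols, omega = config$omega,
        V_extra = if (length(Vc)) do.call(cbind, Vc),
        W_extra = if (length(Wc)) do.call(cbind, Wc))
      # trust region on the interface update: wild least-squares probes
      # (far outside the physiological pressure scale) destabilize the wall
      # solver without informing the secant model
      dx <- x_new - x
      cap <- mmHg_to_Pa(30)
      if (max(abs(dx)) > cap) dx <- dx * cap / max(abs(dx))
      x <- x + dx
      if (it == config$max_coupling_iter) {
        stop(sprintf("coupling did not converge at step %d (residual %.3e)",
                     s, rnorm))
      }
    }
    # commit the step
    A <- luminal_areas(mesh, sol$u * 1e3) * 1e-6
    fl <- fluid_solve_1d(A, A_prev, q_prev, q_in, dt, z, wk, pB, carreau)
    u_prev2 <- u_prev; u_prev <- sol$u
    A_prev <- A; q_prev <- fl$q; pB <- fl$pB
    p_profile_prev <- p_profile; p_profile <- fl$p
    if (!is.null(r_cols) && ncol(r_cols) >= 2) {
      k <- ncol(r_cols)
      Vd <- r_cols[, k:2, drop = FALSE] - r_cols[, (k - 1):1, drop = FALSE]
      Wd <- xt_cols[, k:2, drop = FALSE] - xt_cols[, (k - 1):1, drop = FALSE]
      Vc <- c(list(Vd), Vc); Wc <- c(list(Wd), Wc)   # newest first
      if (length(Vc) > config$qn_depth) {
        Vc <- Vc[seq_len(config$qn_depth)]; Wc <- Wc[seq_len(config$qn_depth)]
      }
    }
    conv_log <- rbind(conv_log,
                      data.frame(step = s, iterations = it,
                                 residual = sqrt(sum((fl$p - x)^2)) /
                                   max(sqrt(sum(fl$p^2)), 1e-30)))
    cyc <- (s - 1L) %/% per_cycle + 1L
    cycle_mid[cyc, s - (cyc - 1L) * per_cycle] <-
      Pa_to_mmHg(mean(fl$p[mid_native]))
    if (s %in% keep) {
      j <- s - keep[1] + 1L
      P[, j] <- Pa_to_mmHg(fl$p); Q[, j] <- m3s_to_mls(fl$q)
      WSS[, j] <- fl$wss; AR[, j] <- A * 1e6
      disp_hist[[j]] <- sol$u * 1e3
      vm_hist[[j]] <- von_mises(sol$stress) / 1e3
    }
    if (verbose && (s %% 10L == 0L || s %% per_cycle == 0L)) {
      message(sprintf("[%s] step %d/%d (cycle %d): %d coupling iterations, p = %.1f..%.1f mmHg",
                      format(Sys.time(), "%H:%M:%S"), s, n_steps, cyc, it,
                      Pa_to_mmHg(min(fl$p)), Pa_to_mmHg(max(fl$p))))
    }
  }

  periodicity <- if (config$n_cycles >= 2) {
    check_periodicity(cycle_mid[config$n_cycles - 1L, ],
                      cycle_mid[config$n_cycles, ])
  } else NA_real_
  if (!config$prestress && is.finite(periodicity) && periodicity > 0.5) {
    warning(sprintf(
      "no-PSE arm not periodic after %d cycles (cycle-to-cycle dp = %.2f mmHg); more cycles are advisable",
      config$n_cycles, periodicity))
  }

  lumen_mid <- colMeans(P[mid_native, , drop = FALSE])
  structure(list(
    time = (seq_along(keep) - 1) * dt, stations = mesh$fine_stations,
    native_stations = native_st,
    p = P, q = Q, wss = WSS, areas = AR,
    lumen_pressure = lumen_mid,
    dia_pressure = min(lumen_mid), sys_pressure = max(lumen_mid),
    sys_step = which.max(lumen_mid), dia_step = which.min(lumen_mid),
    displacement = disp_hist, von_mises_qp = vm_hist,
    cycle_pressure = cycle_mid, periodicity = periodicity,
    convergence = conv_log, prestress = config$prestress,
    config = config, mesh = mesh
  ), class = "aaa_fsi_result")
}

#' @export
print.aaa_fsi_result <- function(x, ...) {
  cat(sprintf("FSI result (%s): %d cycles at dt = %.3g s; last-cycle dia/sys = %.1f/%.1f mmHg; periodicity %.3f mmHg\n",
              if (x$prestress) "PSE" else "no-PSE", x$config$n_cycles,
              x$config$dt, x$dia_pressure, x$sys_pressure, x$periodicity))
  cat(sprintf("mean coupling iterations per step: %.2f\n",
              mean(x$convergence$iterations)))
  invisible(x)
}
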