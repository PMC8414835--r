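# Nonlinear wall solver: total Lagrangian Newton iteration on the measured
# geometry with a follower (deformation-dependent, surface-normal) pressure
# load on the luminal faces, cylindrical end constraints (inlet/outlet nodes
# move radially only), and an optional initial Cauchy stress field carried in
# the residual -- the ingredient the Backward Incremental pre-stress needs.
#
# Internally SI (m, Pa); meshes arrive in mm, pressures in mmHg.

#' Low-level wall FEM setup
#'
#' Precomputes the SI node table, the reduced-coordinate transformation that
#' enforces radial-only motion of the inlet/outlet rings, and the luminal
#' face table. The returned object carries a cache environment reused across
#' solves (factorized tangents for modified Newton).
#'
#' @param mesh a `wall_mesh`.
#' @param material an `aaa_material`.
#' @return a `wall_fem` setup object.
#' @export
wall_fem_setup <- function(mesh, material) {
  X <- mesh$nodes * 1e-3
  n <- nrow(X)
  ends <- list(
    list(ids = mesh$node_sets$inlet, origin = mesh$centers[1, ] * 1e-3,
         axis = mesh$tangents[1, ]),
    list(ids = mesh$node_sets$outlet,
         origin = mesh$centers[nrow(mesh$centers), ] * 1e-3,
         axis = mesh$tangents[nrow(mesh$tangents), ])
  )
  constrained <- integer(0); rhat <- NULL
  for (e in ends) {
    d <- X[e$ids, , drop = FALSE] - matrix(e$origin, length(e$ids), 3, byrow = TRUE)
    ax <- e$axis / sqrt(sum(e$axis^2))
    d <- d - (d %*% ax) %*% t(ax)
    nr <- sqrt(rowSums(d^2))
    constrained <- c(constrained, e$ids)
    rhat <- rbind(rhat, d / nr)
  }
  free <- setdiff(seq_len(n), constrained)
  n_red <- 3L * length(free) + length(constrained)
  ii <- c(as.vector(t(outer(3 * (free - 1), 1:3, "+"))),
          as.vector(t(outer(3 * (constrained - 1), 1:3, "+"))))
  jj <- c(seq_len(3L * length(free)),
          rep(3L * length(free) + seq_along(constrained), each = 3))
  xx <- c(rep(1, 3L * length(free)), as.vector(t(rhat)))
  Tmat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, n_red))
  structure(list(
    mesh = mesh, X = X, conn = mesh$hexes, n = n,
    Tmat = Tmat, faces = mesh$luminal_faces,
    G = material$G * 1e6, kappa = material$kappa * 1e6,
    material = material, n_qp = nrow(mesh$hexes) * 27L,
    cache = new.env(parent = emptyenv())
  ), class = "wall_fem")
}

#' Low-level static wall solve
#'
#' Newton iteration on the nonlinear equilibrium of the wall under a
#' per-face luminal pressure, with optional initial Cauchy stress `sigma0`
#' carried in the residual. Converged when the reduced residual norm drops
#' below `tol` times the external force norm. A backtracking line search
#' guards divergent steps; the factorized tangent is reused across
#' iterations (and calls, when `reuse_tangent = TRUE`) and reassembled when
#' convergence stalls.
#'
#' @param setup a `wall_fem` object from [wall_fem_setup()].
#' @param face_pressure_Pa scalar or per-face luminal pressure, Pa.
#' @param sigma0 optional initial Cauchy stress, (n_el*27) x 6 Voigt, Pa.
#' @param u0 optional initial displacement guess, n x 3 in meters.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap.
#' @param reuse_tangent start from a previously factorized tangent if one is
#'   cached (modified Newton; used by the FSI driver).
#' @return list with `u` (m), `stress` (Pa, Voigt per quadrature point),
#'   `fext` (N), `energy` (J), `iterations`, `residuals`, `converged`.
#' @export
solve_wall_static <- function(setup, face_pressure_Pa, sigma0 = NULL, u0 = NULL,
                              tol = 1e-8, max_iter = 50, reuse_tangent = FALSE) {
  X <- setup$X; conn <- setup$conn; n <- setup$n
  Tm <- setup$Tmat
  pf <- rep_len(face_pressure_Pa, nrow(setup$faces))
  u <- if (is.null(u0)) matrix(0, n, 3) else u0
  cache <- setup$cache
  if (!reuse_tangent) cache$lu <- NULL

  res_hist <- numeric(0)
  resid <- function(u) {
    fext <- .fem_follower_load(X, u, setup$faces, pf)$f
    a <- .fem_assemble(X, conn, u, setup$G, setup$kappa, sigma0,
                       want_tangent = FALSE, want_stress = FALSE)
    if (a$detF_min <= 0) return(list(ok = FALSE))
    r <- a$fint - fext
    rr <- as.numeric(Matrix::crossprod(Tm, r))
    list(ok = TRUE, rr = rr, rnorm = sqrt(sum(rr^2)),
         fextnorm = sqrt(sum(as.numeric(Matrix::crossprod(Tm, fext))^2)))
  }

  # Assemble and factorize the symmetrized tangent at the given state.
  # The follower-load and initial-stress contributions are asymmetric and
  # (away from equilibrium) indefinite; the averaged tangent keeps the
  # quasi-Newton flow convergent. A supernodal LL' is tried first (fast;
  # succeeds near stable equilibria), then simplicial LDL', then sparse LU.
  factorize <- function(u) {
    cache$nfact <- if (is.null(cache$nfact)) 1L else cache$nfact + 1L
    a <- .fem_assemble(X, conn, u, setup$G, setup$kappa, sigma0,
                       want_tangent = TRUE, want_stress = FALSE)
    fl <- .fem_follower_load(X, u, setup$faces, pf, want_tangent = TRUE)
    # dR/du = K_material - K_followerLoad
    K <- Matrix::sparseMatrix(i = c(a$ti, fl$ti), j = c(a$tj, fl$tj),
                              x = c(a$tx, -fl$tx),
                              dims = c(3L * n, 3L * n))
    Kr <- Matrix::symmpart(Matrix::t(Tm) %*% K %*% Tm)
    f <- NULL
    if (!isFALSE(cache$use_super)) {
      # supernodal LL' is much faster but only valid near stable equilibria
      # (positive definite); once it fails, stick to LDL' for this setup
      ok <- TRUE
      f <- withCallingHandlers(
        tryCatch(Matrix::Cholesky(Kr, LDL = FALSE, perm = TRUE, super = TRUE),
                 error = function(e) NULL),
        warning = function(w) {
          ok <<- FALSE                    # 'not positive definite' etc.
          invokeRestart("muffleWarning")
        })
      if (is.null(f) || !ok) {
        cache$use_super <- FALSE
        f <- NULL
      }
    }
    if (is.null(f)) {
      f <- tryCatch(Matrix::Cholesky(Kr, LDL = TRUE, perm = TRUE),
                    error = function(e) Matrix::lu(as(Kr, "generalMatrix")))
    }
    cache$lu <- f
    invisible(NULL)
  }

  st <- resid(u)
  if (!st$ok) stop("inverted element in initial state (det F <= 0)")
  ref <- function(st) max(st$fextnorm, 1e-30)
  it <- 0L
  fresh <- FALSE
  while (st$rnorm > tol * ref(st) && it < max_iter) {
    it <- it + 1L
    # Modified Newton: iterations with a frozen factorization are cheap, a
    # refactorization is not. Refactorize only when progress over the last
    # two accepted steps is poor and the factor is not already current.
    k <- length(res_hist)
    stalled <- !fresh && k >= 3 &&
      res_hist[k] > 0.7 * res_hist[k - 1] &&
      res_hist[k - 1] > 0.7 * res_hist[k - 2]
    if (is.null(cache$lu) || stalled) {
      factorize(u)
      fresh <- TRUE
    }
    du_red <- Matrix::solve(cache$lu, -st$rr)
    du <- matrix(as.numeric(Tm %*% du_red), n, 3, byrow = TRUE)
    alpha <- 1
    repeat {
      st_new <- resid(u + alpha * du)
      if (st_new$ok && st_new$rnorm < st$rnorm) break
      alpha <- alpha / 2
      if (alpha < 1 / 64) break
    }
    if (!st_new$ok || st_new$rnorm >= st$rnorm) {
      if (!fresh) {
        # stale direction rejected: refactorize at the current state and
        # retry with the next iteration
        factorize(u)
        fresh <- TRUE
      } else {
        # even the fresh tangent makes no progress: stop here
        res_hist <- c(res_hist, st$rnorm)
        break
      }
    } else {
      u <- u + alpha * du
      st <- st_new
      fresh <- FALSE
    }
    res_hist <- c(res_hist, st$rnorm)
  }
  converged <- st$rnorm <= tol * ref(st)
  fin <- .fem_assemble(X, conn, u, setup$G, setup$kappa, sigma0,
                       want_tangent = FALSE, want_stress = TRUE)
  list(u = u, stress = fin$stress,
       fext = .fem_follower_load(X, u, setup$faces, pf)$f,
       energy = fin$energy, iterations = it, residuals = res_hist,
       converged = converged, rnorm = st$rnorm, ref = ref(st))
}

new_wall_state <- function(mesh, u_m, stress_Pa, pressure_mmHg, prestressed,
                           iterations = NA_integer_) {
  structure(list(
    mesh = mesh,
    displacement = u_m * 1e3,        # mm
    cauchy_stress = stress_Pa / 1e3, # kPa
    applied_pressure = pressure_mmHg,
    prestressed = prestressed,
    iterations = iterations
  ), class = "aaa_wall_state")
}

#' @export
print.aaa_wall_state <- function(x, ...) {
  um <- sqrt(rowSums(x$displacement^2))
  cat(sprintf("Wall state at %.1f mmHg%s: max |u| = %.4f mm, max von Mises = %.1f kPa\n",
              x$applied_pressure, if (x$prestressed) " (pre-stressed)" else "",
              max(um), max(von_mises(x$cauchy_stress))))
  invisible(x)
}

#' Static inflation of the wall mesh
#'
#' Solves the nonlinear equilibrium of the Neo-Hookean wall under a uniform
#' luminal pressure with radial-only end constraints. If the target load
#' does not converge in one go it is applied in automatic sub-steps.
#'
#' @param mesh a `wall_mesh` (or a `wall_fem` setup via `setup`).
#' @param material an `aaa_material`.
#' @param pressure luminal pressure, mmHg (>= 0).
#' @param initial optional `aaa_wall_state` used as warm start; if it is
#'   pre-stressed its stress field is carried as initial stress, which makes
#'   this call the equilibrium re-check of the pre-stressed configuration.
#' @param sigma0_kPa optional explicit initial Cauchy stress (kPa, Voigt).
#' @param tol,max_iter Newton controls.
#' @param setup optional precomputed [wall_fem_setup()] (avoids re-setup).
#' @return an `aaa_wall_state`.
#' @export
solve_static_inflation <- function(mesh, material, pressure, initial = NULL,
                                   sigma0_kPa = NULL, tol = 1e-8,
                                   max_iter = 50, setup = NULL) {
  stopifnot(pressure >= 0)
  if (is.null(setup)) setup <- wall_fem_setup(mesh, material)
  sigma0 <- NULL
  prestressed <- FALSE
  if (!is.null(sigma0_kPa)) {
    sigma0 <- sigma0_kPa * 1e3
    prestressed <- TRUE
  } else if (!is.null(initial) && isTRUE(initial$prestressed)) {
    sigma0 <- initial$cauchy_stress * 1e3
    prestressed <- TRUE
  }
  u0 <- if (!is.null(initial)) initial$displacement * 1e-3 else NULL
  p_target <- mmHg_to_Pa(pressure)
  # ramp from the warm-start pressure (if any) in ~25 mmHg load steps;
  # halve the steps further if an increment fails to converge
  p_from <- if (!is.null(initial) && is.finite(initial$applied_pressure)) {
    mmHg_to_Pa(initial$applied_pressure)
  } else 0
  n_sub <- max(1L, ceiling(abs(pressure - Pa_to_mmHg(p_from)) / 25))
  repeat {
    ok <- TRUE
    u <- u0
    sol <- NULL
    for (s in seq_len(n_sub)) {
      p_s <- p_from + (p_target - p_from) * s / n_sub
      sol <- solve_wall_static(setup, p_s, sigma0 = sigma0,
                               u0 = u, tol = tol, max_iter = max_iter,
                               reuse_tangent = TRUE)
      if (!sol$converged) { ok <- FALSE; break }
      u <- sol$u
    }
    if (ok) break
    n_sub <- n_sub * 2L
    if (n_sub > 32L) {
      stop(sprintf("static inflation did not converge (final residual %.3e, history: %s)",
                   sol$rnorm, paste(signif(sol$residuals, 3), collapse = ", ")))
    }
  }
  new_wall_state(mesh, sol$u, sol$stress, pressure, prestressed,
                 iterations = sol$iterations)
}

#' Backward Incremental pre-stress estimation
#'
#' Estimates the wall stress already present in the measured (pressurized)
#' geometry. The measured pressure `p_m` is applied in `i_max` increments
#' `p_i = p_m * sin(i * pi / (2 * i_max))`; at every increment the nodal
#' positions are reset to the measured geometry, the total Cauchy stress of
#' the previous increment is carried as initial stress, and one equilibrium
#' solve is performed. At the final increment the load increments are small,
#' so the returned state has near-zero displacement and a stress field in
#' equilibrium with `p_m` on the measured geometry.
#'
#' @param mesh a `wall_mesh`.
#' @param material an `aaa_material`.
#' @param p_m measured (diastolic) pressure, mmHg, > 0.
#' @param i_max number of increments (default 20).
#' @param tol,max_iter Newton controls per increment.
#' @param setup optional precomputed [wall_fem_setup()].
#' @return a pre-stressed `aaa_wall_state` (displacement near zero, stress in
#'   equilibrium with `p_m`).
#' @export
bim_prestress <- function(mesh, material, p_m, i_max = 20L, tol = 1e-8,
                          max_iter = 50, setup = NULL) {
  stopifnot(p_m > 0, i_max >= 1)
  if (is.null(setup)) setup <- wall_fem_setup(mesh, material)
  sigma0 <- matrix(0, setup$n_qp, 6)
  u_guess <- NULL
  sol <- NULL
  for (i in seq_len(i_max)) {
    p_i <- mmHg_to_Pa(p_m) * sin(i * pi / (2 * i_max))
    sol <- tryCatch(
      solve_wall_static(setup, p_i, sigma0 = sigma0, u0 = u_guess,
                        tol = tol, max_iter = max_iter, reuse_tangent = TRUE),
      error = function(e) stop(sprintf("BIM increment %d failed: %s", i,
                                       conditionMessage(e))))
    if (!sol$converged) {
      stop(sprintf("BIM increment %d did not converge (residuals: %s)", i,
                   paste(signif(sol$residuals, 3), collapse = ", ")))
    }
    sigma0 <- sol$stress      # total Cauchy at this increment
    u_guess <- sol$u          # Newton warm start only; geometry is reset
  }
  new_wall_state(mesh, sol$u, sol$stress, p_m, prestressed = TRUE,
                 iterations = sol$iterations)
}

#' BIM pressure load schedule
#'
#' @param i increment index (1..i_max).
#' @param i_max number of increments.
#' @param p_m measured pressure.
#' @return the increment pressure `p_m * sin(i*pi/(2*i_max))`.
#' @export
bim_pressure_schedule <- function(i, i_max, p_m = 1) {
  p_m * sin(i * pi / (2 * i_max))
}

#' Nodal von Mises stress field
#'
#' Quadrature-point stresses are averaged per element and distributed to the
#' element's nodes (simple volume-less averaging), giving a nodal field for
#' percentile summaries and export.
#'
#' @param state an `aaa_wall_state`.
#' @return numeric vector, one von Mises value (kPa) per mesh node.
#' @export
nodal_von_mises <- function(state) {
  mesh <- state$mesh
  vm_qp <- von_mises(state$cauchy_stress)
  el_mean <- rowMeans(matrix(vm_qp, nrow = nrow(mesh$hexes), byrow = TRUE))
  acc <- numeric(nrow(mesh$nodes)); cnt <- numeric(nrow(mesh$nodes))
  for (e in seq_len(nrow(mesh$hexes))) {
    ids <- mesh$hexes[e, ]
    acc[ids] <- acc[ids] + el_mean[e]
    cnt[ids] <- cnt[ids] + 1
  }
  cnt[cnt == 0] <- 1
  acc / cnt
}
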