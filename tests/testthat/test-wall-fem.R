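# Material law, static inflation against the closed-form incompressible
# cylinder solution, Backward-Incremental pre-stress, and energy/objectivity
# properties of the wall solver.

test_that("Neo-Hookean Cauchy stress matches closed forms", {
  # F = I: purely hydrostatic response
  s <- neo_hookean_cauchy(diag(3), G = 1, p = 2.5)
  expect_equal(s, -2.5 * diag(3))
  # simple shear gamma: sigma_12 = G * gamma (J = 1, penalty p = 0)
  gam <- 0.3
  Fs <- diag(3); Fs[1, 2] <- gam
  s <- neo_hookean_cauchy(Fs, G = 0.92)
  expect_equal(s[1, 2], 0.92 * gam, tolerance = 1e-12)
  # incompressible uniaxial stretch: eliminate p from the lateral
  # zero-stress condition -> sigma_axial = G (lambda^2 - 1/lambda)
  lam <- 1.4
  Fu <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  s <- neo_hookean_cauchy(Fu, G = 1, p = NULL)
  # penalty p equals the lateral stress term: subtract it
  s_axial <- s[1, 1] - s[2, 2]
  expect_equal(s_axial, lam^2 - 1 / lam, tolerance = 1e-12)
  expect_error(neo_hookean_cauchy(diag(c(-1, 1, 1)), G = 1), "inverted")
})

test_that("group shear moduli follow the diameter classification", {
  expect_equal(assign_shear_modulus("S")$G, 0.92)
  expect_equal(assign_shear_modulus("M")$G, 1.02)
  expect_equal(assign_shear_modulus("L")$G, 1.36)
  m <- assign_shear_modulus("S")
  expect_equal(m$E, 2 * 0.92 * 1.499)
  expect_error(wall_material(1, nu = 0.3), "Poisson")
})

test_that("von Mises stress has the standard closed forms", {
  expect_equal(von_mises(-3 * diag(3)), 0)
  uni <- matrix(c(5, 0, 0, 0, 0, 0), 1)
  expect_equal(von_mises(uni), 5)
  shear <- matrix(c(0, 0, 0, 2, 0, 0), 1)
  expect_equal(von_mises(shear), sqrt(3) * 2)
  expect_error(von_mises(matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3)), "symmetric")
})

test_that("zero pressure gives zero displacement and stress", {
  mesh <- tube_wall_mesh(r = 10, L = 40, target_edge = 5)
  st <- solve_static_inflation(mesh, wall_material(0.92), 0)
  expect_equal(max(abs(st$displacement)), 0)
  expect_lt(max(abs(st$cauchy_stress)), 1e-9)
})

test_that("rigid rotation of a load-free mesh produces no stress (objectivity)", {
  mesh <- tube_wall_mesh(r = 10, L = 40, target_edge = 5)
  th <- 0.35
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  u <- mesh$nodes %*% t(R) - mesh$nodes
  a <- aaafsi:::.fem_assemble(mesh$nodes * 1e-3, mesh$hexes, u * 1e-3,
                              0.92e6, 459.7e6, NULL, FALSE, TRUE)
  expect_lt(max(abs(a$stress)), 1e-3)   # Pa, vs MPa-scale moduli
  expect_lt(max(abs(a$fint)), 1e-9)
})

test_that("thick-tube inflation matches the analytic incompressible solution within 2%", {
  mesh <- tube_wall_mesh(r = 10, L = 40, target_edge = 5)
  mat <- wall_material(0.92)
  st <- solve_static_inflation(mesh, mat, 70)
  u_fem <- luminal_radial_displacement(mesh, st)
  ri <- analytic_inflated_radius(mmHg_to_Pa(70), 0.92e6, 10e-3, 12e-3)
  u_exact <- ri * 1e3 - 10
  expect_lt(abs(u_fem / u_exact - 1), 0.02)
})

test_that("BIM load schedule follows p_m sin(i pi / (2 i_max))", {
  expect_equal(bim_pressure_schedule(20, 20, 80), 80)
  expect_equal(bim_pressure_schedule(10, 20, 1), sin(pi / 4), tolerance = 1e-12)
  expect_equal(bim_pressure_schedule(10, 20, 1), 0.7071, tolerance = 1e-4)
})

test_that("BIM pre-stress reaches equilibrium on the measured geometry", {
  # thin tube r/h = 20: hoop stress close to the Laplace value p r / h
  mesh <- tube_wall_mesh(r = 20, L = 60, target_edge = 7, thickness = 1)
  mat <- wall_material(0.92)
  p_m <- 70
  bim <- bim_prestress(mesh, mat, p_m)
  expect_true(bim$prestressed)
  expect_lt(max(sqrt(rowSums(bim$displacement^2))), 0.05)  # mm, ~0 by design
  # mean max-principal (hoop) stress vs Laplace
  S <- bim$cauchy_stress * 1e3
  hoop <- vapply(seq_len(nrow(S)), function(i) {
    v <- S[i, ]
    m <- matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3, 3)
    max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  expect_lt(abs(mean(hoop) / (mmHg_to_Pa(p_m) * 20 / 1) - 1), 0.05)
  # re-solving at p_m from the pre-stressed state moves no node by more
  # than 1% of the wall thickness
  chk <- solve_static_inflation(mesh, mat, p_m, initial = bim)
  expect_lt(max(sqrt(rowSums(chk$displacement^2))), 0.01 * mesh$thickness)
})

test_that("pressure work matches stored strain energy along a quasi-static path", {
  mesh <- tube_wall_mesh(r = 10, L = 40, target_edge = 5)
  mat <- wall_material(0.92)
  setup <- wall_fem_setup(mesh, mat)
  p_end <- mmHg_to_Pa(70)
  n_steps <- 25
  u <- matrix(0, setup$n, 3)
  f_prev <- rep(0, 3 * setup$n)
  W_ext <- 0
  sol <- NULL
  for (s in seq_len(n_steps)) {
    sol <- solve_wall_static(setup, p_end * s / n_steps, u0 = u, tol = 1e-10,
                             reuse_tangent = TRUE)
    du <- as.vector(t(sol$u - u))
    W_ext <- W_ext + sum((f_prev + sol$fext) / 2 * du)
    u <- sol$u
    f_prev <- sol$fext
  }
  expect_lt(abs(W_ext / sol$energy - 1), 0.01)
})

test_that("systolic wall stress increases with maximum diameter across size groups", {
  p99 <- vapply(c(33, 47, 53), function(dmax) {
    prof <- default_aaa_profile()
    prof$max_diameter <- dmax
    prof$neck_diameter <- min(22, 0.55 * dmax)
    case <- aaa_case(prof, seed = 7, target_edge = 6,
                     brachial_dia = 80, brachial_sys = 141)
    setup <- wall_fem_setup(case$mesh, case$material)
    bim <- bim_prestress(case$mesh, case$material, case$bp$aa_dia, setup = setup)
    sys_state <- solve_static_inflation(case$mesh, case$material, case$bp$aa_sys,
                                        initial = bim, setup = setup)
    vm <- nodal_von_mises(sys_state)
    percentile_extreme(vm[case$mesh$node_native], "p99")
  }, numeric(1))
  expect_true(all(diff(p99) > 0))
})
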