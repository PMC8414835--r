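# Synthetic segmentation generator, elongation protocol, surface and wall
# meshing, and enclosed-volume computation.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("synthetic AAA generator honors the profile and the seed", {
  prof <- default_aaa_profile()
  prof$max_diameter <- 27
  prof$noise_sd <- 0.2
  st1 <- generate_synthetic_aaa(prof, seed = 1)
  st2 <- generate_synthetic_aaa(prof, seed = 1)
  expect_identical(st1, st2)  # byte-identical for a fixed seed
  st3 <- generate_synthetic_aaa(prof, seed = 2)
  expect_false(identical(st1$contours, st3$contours))
  d <- max_diameter_and_group(st1)
  expect_lt(abs(d$d_max - 27), 3 * prof$noise_sd + 1e-9)

  bad <- prof; bad$max_diameter <- 10; bad$neck_diameter <- 22
  expect_error(generate_synthetic_aaa(bad), "non-physical")
  expect_error(generate_synthetic_aaa(utils::modifyList(prof, list(n_contours = 3))),
               "5 contours")
})

test_that("noise-free symmetric profile gives circular contours on a straight axis", {
  prof <- default_aaa_profile()
  prof$asymmetry <- 0; prof$centerline_bow <- 0; prof$noise_sd <- 0
  st <- generate_synthetic_aaa(prof, seed = 5)
  expect_equal(st$contours$major, st$contours$minor)
  expect_true(all(abs(st$contours$cx) < 1e-12))
  expect_true(all(abs(st$contours$cy) < 1e-12))
  expect_equal(st$contours$nz, rep(1, nrow(st$contours)))
})

test_that("size groups follow the clinical cut-offs", {
  expect_equal(diameter_group(39), "S")
  expect_equal(diameter_group(40), "M")
  expect_equal(diameter_group(49), "M")
  expect_equal(diameter_group(50), "L")
  tube <- tube_stack(r = 10, L = 50)
  d <- max_diameter_and_group(tube)
  expect_equal(d$d_max, 20)
  expect_equal(d$group, "S")
})

test_that("elongation adds 50 mm of arc length per side and 20 mm circular ends", {
  st <- generate_synthetic_aaa(default_aaa_profile(), seed = 3)
  L0 <- diff(range(st$contours$station))
  el <- elongate_contours(st)
  expect_equal(diff(range(el$contours$station)), L0 + 100, tolerance = 1e-9)
  first <- el$contours[1, ]; last <- el$contours[nrow(el$contours), ]
  expect_equal(2 * first$major, 20, tolerance = 1e-9)
  expect_equal(2 * first$minor, 20, tolerance = 1e-9)
  expect_equal(2 * last$major, 20, tolerance = 1e-9)
  # proximal extension ends parallel to the spine (global z)
  expect_equal(abs(first$nz), 1, tolerance = 1e-9)
  # native region flagged
  expect_equal(sum(el$contours$native), nrow(st$contours))
})

test_that("elongating a straight 20 mm tube degenerates to straight circular segments", {
  st <- tube_stack(r = 10, L = 60, n = 13)
  el <- elongate_contours(st)
  df <- el$contours
  expect_true(all(abs(df$major - 10) < 1e-9))
  expect_true(all(abs(df$cx) < 1e-9 & abs(df$cy) < 1e-9))
  expect_true(all(abs(df$nz - 1) < 1e-9))
  # centerline tangent is G1 across the junctions by construction
  dz <- diff(df$cz)
  expect_true(all(dz > 0))
})

test_that("lumen surface meshing has the contracted topology and sizing", {
  surf <- build_lumen_surface(tube_stack(10, 100, 21), target_edge = 0.8)
  # ~2*pi*10/0.8 = 78.5 circumferential nodes, forced even
  expect_true(abs(surf$n_circ - 79) <= 1)
  expect_equal(surf$n_circ %% 2, 0)
  expect_equal(nrow(surf$quads), (surf$n_rings - 1) * surf$n_circ)
  expect_lt(abs(median_edge_length(surf) / 0.8 - 1), 0.2)
  # outward normals: quad normal dot (node - ring centroid) > 0
  q1 <- surf$quads[1, ]
  p <- surf$nodes[q1, ]
  nrm <- cross3(p[2, ] - p[1, ], p[4, ] - p[1, ])
  centroid <- colMeans(surf$nodes[seq_len(surf$n_circ), ])
  expect_gt(sum(nrm * (p[1, ] - centroid)), 0)
  # too-small contours are rejected
  expect_error(build_lumen_surface(tube_stack(1, 20, 5), target_edge = 0.8),
               ">= 8 circumferential")
})

test_that("wall extrusion produces 2 hex layers with correct offsets and node sets", {
  surf <- build_lumen_surface(tube_stack(10, 40, 9), target_edge = 5)
  mesh <- extrude_wall_mesh(surf, thickness = 2)
  expect_equal(nrow(mesh$hexes), 2 * nrow(surf$quads))
  # straight tube: outer radius = inner + thickness
  r_out <- sqrt(rowSums(mesh$nodes[mesh$node_sets$outer, 1:2]^2))
  expect_equal(range(r_out), c(12, 12), tolerance = 1e-6)
  # five through-thickness sheets, local thickness within 5% of nominal
  d <- sqrt(rowSums((mesh$nodes[mesh$node_sets$outer, ] -
                       mesh$nodes[mesh$node_sets$luminal, ])^2))
  expect_true(all(abs(d / 2 - 1) < 0.05))
  expect_length(mesh$node_sets$inlet, mesh$grid$n_circ * mesh$grid$n_sheet)
  # positive Jacobians at every quadrature point
  a <- aaafsi:::.fem_assemble(mesh$nodes, mesh$hexes,
                              matrix(0, nrow(mesh$nodes), 3), 1, 100, NULL,
                              FALSE, FALSE)
  expect_gt(a$jac_min, 0)
})

test_that("wall mesh invariants hold across random generator seeds", {
  for (seed in 1:20) {
    prof <- default_aaa_profile()
    prof$noise_sd <- 0.3
    case_mesh <- extrude_wall_mesh(build_lumen_surface(
      elongate_contours(generate_synthetic_aaa(prof, seed = seed)),
      target_edge = 6))
    a <- aaafsi:::.fem_assemble(case_mesh$nodes, case_mesh$hexes,
                                matrix(0, nrow(case_mesh$nodes), 3), 1, 100,
                                NULL, FALSE, FALSE)
    expect_gt(a$jac_min, 0)
    d <- sqrt(rowSums((case_mesh$nodes[case_mesh$node_sets$outer, ] -
                         case_mesh$nodes[case_mesh$node_sets$luminal, ])^2))
    expect_true(all(abs(d / 2 - 1) < 0.05))
  }
})

test_that("enclosed volume matches analytic cylinder and sphere values", {
  surf <- build_lumen_surface(tube_stack(10, 100, 21), target_edge = 0.8)
  V <- enclosed_lumen_volume(surf)
  expect_lt(abs(V / (pi * 100 * 100) - 1), 0.005)

  # lat-long sphere fixture, r = 10; rows run south to north so the ring
  # convention matches the tube (ring 1 = "proximal" cap)
  n_th <- 60; n_ph <- 60
  th <- seq(pi - pi / n_th, pi / n_th, length.out = n_th)  # polar, descending
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[seq_len(n_ph)]
  nodes <- do.call(rbind, lapply(th, function(t) {
    cbind(10 * sin(t) * cos(ph), 10 * sin(t) * sin(ph), 10 * cos(t))
  }))
  idx <- function(i, j) (i - 1L) * n_ph + ((j - 1L) %% n_ph) + 1L
  quads <- do.call(rbind, lapply(seq_len(n_th - 1L), function(i) {
    j <- seq_len(n_ph)
    cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
  }))
  Vs <- enclosed_lumen_volume(list(nodes = nodes, quads = quads,
                                   rings = list(seq_len(n_ph),
                                                (n_th - 1L) * n_ph + seq_len(n_ph))))
  expect_lt(abs(Vs / (4 / 3 * pi * 1000) - 1), 0.01)

  # flipped orientation is rejected
  expect_error(enclosed_lumen_volume(list(nodes = nodes,
                                          quads = quads[, 4:1],
                                          rings = list())),
               "orient")
})

test_that("extruded annulus volume matches pi (Ro^2 - Ri^2) L", {
  mesh <- tube_wall_mesh(r = 10, L = 100, target_edge = 1.5)
  # annulus volume via the two closed tubes
  nc <- mesh$grid$n_circ; nax <- mesh$grid$n_ax
  tube_vol <- function(ids) {
    P <- mesh$nodes[ids, ]
    i2 <- function(k, j) (k - 1L) * nc + ((j - 1L) %% nc) + 1L
    quads <- do.call(rbind, lapply(seq_len(nax - 1L), function(k) {
      j <- seq_len(nc)
      cbind(i2(k, j), i2(k, j + 1L), i2(k + 1L, j + 1L), i2(k + 1L, j))
    }))
    enclosed_lumen_volume(list(nodes = P, quads = quads,
                               rings = list(seq_len(nc),
                                            (nax - 1L) * nc + seq_len(nc))))
  }
  V_wall <- tube_vol(mesh$node_sets$outer) - tube_vol(mesh$node_sets$luminal)
  expect_lt(abs(V_wall / (pi * (12^2 - 10^2) * 100) - 1), 0.01)
})

test_that("volume converges under mesh refinement", {
  st <- elongate_contours(generate_synthetic_aaa(default_aaa_profile(), seed = 4))
  exact <- enclosed_lumen_volume(build_lumen_surface(st, target_edge = 1))
  err <- vapply(c(6, 3), function(e) {
    abs(enclosed_lumen_volume(build_lumen_surface(st, target_edge = e)) - exact)
  }, numeric(1))
  expect_lt(err[2], err[1])
})
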