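# Structured meshing of the lumen surface and the two-layer quadratic
# hexahedral wall. The surface grid is ring-structured: a shared, even
# circumferential node count across all rings and axial resampling at the
# target element size, so the wall extrusion yields a clean structured grid
# of 27-node triquadratic hexahedra.

ellipse_perimeter <- function(a, b) {
  # Ramanujan approximation, ample for sizing the circumferential grid
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# sample ring parameters (center, radii, rotation, frame) at given stations
resample_rings <- function(stack, stations) {
  df <- stack$contours
  s <- df$station
  sp <- function(y) stats::splinefun(s, y, method = "natural")
  fx <- sp(df$cx); fy <- sp(df$cy); fz <- sp(df$cz)
  # ellipse orientation is pi-periodic: unwrap it onto a continuous branch
  # before interpolating, so parametrization twist stays minimal
  rot <- df$rot
  for (k in seq_along(rot)[-1]) {
    rot[k] <- rot[k] - pi * round((rot[k] - rot[k - 1]) / pi)
  }
  fa <- sp(df$major); fb <- sp(df$minor); fr <- sp(rot)
  fn <- stats::approxfun(s, as.numeric(df$native), rule = 2)
  C <- cbind(fx(stations), fy(stations), fz(stations))
  Tn <- cbind(fx(stations, deriv = 1), fy(stations, deriv = 1), fz(stations, deriv = 1))
  Tn <- Tn / sqrt(rowSums(Tn^2))
  # parallel-transported frame (u, v) perpendicular to the tangent
  n <- length(stations)
  U <- matrix(0, n, 3); V <- matrix(0, n, 3)
  u <- c(1, 0, 0)
  u <- u - sum(u * Tn[1, ]) * Tn[1, ]
  if (sqrt(sum(u^2)) < 1e-6) {
    u <- c(0, 1, 0); u <- u - sum(u * Tn[1, ]) * Tn[1, ]
  }
  u <- u / sqrt(sum(u^2))
  for (k in seq_len(n)) {
    if (k > 1) {
      u <- u - sum(u * Tn[k, ]) * Tn[k, ]
      u <- u / sqrt(sum(u^2))
    }
    U[k, ] <- u
    tt <- Tn[k, ]
    V[k, ] <- c(tt[2] * u[3] - tt[3] * u[2],   # v = t x u keeps (u, v, t) right-handed
                tt[3] * u[1] - tt[1] * u[3],
                tt[1] * u[2] - tt[2] * u[1])
  }
  list(station = stations, center = C, a = pmax(fa(stations), 1e-6),
       b = pmax(fb(stations), 1e-6), rot = fr(stations), t = Tn, u = U, v = V,
       native = fn(stations) > 0.5)
}

ring_points <- function(rings, k, theta) {
  a <- rings$a[k]; b <- rings$b[k]; phi <- rings$rot[k]
  u <- rings$u[k, ]; v <- rings$v[k, ]
  e1 <- cos(phi) * u + sin(phi) * v
  e2 <- -sin(phi) * u + cos(phi) * v
  rep(rings$center[k, ], each = length(theta)) +
    outer(a * cos(theta), e1) + outer(b * sin(theta), e2)
}

#' Build the structured quadrangular lumen surface mesh
#'
#' Resamples an (elongated) contour stack axially and circumferentially so
#' the median quad edge is close to `target_edge`, and connects consecutive
#' rings with quadrangular faces with consistent outward normals. The
#' circumferential node count is even and shared by all rings.
#'
#' @param stack an elongated `contour_stack`.
#' @param target_edge target element edge length, mm (default 0.8).
#' @return a `lumen_surface` with fields `nodes` (mm), `quads` (1-based,
#'   outward-oriented), `ring_index`, `n_rings`, `n_circ`, per-ring
#'   `stations` and `native` flags, plus a double-resolution `fine` grid
#'   used by the wall extrusion.
#' @export
build_lumen_surface <- function(stack, target_edge = 0.8) {
  df <- stack$contours
  per <- ellipse_perimeter(df$major, df$minor)
  if (any(per / target_edge < 8)) {
    stop("a contour is too small to carry >= 8 circumferential nodes at target_edge")
  }
  M <- round(stats::median(per) / target_edge)
  M <- max(8L, 2L * round(M / 2))
  total <- diff(range(df$station))
  N <- max(3L, round(total / target_edge) + 1L)

  stations <- seq(min(df$station), max(df$station), length.out = N)
  fine_stations <- seq(min(df$station), max(df$station), length.out = 2L * N - 1L)
  rings_f <- resample_rings(stack, fine_stations)
  theta_f <- seq(0, 2 * pi, length.out = 2L * M + 1L)[seq_len(2L * M)]

  nodes_f <- matrix(NA_real_, (2L * N - 1L) * 2L * M, 3)
  for (k in seq_len(2L * N - 1L)) {
    nodes_f[(k - 1L) * 2L * M + seq_len(2L * M), ] <- ring_points(rings_f, k, theta_f)
  }
  # coarse surface = every other fine node
  coarse_lev <- seq(1L, 2L * N - 1L, by = 2L)
  coarse_circ <- seq(1L, 2L * M, by = 2L)
  idx <- as.vector(t(outer((coarse_lev - 1L) * 2L * M, coarse_circ, "+")))
  nodes <- nodes_f[idx, , drop = FALSE]

  quads <- matrix(NA_integer_, (N - 1L) * M, 4)
  q <- 1L
  for (k in seq_len(N - 1L)) {
    for (j in seq_len(M)) {
      jp <- if (j == M) 1L else j + 1L
      quads[q, ] <- c((k - 1L) * M + j, (k - 1L) * M + jp,
                      k * M + jp, k * M + j)
      q <- q + 1L
    }
  }
  structure(list(
    nodes = nodes, quads = quads,
    ring_index = rep(seq_len(N), each = M),
    n_rings = N, n_circ = M, target_edge = target_edge,
    stations = stations, native = rings_f$native[coarse_lev],
    fine = list(nodes = nodes_f, n_ax = 2L * N - 1L, n_circ = 2L * M,
                stations = fine_stations, native = rings_f$native,
                centers = rings_f$center, tangents = rings_f$t)
  ), class = "lumen_surface")
}

#' @export
print.lumen_surface <- function(x, ...) {
  cat(sprintf("Lumen surface mesh: %d rings x %d nodes, %d quads (target edge %.2f mm)\n",
              x$n_rings, x$n_circ, nrow(x$quads), x$target_edge))
  invisible(x)
}

#' Median edge length of a lumen surface mesh
#' @param surface a `lumen_surface`.
#' @return median quad edge length in mm.
#' @export
median_edge_length <- function(surface) {
  n <- surface$nodes; q <- surface$quads
  e <- rbind(cbind(q[, 1], q[, 2]), cbind(q[, 2], q[, 3]),
             cbind(q[, 3], q[, 4]), cbind(q[, 4], q[, 1]))
  stats::median(sqrt(rowSums((n[e[, 1], ] - n[e[, 2], ])^2)))
}

# outward unit normals of the fine surface grid by averaging cell normals;
# a few Laplacian smoothing passes keep the extrusion direction from
# flipping sign across local surface wiggles (which would invert elements)
fine_surface_normals <- function(fine, smooth_passes = 3L) {
  nax <- fine$n_ax; nc <- fine$n_circ
  P <- fine$nodes
  idx <- function(k, j) (k - 1L) * nc + ((j - 1L) %% nc) + 1L
  N <- matrix(0, nrow(P), 3)
  for (k in seq_len(nax)) {
    km <- max(1L, k - 1L); kp <- min(nax, k + 1L)
    j <- seq_len(nc)
    e_ax <- P[idx(kp, j), , drop = FALSE] - P[idx(km, j), , drop = FALSE]
    e_th <- P[idx(k, j + 1L), , drop = FALSE] - P[idx(k, j - 1L), , drop = FALSE]
    nrm <- cbind(e_th[, 2] * e_ax[, 3] - e_th[, 3] * e_ax[, 2],
                 e_th[, 3] * e_ax[, 1] - e_th[, 1] * e_ax[, 3],
                 e_th[, 1] * e_ax[, 2] - e_th[, 2] * e_ax[, 1])
    N[idx(k, j), ] <- nrm / sqrt(rowSums(nrm^2))
  }
  for (pass in seq_len(smooth_passes)) {
    Ns <- N
    for (k in seq_len(nax)) {
      km <- max(1L, k - 1L); kp <- min(nax, k + 1L)
      j <- seq_len(nc)
      Ns[idx(k, j), ] <- N[idx(k, j), ] +
        N[idx(km, j), ] + N[idx(kp, j), ] +
        N[idx(k, j + 1L), ] + N[idx(k, j - 1L), ]
    }
    N <- Ns / sqrt(rowSums(Ns^2))
  }
  N
}

#' Extrude the lumen surface into a quadratic hexahedral wall mesh
#'
#' Offsets the lumen surface along its outward normals and builds `layers`
#' through-thickness layers of 27-node triquadratic hexahedra (structured
#' extrusion, so 5 through-thickness node sheets for 2 layers). Node sets
#' for the luminal surface, outer surface and the inlet/outlet rings are
#' populated, together with per-node axial stations used by the FSI
#' interface and the AAA-region metric mask.
#'
#' @param surface a `lumen_surface`.
#' @param thickness wall thickness, mm (default 2, split equally over layers).
#' @param layers number of element layers through the thickness (default 2).
#' @return a `wall_mesh` with `nodes` (mm), `hexes` (n_el x 27, 1-based,
#'   local ordering lexicographic in circumferential/axial/thickness),
#'   `node_sets`, `luminal_faces` (9-node faces with axial station and fine
#'   axial level), and grid bookkeeping.
#' @export
extrude_wall_mesh <- function(surface, thickness = 2, layers = 2L) {
  stopifnot(layers == 2L)  # two quadratic layers = 5 node sheets
  fine <- surface$fine
  nax <- fine$n_ax; nc <- fine$n_circ
  n_sheet <- 2L * layers + 1L
  nrm <- fine_surface_normals(fine)
  npx <- nax * nc
  nodes <- matrix(NA_real_, npx * n_sheet, 3)
  for (l in seq_len(n_sheet)) {
    off <- thickness * (l - 1L) / (n_sheet - 1L)
    nodes[(l - 1L) * npx + seq_len(npx), ] <- fine$nodes + off * nrm
  }
  nid <- function(l, k, j) (l - 1L) * npx + (k - 1L) * nc + ((j - 1L) %% nc) + 1L

  Nel_ax <- (nax - 1L) %/% 2L
  Nel_c <- nc %/% 2L
  n_el <- Nel_ax * Nel_c * layers
  hexes <- matrix(NA_integer_, n_el, 27)
  el_station <- numeric(n_el)
  el_native <- logical(n_el)
  e <- 1L
  for (lay in seq_len(layers)) {
    l0 <- 2L * (lay - 1L) + 1L
    for (ke in seq_len(Nel_ax)) {
      k0 <- 2L * ke - 1L
      for (je in seq_len(Nel_c)) {
        j0 <- 2L * je - 1L
        m <- 1L
        conn <- integer(27)
        for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
          conn[m] <- nid(l0 + dk, k0 + dj, j0 + di)
          m <- m + 1L
        }
        hexes[e, ] <- conn
        el_station[e] <- fine$stations[k0 + 1L]
        el_native[e] <- fine$native[k0 + 1L]
        e <- e + 1L
      }
    }
  }

  # luminal 9-node faces (one per surface element footprint, sheet 1)
  n_face <- Nel_ax * Nel_c
  faces <- matrix(NA_integer_, n_face, 9)
  face_level <- integer(n_face)
  f <- 1L
  for (ke in seq_len(Nel_ax)) {
    k0 <- 2L * ke - 1L
    for (je in seq_len(Nel_c)) {
      j0 <- 2L * je - 1L
      m <- 1L
      for (dj in 0:2) for (di in 0:2) {
        faces[f, m] <- nid(1L, k0 + dj, j0 + di)
        m <- m + 1L
      }
      face_level[f] <- k0 + 1L
      f <- f + 1L
    }
  }

  all_sheets <- seq_len(n_sheet)
  node_sets <- list(
    luminal = seq_len(npx),
    outer = (n_sheet - 1L) * npx + seq_len(npx),
    inlet = as.vector(outer(seq_len(nc), (all_sheets - 1L) * npx, "+")),
    outlet = as.vector(outer((nax - 1L) * nc + seq_len(nc), (all_sheets - 1L) * npx, "+"))
  )
  node_station <- rep(rep(fine$stations, each = nc), times = n_sheet)
  node_native <- rep(rep(fine$native, each = nc), times = n_sheet)

  structure(list(
    nodes = nodes, hexes = hexes, thickness = thickness, layers = layers,
    node_sets = node_sets,
    luminal_faces = faces, face_level = face_level,
    face_station = fine$stations[face_level],
    face_native = fine$native[face_level],
    node_station = node_station, node_native = node_native,
    grid = list(n_ax = nax, n_circ = nc, n_sheet = n_sheet, npx = npx),
    fine_stations = fine$stations, fine_native = fine$native,
    centers = fine$centers, tangents = fine$tangents,
    el_station = el_station, el_native = el_native
  ), class = "wall_mesh")
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat(sprintf("Wall mesh: %d nodes, %d triquadratic hexahedra (%d layers, thickness %.1f mm)\n",
              nrow(x$nodes), nrow(x$hexes), x$layers, x$thickness))
  invisible(x)
}

#' Luminal ring node indices of a wall mesh
#'
#' One ordered circumferential loop of luminal nodes per fine axial level.
#'
#' @param mesh a `wall_mesh`.
#' @return list of integer vectors (1-based node ids).
#' @export
luminal_rings <- function(mesh) {
  nc <- mesh$grid$n_circ
  lapply(seq_len(mesh$grid$n_ax), function(k) (k - 1L) * nc + seq_len(nc))
}

# planar polygon area of an ordered 3D loop (Newell's method)
polygon_area3 <- function(P) {
  Q <- rbind(P, P[1, ])
  n <- colSums(cbind(
    Q[-nrow(Q), 2] * Q[-1, 3] - Q[-nrow(Q), 3] * Q[-1, 2],
    Q[-nrow(Q), 3] * Q[-1, 1] - Q[-nrow(Q), 1] * Q[-1, 3],
    Q[-nrow(Q), 1] * Q[-1, 2] - Q[-nrow(Q), 2] * Q[-1, 1]))
  sqrt(sum(n^2)) / 2
}

#' Luminal cross-sectional areas along the vessel
#'
#' Polygon areas of the (possibly displaced) luminal node rings, one per
#' fine axial level. This is the wall-side interface field of the FSI
#' coupling.
#'
#' @param mesh a `wall_mesh`.
#' @param displacement optional n_nodes x 3 displacement (mm).
#' @return numeric vector of areas (mm^2).
#' @export
luminal_areas <- function(mesh, displacement = NULL) {
  P <- mesh$nodes
  if (!is.null(displacement)) P <- P + displacement
  vapply(luminal_rings(mesh), function(ids) polygon_area3(P[ids, , drop = FALSE]),
         numeric(1))
}

#' Enclosed volume of a closed tubular surface
#'
#' Caps the two boundary rings with centroid fans and evaluates the volume
#' by the divergence theorem over the oriented triangulated surface. A
#' non-positive result signals inconsistent face orientation and is
#' rejected.
#'
#' @param surface a `lumen_surface`, a `wall_mesh` (its luminal surface is
#'   used), or a list with `nodes`, `quads` and `rings` (two ordered node
#'   loops to cap, first = proximal).
#' @param displacement optional nodal displacement (mm) applied before the
#'   volume is computed (wall meshes: full mesh displacement).
#' @return enclosed volume, mm^3.
#' @export
enclosed_lumen_volume <- function(surface, displacement = NULL) {
  if (inherits(surface, "wall_mesh")) {
    nc <- surface$grid$n_circ; nax <- surface$grid$n_ax
    P <- surface$nodes
    if (!is.null(displacement)) P <- P + displacement
    P <- P[surface$node_sets$luminal, , drop = FALSE]
    idx <- function(k, j) (k - 1L) * nc + ((j - 1L) %% nc) + 1L
    quads <- do.call(rbind, lapply(seq_len(nax - 1L), function(k) {
      j <- seq_len(nc)
      cbind(idx(k, j), idx(k, j + 1L), idx(k + 1L, j + 1L), idx(k + 1L, j))
    }))
    rings <- list(seq_len(nc), (nax - 1L) * nc + seq_len(nc))
  } else if (inherits(surface, "lumen_surface")) {
    P <- surface$nodes
    if (!is.null(displacement)) P <- P + displacement
    quads <- surface$quads
    M <- surface$n_circ
    rings <- list(seq_len(M), (surface$n_rings - 1L) * M + seq_len(M))
  } else {
    P <- surface$nodes; quads <- surface$quads; rings <- surface$rings
    if (!is.null(displacement)) P <- P + displacement
  }
  tri_vol <- function(a, b, c) {
    (P[a, 1] * (P[b, 2] * P[c, 3] - P[b, 3] * P[c, 2]) -
       P[a, 2] * (P[b, 1] * P[c, 3] - P[b, 3] * P[c, 1]) +
       P[a, 3] * (P[b, 1] * P[c, 2] - P[b, 2] * P[c, 1])) / 6
  }
  V <- sum(tri_vol(quads[, 1], quads[, 2], quads[, 3])) +
    sum(tri_vol(quads[, 1], quads[, 3], quads[, 4]))
  for (side in seq_along(rings)) {
    ids <- rings[[side]]
    cen <- colMeans(P[ids, , drop = FALSE])
    P <- rbind(P, cen)
    ci <- nrow(P)
    jp <- c(ids[-1], ids[1])
    V <- V + if (side == 1) sum(tri_vol(rep(ci, length(ids)), jp, ids))
    else sum(tri_vol(rep(ci, length(ids)), ids, jp))
  }
  if (V <= 0) stop("surface is not consistently outward-oriented (non-positive volume)")
  V
}
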