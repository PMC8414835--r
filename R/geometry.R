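# Synthetic AAA lumen geometry as stacked elliptical contours along a curved
# centerline. This emulates the output of an automated ultrasound lumen
# segmentation at the diastolic frame: one planar, possibly elliptical
# contour per axial station.
#
# Conventions: right-handed global frame, z = longitudinal ("spine") axis,
# units mm. Axial stations are arc length along the centerline measured from
# the proximal end.

new_contour_stack <- function(df, spacing, frame_label = "diastole") {
  stopifnot(all(c("station", "cx", "cy", "cz", "major", "minor", "rot",
                  "nx", "ny", "nz", "native") %in% names(df)))
  if (any(diff(df$station) <= 0)) stop("axial stations must be strictly increasing")
  if (any(df$major < df$minor) || any(df$minor <= 0)) {
    stop("contour radii must satisfy major >= minor > 0")
  }
  nrm <- sqrt(df$nx^2 + df$ny^2 + df$nz^2)
  if (any(abs(nrm - 1) > 1e-9)) stop("contour normals must be unit vectors")
  structure(list(contours = df, spacing = spacing, frame_label = frame_label),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  d <- max_diameter_and_group(x, native_only = FALSE)
  cat(sprintf("Contour stack (%s): %d contours, arc length %.1f mm, max diameter %.1f mm\n",
              x$frame_label, nrow(x$contours), diff(range(x$contours$station)), d$d_max))
  invisible(x)
}

#' Generate a synthetic AAA contour-stack segmentation
#'
#' Produces an ordered stack of planar elliptical lumen contours along a
#' curved centerline, emulating an automated 3D ultrasound segmentation of a
#' fusiform AAA at the diastolic frame. The dilation follows a smooth
#' cosine-squared bulge between two straight neck segments; `asymmetry`
#' shifts the bulge anteriorly (+x) as real AAA sacs do, and
#' `centerline_bow` bows the centerline in the x-z plane.
#'
#' @param profile list with fields `max_diameter` (mm), `neck_diameter`
#'   (mm), `sac_length` (mm), `asymmetry` (fraction of local dilation
#'   converted to anterior offset), `centerline_bow` (mm), `n_contours`
#'   (>= 5), `noise_sd` (mm, per-radius Gaussian jitter). Missing fields
#'   take the defaults of [default_aaa_profile()].
#' @param seed integer seed; the same profile and seed give byte-identical
#'   stacks.
#' @return a `contour_stack` whose maximum diameter equals
#'   `profile$max_diameter` up to the contour noise.
#' @export
generate_synthetic_aaa <- function(profile = default_aaa_profile(), seed = 1L) {
  p <- utils::modifyList(default_aaa_profile(), profile)
  if (!(p$max_diameter > p$neck_diameter && p$neck_diameter > 0)) {
    stop("non-physical profile: need max_diameter > neck_diameter > 0")
  }
  if (p$n_contours < 5) stop("need at least 5 contours")
  if (p$sac_length <= 0 || p$noise_sd < 0) stop("non-physical profile")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  neck_len <- 10                       # straight neck on each side, mm
  L <- p$sac_length + 2 * neck_len
  s <- seq(0, L, length.out = p$n_contours)
  r_neck <- p$neck_diameter / 2
  r_max <- p$max_diameter / 2
  shat <- (s - L / 2) / (p$sac_length / 2)
  bump <- ifelse(abs(shat) <= 1, cos(pi * shat / 2)^2, 0)
  r <- r_neck + (r_max - r_neck) * bump

  cx <- p$centerline_bow * sin(pi * s / L) + p$asymmetry * (r - r_neck)
  cy <- rep(0, length(s))
  cz <- s

  # segmentation jitter is axially correlated (the tracking filter smooths
  # frame-to-frame output); a 3-contour moving average emulates that and
  # keeps the stack free of single-contour spikes
  smooth_noise <- function(n, sd) {
    e <- stats::rnorm(n + 2, sd = sd)
    (e[1:n] + e[2:(n + 1)] + e[3:(n + 2)]) / sqrt(3)
  }
  major <- r + if (p$noise_sd > 0) smooth_noise(length(s), p$noise_sd) else 0
  minor <- r + if (p$noise_sd > 0) smooth_noise(length(s), p$noise_sd) else 0
  swap <- major < minor
  tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  minor <- pmax(minor, 0.25 * r_neck)
  major <- pmax(major, minor)
  if (p$noise_sd > 0) {
    # enforce the generator contract: the realized maximum diameter deviates
    # from the profile value by at most noise_sd (truncated jitter)
    dev <- max(-p$noise_sd, min(p$noise_sd, stats::rnorm(1, sd = p$noise_sd / 2)))
    sfac <- (p$max_diameter + dev) / (2 * max(major))
    major <- major * sfac
    minor <- minor * sfac
  }
  # small orientation wobble: ellipse orientation of a near-circular lumen
  # is weakly determined, and large contour-to-contour twist would shear the
  # structured surface grid
  rot <- if (p$noise_sd > 0) stats::rnorm(length(s), sd = 0.15) else rep(0, length(s))

  # centerline tangents by centered differences on the center curve
  C <- cbind(cx, cy, cz)
  Tn <- rbind(C[2, ] - C[1, ],
              (C[-(1:2), , drop = FALSE] - C[1:(nrow(C) - 2), , drop = FALSE]) / 2,
              C[nrow(C), ] - C[nrow(C) - 1, ])
  Tn <- Tn / sqrt(rowSums(Tn^2))

  station <- c(0, cumsum(sqrt(rowSums(diff(C)^2))))
  df <- data.frame(station = station, cx = cx, cy = cy, cz = cz,
                   major = major, minor = minor, rot = rot,
                   nx = Tn[, 1], ny = Tn[, 2], nz = Tn[, 3],
                   native = TRUE)
  new_contour_stack(df, spacing = mean(diff(station)))
}

#' Default synthetic AAA profile
#'
#' Moderate-size fusiform AAA with mild anterior asymmetry and centerline
#' bow, representative of the middle of the study cohort (maximum diameter
#' 45 mm, sac length 70 mm, necks of native diameter 22 mm).
#'
#' @return a named list usable as `profile` in [generate_synthetic_aaa()].
#' @export
default_aaa_profile <- function() {
  list(max_diameter = 45, neck_diameter = 22, sac_length = 70,
       asymmetry = 0.35, centerline_bow = 8, n_contours = 37, noise_sd = 0)
}

#' Maximum diameter and size group of a contour stack
#'
#' The maximum diameter is the largest in-plane chord over all contours
#' (twice the major radius). Size groups follow the clinical cut-offs:
#' small (S) <= 39 mm, moderate (M) 40-49 mm, large (L) >= 50 mm.
#'
#' @param stack a `contour_stack` (native, pre-elongation).
#' @param native_only if `TRUE` (default) only native (non-extension)
#'   contours are considered.
#' @return list with `d_max` (mm) and `group` (`"S"`, `"M"` or `"L"`).
#' @export
max_diameter_and_group <- function(stack, native_only = TRUE) {
  df <- stack$contours
  if (native_only && any(df$native)) df <- df[df$native, ]
  d_max <- 2 * max(df$major)
  group <- diameter_group(d_max)
  list(d_max = d_max, group = group)
}

#' @rdname max_diameter_and_group
#' @param d_max maximum diameter in mm.
#' @export
diameter_group <- function(d_max) {
  if (d_max < 40) "S" else if (d_max < 50) "M" else "L"
}

# cubic Bezier point and derivative
bezier3 <- function(P0, P1, P2, P3, t) {
  u <- 1 - t
  outer(u^3, P0) + outer(3 * u^2 * t, P1) + outer(3 * u * t^2, P2) + outer(t^3, P3)
}
bezier3_d <- function(P0, P1, P2, P3, t) {
  u <- 1 - t
  outer(3 * u^2, P1 - P0) + outer(6 * u * t, P2 - P1) + outer(3 * t^2, P3 - P2)
}

bezier_arclength <- function(P0, P1, P2, P3, n = 200) {
  t <- seq(0, 1, length.out = n)
  pts <- bezier3(P0, P1, P2, P3, t)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# One elongation: a cubic Bezier blend that turns the end tangent into the
# target direction over `blend_len` of arc length, followed by a straight
# circular segment so the total added arc length is exactly `length`.
elongate_one_end <- function(end_row, tangent_out, target_dir, length, end_radius,
                             blend_len, spacing) {
  target_dir <- target_dir / sqrt(sum(target_dir^2))
  ct <- sum(tangent_out * target_dir)
  if (ct < 1e-6) {
    stop("end tangent is orthogonal (or opposed) to the requested extension direction")
  }
  P0 <- c(end_row$cx, end_row$cy, end_row$cz)
  straight <- ct > 1 - 1e-10

  if (straight) {
    centers_fun <- function(s) outer(s, tangent_out) + rep(P0, each = length(s))
    tangents_fun <- function(s) matrix(tangent_out, length(s), 3, byrow = TRUE)
    blen <- blend_len
  } else {
    # scale the control offset so the blend arc length hits blend_len
    make <- function(scale) {
      P3 <- P0 + scale * (blend_len / 2) * (tangent_out + target_dir)
      list(P0 = P0, P1 = P0 + scale * (blend_len / 3) * tangent_out,
           P2 = P3 - scale * (blend_len / 3) * target_dir, P3 = P3)
    }
    f <- function(scale) {
      b <- make(scale)
      bezier_arclength(b$P0, b$P1, b$P2, b$P3) - blend_len
    }
    scale <- stats::uniroot(f, c(0.3, 3), tol = 1e-10)$root
    b <- make(scale)
    # arc-length parametrization of the Bezier
    tt <- seq(0, 1, length.out = 400)
    pts <- bezier3(b$P0, b$P1, b$P2, b$P3, tt)
    al <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    blen <- al[length(al)]
    t_of_s <- stats::approxfun(al, tt)
    centers_fun <- function(s) {
      t <- t_of_s(pmin(s, blen))
      bezier3(b$P0, b$P1, b$P2, b$P3, t)
    }
    tangents_fun <- function(s) {
      t <- t_of_s(pmin(s, blen))
      d <- bezier3_d(b$P0, b$P1, b$P2, b$P3, t)
      d / sqrt(rowSums(d^2))
    }
  }

  n_new <- max(2L, ceiling(length / spacing))
  s_new <- seq(0, length, length.out = n_new + 1)[-1]  # exclude junction
  in_blend <- s_new <= blen
  centers <- matrix(NA_real_, length(s_new), 3)
  tangents <- centers
  centers[in_blend, ] <- centers_fun(s_new[in_blend])
  tangents[in_blend, ] <- tangents_fun(s_new[in_blend])
  if (any(!in_blend)) {
    Pend <- centers_fun(blen)[1, ]
    dir_end <- if (straight) tangent_out else target_dir
    centers[!in_blend, ] <- outer(s_new[!in_blend] - blen, dir_end) +
      rep(Pend, each = sum(!in_blend))
    tangents[!in_blend, ] <- matrix(dir_end, sum(!in_blend), 3, byrow = TRUE)
  }

  # contour shape blends linearly along the blend, circular beyond it
  w <- pmin(s_new / blen, 1)
  data.frame(station = s_new,
             cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
             major = (1 - w) * end_row$major + w * end_radius,
             minor = (1 - w) * end_row$minor + w * end_radius,
             rot = (1 - w) * end_row$rot,
             nx = tangents[, 1], ny = tangents[, 2], nz = tangents[, 3],
             native = FALSE)
}

#' Elongate a contour stack at both ends
#'
#' Extends the segmentation by `length` mm of arc length proximally and
#' distally so boundary conditions act far from the aneurysm sac. The
#' proximal extension turns the vessel parallel to the spine (global z
#' axis) and the distal extension continues along the local centerline
#' direction; both use a cubic Bezier blend (G1-continuous at the junction)
#' followed by a straight segment. Contour shape blends linearly to a
#' circle of diameter `end_diameter` along the blend.
#'
#' @param stack a native `contour_stack` with at least two contours.
#' @param length added arc length per end, mm (default 50).
#' @param end_diameter terminal circular diameter, mm (default 20).
#' @param blend_len arc length of the Bezier blend region, mm.
#' @return the elongated `contour_stack`; extension contours are flagged
#'   `native = FALSE`.
#' @export
elongate_contours <- function(stack, length = 50, end_diameter = 20,
                              blend_len = 20) {
  df <- stack$contours
  if (nrow(df) < 2) stop("need at least 2 contours to elongate")
  blend_len <- min(blend_len, 0.9 * length)
  er <- end_diameter / 2

  first <- df[1, ]; last <- df[nrow(df), ]
  t_first <- c(first$nx, first$ny, first$nz)     # points distally
  t_last <- c(last$nx, last$ny, last$nz)

  prox <- elongate_one_end(first, tangent_out = -t_first,
                           target_dir = c(0, 0, -1), length = length,
                           end_radius = er, blend_len = blend_len,
                           spacing = stack$spacing)
  dist <- elongate_one_end(last, tangent_out = t_last,
                           target_dir = t_last, length = length,
                           end_radius = er, blend_len = blend_len,
                           spacing = stack$spacing)

  # proximal rows run outward from the junction; reverse and re-station.
  prox <- prox[rev(seq_len(nrow(prox))), ]
  prox$station <- length - prox$station
  # proximal contour normals should point distally (along the vessel)
  prox[, c("nx", "ny", "nz")] <- -prox[, c("nx", "ny", "nz")]
  mid <- df
  mid$station <- mid$station + length
  dist$station <- dist$station + max(mid$station)
  out <- rbind(prox, mid, dist)
  rownames(out) <- NULL
  new_contour_stack(out, spacing = stack$spacing, frame_label = stack$frame_label)
}
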