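# Neo-Hookean wall material: constitutively linear, geometrically nonlinear.
# The vessel wall is treated as isotropic and incompressible; numerically the
# incompressibility constraint is imposed by a volumetric penalty with
# Poisson ratio just below 0.5.

#' Wall material definition
#'
#' Creates a Neo-Hookean material for the AAA wall. The wall is modeled as
#' isotropic and incompressible; numerically a nearly-incompressible penalty
#' formulation is used with `nu` (default 0.499) and a bulk modulus
#' `kappa = 2*G*(1 + nu) / (3*(1 - 2*nu))` derived from the shear modulus.
#'
#' @param G shear modulus in MPa.
#' @param nu numerical Poisson ratio, in `[0.45, 0.5)`.
#' @return an object of class `aaa_material` with fields `G` (MPa), `nu`,
#'   `E` (MPa, `2*G*(1+nu)`) and `kappa` (MPa).
#' @export
#' @examples
#' wall_material(0.92)
wall_material <- function(G, nu = 0.499) {
  stopifnot(is.numeric(G), length(G) == 1, G > 0)
  if (nu < 0.45 || nu >= 0.5) {
    stop("numerical Poisson ratio must lie in [0.45, 0.5)")
  }
  structure(list(
    G = G, nu = nu,
    E = 2 * G * (1 + nu),
    kappa = 2 * G * (1 + nu) / (3 * (1 - 2 * nu))
  ), class = "aaa_material")
}

#' @export
print.aaa_material <- function(x, ...) {
  cat(sprintf("Neo-Hookean wall material: G = %.3f MPa, nu = %.4f, E = %.3f MPa, kappa = %.1f MPa\n",
              x$G, x$nu, x$E, x$kappa))
  invisible(x)
}

#' Group shear modulus by maximum AAA diameter
#'
#' Assigns the diameter-group shear modulus used for the wall: 0.92 MPa for
#' small (S, max diameter <= 39 mm), 1.02 MPa for moderate (M, 40-49 mm) and
#' 1.36 MPa for large (L, >= 50 mm) aneurysms.
#'
#' @param group one of `"S"`, `"M"`, `"L"`.
#' @param nu numerical Poisson ratio passed to [wall_material()].
#' @return an `aaa_material`.
#' @export
assign_shear_modulus <- function(group, nu = 0.499) {
  group <- match.arg(group, c("S", "M", "L"))
  G <- c(S = 0.92, M = 1.02, L = 1.36)[[group]]
  wall_material(G, nu = nu)
}

#' Neo-Hookean Cauchy stress
#'
#' Evaluates the incompressible Neo-Hookean constitutive relation
#' `sigma = -p*I + G*(B - I)` with `B = F %*% t(F)` the left Cauchy-Green
#' deformation tensor. When `p` is not supplied, the volumetric penalty
#' `p = -kappa * log(det F) / det F` is used, which recovers the
#' incompressible Lagrange-multiplier pressure in the limit `nu -> 0.5`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param G shear modulus (stress units of the result).
#' @param p pressure-like term; default is the penalty expression.
#' @param nu numerical Poisson ratio used for the penalty bulk modulus.
#' @return symmetric 3x3 Cauchy stress in the units of `G`.
#' @export
#' @examples
#' neo_hookean_cauchy(diag(3), G = 1)            # zero stress
#' Fs <- diag(3); Fs[1, 2] <- 0.1                # simple shear
#' neo_hookean_cauchy(Fs, G = 1, p = 0)[1, 2]    # = G * gamma
neo_hookean_cauchy <- function(F, G, p = NULL, nu = 0.499) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  if (is.null(p)) {
    kappa <- 2 * G * (1 + nu) / (3 * (1 - 2 * nu))
    p <- -kappa * log(J) / J
  }
  B <- F %*% t(F)
  s <- -p * diag(3) + G * (B - diag(3))
  (s + t(s)) / 2
}

#' Von Mises equivalent stress
#'
#' `sqrt(3/2 * dev(sigma) : dev(sigma))` for one or more symmetric stress
#' tensors.
#'
#' @param stress either a symmetric 3x3 matrix or an `n x 6` matrix of Voigt
#'   components ordered `(xx, yy, zz, xy, yz, xz)`.
#' @return scalar (matrix input) or length-`n` vector of equivalent stress.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    if (max(abs(stress - t(stress))) > 1e-9 * max(1, max(abs(stress)))) {
      stop("stress tensor must be symmetric")
    }
    stress <- matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                       stress[1, 2], stress[2, 3], stress[1, 3]), nrow = 1)
  }
  stopifnot(ncol(stress) == 6)
  m <- (stress[, 1] + stress[, 2] + stress[, 3]) / 3
  d1 <- stress[, 1] - m; d2 <- stress[, 2] - m; d3 <- stress[, 3] - m
  sqrt(pmax(0, 1.5 * (d1^2 + d2^2 + d3^2 +
                        2 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))))
}
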