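#' One-term Ogden hyperelastic material
#'
#' Isotropic strain-energy density in principal stretches,
#' \deqn{W = \frac{2\mu}{\alpha^2}\left(\bar\lambda_1^\alpha +
#'   \bar\lambda_2^\alpha + \bar\lambda_3^\alpha - 3\right) +
#'   \frac{\kappa}{2}(J-1)^2,}
#' with isochoric stretches \eqn{\bar\lambda_i = J^{-1/3}\lambda_i},
#' \eqn{J = \lambda_1\lambda_2\lambda_3}.  \eqn{\mu} is the shear modulus
#' (kPa), \eqn{\alpha} the dimensionless nonlinearity, and \eqn{\kappa}
#' (`bulk_penalty`) a volumetric penalty modulus used only by the finite
#' element solver to enforce near-incompressibility.
#'
#' @param mu shear modulus in kPa, > 0.
#' @param alpha dimensionless nonlinearity exponent, nonzero.
#' @param bulk_penalty volumetric penalty modulus in kPa; must be at least
#'   `10 * mu`.  Default `100 * mu` (approximately Poisson ratio 0.495).
#' @return An object of class `ogden_material`.
#' @examples
#' mat <- ogden_material(32.8, 8.22)
#' uniaxial_nominal_stress(1.06, mat)
#' @export
ogden_material <- function(mu, alpha, bulk_penalty = 100 * mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(bulk_penalty), length(bulk_penalty) == 1L)
  if (mu <= 0) stop("shear modulus `mu` must be positive")
  if (alpha == 0) stop("`alpha` must be nonzero")
  if (bulk_penalty < 10 * mu)
    stop("`bulk_penalty` must be at least 10 * mu for near-incompressibility")
  structure(list(mu = mu, alpha = alpha, bulk_penalty = bulk_penalty),
            class = "ogden_material")
}

#' @export
print.ogden_material <- function(x, ...) {
  cat(sprintf("Ogden material: mu = %g kPa, alpha = %g, bulk penalty = %g kPa\n",
              x$mu, x$alpha, x$bulk_penalty))
  invisible(x)
}

#' Ogden strain-energy density
#'
#' Evaluates the decoupled isochoric + volumetric strain energy at a triple
#' of principal stretches.
#'
#' @param stretches numeric vector of three positive principal stretches.
#' @param mat an [ogden_material()].
#' @return Energy density in kPa.
#' @export
ogden_energy <- function(stretches, mat) {
  stopifnot(inherits(mat, "ogden_material"),
            is.numeric(stretches), length(stretches) == 3L)
  if (any(!is.finite(stretches)) || any(stretches <= 0))
    stop("principal stretches must be positive and finite")
  J <- prod(stretches)
  lb <- J^(-1 / 3) * stretches
  (2 * mat$mu / mat$alpha^2) * (sum(lb^mat$alpha) - 3) +
    (mat$bulk_penalty / 2) * (J - 1)^2
}

#' Closed-form uniaxial nominal stress
#'
#' Nominal (engineering) stress of the incompressible one-term Ogden model
#' in uniaxial tension along the stretch axis,
#' \deqn{S(\lambda) = \frac{2\mu}{\alpha}\left(\lambda^{\alpha-1} -
#'   \lambda^{-\alpha/2-1}\right),}
#' the derivative of \eqn{W(\lambda, \lambda^{-1/2}, \lambda^{-1/2})} with
#' respect to \eqn{\lambda}.  Vectorized over `lam`.
#'
#' @param lam stretch(es), > 0.
#' @param mat an [ogden_material()] (the bulk penalty is not used).
#' @return Nominal stress in kPa.
#' @export
uniaxial_nominal_stress <- function(lam, mat) {
  stopifnot(inherits(mat, "ogden_material"), is.numeric(lam))
  if (any(lam <= 0)) stop("stretch must be positive")
  a <- mat$alpha
  (2 * mat$mu / a) * (lam^(a - 1) - lam^(-a / 2 - 1))
}

#' Tangent modulus of the uniaxial nominal stress
#'
#' Derivative dS/dlambda of [uniaxial_nominal_stress()]; used by the truss
#' fiber tangent.
#'
#' @inheritParams uniaxial_nominal_stress
#' @return dS/dlambda in kPa.
#' @export
uniaxial_tangent_modulus <- function(lam, mat) {
  stopifnot(inherits(mat, "ogden_material"), is.numeric(lam))
  if (any(lam <= 0)) stop("stretch must be positive")
  a <- mat$alpha
  (2 * mat$mu / a) * ((a - 1) * lam^(a - 2) +
                        (a / 2 + 1) * lam^(-a / 2 - 2))
}

#' Stress and consistent tangent at a deformation gradient
#'
#' Evaluates the Cauchy stress, first Piola-Kirchhoff stress and the
#' (major-symmetric) material tangent dP/dF of the decoupled Ogden law by
#' spectral decomposition; the tangent is obtained by central finite
#' differencing of the analytic stress.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param mat an [ogden_material()].
#' @param element_id optional identifier reported if `det(F) <= 0`.
#' @return List with `cauchy` (3x3), `pk1` (3x3), `tangent` (9x9, column
#'   ordering of `as.vector(F)`), and `J`.
#' @export
stress_and_tangent <- function(F, mat, element_id = NULL) {
  stopifnot(inherits(mat, "ogden_material"),
            is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (J <= 0) {
    id <- if (is.null(element_id)) "" else sprintf(" (element %s)", element_id)
    stop(sprintf("element inversion: det(F) = %g <= 0%s", J, id))
  }
  P <- cpp_ogden_pk1(F, mat$mu, mat$alpha, mat$bulk_penalty)
  sig <- cpp_ogden_cauchy(F, mat$mu, mat$alpha, mat$bulk_penalty)
  h <- 1e-6
  A <- matrix(0, 9, 9)
  for (n in seq_len(9)) {
    Fp <- F; Fm <- F
    Fp[n] <- Fp[n] + h
    Fm[n] <- Fm[n] - h
    A[, n] <- as.vector(cpp_ogden_pk1(Fp, mat$mu, mat$alpha, mat$bulk_penalty) -
                          cpp_ogden_pk1(Fm, mat$mu, mat$alpha, mat$bulk_penalty)) / (2 * h)
  }
  list(cauchy = sig, pk1 = P, tangent = (A + t(A)) / 2, J = J)
}
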