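#' Yeoh hyperelastic parameters
#'
#' The three stress-like coefficients (MPa) of the incompressible isotropic
#' Yeoh model, whose strain energy is a cubic polynomial in (I1 - 3):
#' psi = c1 (I1 - 3) + c2 (I1 - 3)^2 + c3 (I1 - 3)^3. No sign constraint is
#' imposed by default; the fitting routine offers optional non-negativity
#' bounds.
#'
#' @param c1,c2,c3 Coefficients in MPa; must be finite.
#' @param label Free-text label (e.g. surrogate composition and rate).
#' @param rate_mm_per_s Nominal displacement rate the set was identified at
#'   (metadata; the model itself is rate-independent).
#' @return An object of class `yeoh_params`.
#' @examples
#' yeoh_params(0.0002, 0.0090, 0.0080, label = "60-20-10-10 (1.96 mm/s)")
#' @export
yeoh_params <- function(c1, c2, c3, label = "", rate_mm_per_s = NA_real_) {
  cs <- c(c1, c2, c3)
  if (length(cs) != 3L || any(!is.finite(cs)))
    stop("c1, c2, c3 must be finite scalars", call. = FALSE)
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, label = label,
         rate_mm_per_s = rate_mm_per_s),
    class = "yeoh_params")
}

#' @rdname yeoh_params
#' @param object A `yeoh_params` object.
#' @param ... Unused.
#' @export
coef.yeoh_params <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2, c3 = object$c3)
}

#' @export
print.yeoh_params <- function(x, ...) {
  cat(sprintf("<yeoh_params> %sc1 = %.4f, c2 = %.4f, c3 = %.4f MPa\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$c1, x$c2, x$c3))
  invisible(x)
}

.check_stretch <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 1e-6))
    stop("stretch must be finite and > 1e-6", call. = FALSE)
  lambda
}

#' Cauchy-Green deformation invariants from principal stretches
#'
#' I1 = sum(lambda_i^2), I3 = prod(lambda_i^2), and I2 as the sum of
#' lambda_i^2 lambda_j^2 over ordered pairs i != j (six terms, so the
#' undeformed reference gives I2 = 6 rather than the classical
#' unordered-pair value 3). I2 plays no role in the uniaxial stress equation;
#' it is exposed for completeness under this convention.
#'
#' @param lambda1,lambda2,lambda3 Principal stretches; all > 0.
#' @return Named numeric vector `c(I1, I2, I3)`.
#' @examples
#' cg_invariants(1, 1, 1)  # I1 = 3, I2 = 6, I3 = 1
#' @export
cg_invariants <- function(lambda1, lambda2, lambda3) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("principal stretches must be finite and > 0", call. = FALSE)
  s <- l^2
  c(I1 = sum(s),
    I2 = 2 * (s[1] * s[2] + s[1] * s[3] + s[2] * s[3]),
    I3 = prod(s))
}

#' First invariant under incompressible uniaxial deformation
#'
#' With lambda1 = lambda and lambda2 = lambda3 = lambda^(-1/2) (so that
#' I3 = 1), I1 = lambda^2 + 2 / lambda.
#'
#' @param lambda Uniaxial stretch(es); > 0. Vectorized.
#' @return I1 value(s).
#' @examples
#' uniaxial_i1(1)    # 3
#' uniaxial_i1(0.5)  # 4.25
#' @export
uniaxial_i1 <- function(lambda) {
  .check_stretch(lambda)
  lambda^2 + 2 / lambda
}

#' Yeoh strain energy density under uniaxial incompressible deformation
#'
#' psi(lambda) = c1 (I1 - 3) + c2 (I1 - 3)^2 + c3 (I1 - 3)^3 with
#' I1 = lambda^2 + 2/lambda. Zero at the reference state (lambda = 1), and
#' consistent with [yeoh_uniaxial_stress()] through
#' sigma = lambda * d(psi)/d(lambda).
#'
#' @param lambda Uniaxial stretch(es); > 0. Vectorized.
#' @param params A [yeoh_params()].
#' @return Strain energy density in MPa (= MJ/m^3).
#' @export
yeoh_strain_energy <- function(lambda, params) {
  stopifnot(inherits(params, "yeoh_params"))
  x <- uniaxial_i1(lambda) - 3
  params$c1 * x + params$c2 * x^2 + params$c3 * x^3
}

#' Uniaxial stress-stretch relation of the incompressible Yeoh model
#'
#' sigma(lambda) = 2 (lambda^2 - 1/lambda) (c1 + 2 c2 (I1 - 3)
#' + 3 c3 (I1 - 3)^2), the standard closed form for incompressible uniaxial
#' loading (equal to lambda * d(psi)/d(lambda)). Signed: sigma(1) = 0, and
#' for nonnegative coefficients compression (lambda < 1) gives sigma < 0.
#' This is the relation fitted to measured engineering stress-stretch data.
#'
#' @param lambda Uniaxial stretch(es); > 0. Vectorized.
#' @param params A [yeoh_params()].
#' @return Stress in MPa, same length as `lambda`.
#' @examples
#' p <- yeoh_params(0.0002, 0.009, 0.008)
#' yeoh_uniaxial_stress(0.5, p)  # -0.2107
#' @export
yeoh_uniaxial_stress <- function(lambda, params) {
  stopifnot(inherits(params, "yeoh_params"))
  x <- uniaxial_i1(lambda) - 3
  2 * (lambda^2 - 1 / lambda) *
    (params$c1 + 2 * params$c2 * x + 3 * params$c3 * x^2)
}

# Stress basis at given stretches: sigma = B %*% c(c1, c2, c3).
# The uniaxial Yeoh stress is linear in the coefficients; this matrix is the
# analytic Jacobian used by the fitter and the cohort generators.
.yeoh_stress_basis <- function(lambda) {
  x <- lambda^2 + 2 / lambda - 3
  g <- 2 * (lambda^2 - 1 / lambda)
  cbind(c1 = g, c2 = 2 * g * x, c3 = 3 * g * x^2)
}
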