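#' Coefficient of determination between observed and predicted stresses
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot taken about the observed mean. Can be
#' negative (prediction worse than the mean); never exceeds 1.
#'
#' @param observed Observed values; must not be constant.
#' @param predicted Predicted values, same length as `observed` (>= 2).
#' @return R^2, a dimensionless scalar <= 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  n <- length(observed)
  if (n < 2L || length(predicted) != n)
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("inputs must be finite", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are constant; R^2 undefined (zero variance)",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit the Yeoh model to a stress-stretch curve by least squares
#'
#' Minimizes the sum of squared stress residuals
#' sum_i (sigma_obs_i - sigma_yeoh(lambda_i; c1, c2, c3))^2 by
#' Levenberg-Marquardt nonlinear least squares (via [minpack.lm::nls.lm])
#' with the analytic Jacobian of the uniaxial stress relation, restarted from
#' several neutral initial guesses; the start reaching the smallest residual
#' sum of squares wins, ties broken by the smallest coefficient 2-norm.
#' Unconstrained by default; set `nonneg = TRUE` (or pass explicit bounds)
#' to restrict the coefficients.
#'
#' R^2 between observed and fitted stresses is reported alongside; fits with
#' R^2 above 0.95 are conventionally flagged highly accurate (see
#' [classify_fit()]).
#'
#' @param curve A [stress_stretch_curve()] in the signed convention, with at
#'   least 4 distinct stretch values.
#' @param init Optional [yeoh_params()] initial guess, used as an additional
#'   start.
#' @param lower,upper Optional length-3 coefficient bounds (MPa).
#' @param nonneg If TRUE, constrain c1, c2, c3 >= 0.
#' @param n_starts Number of built-in multi-starts (>= 1): the origin-adjacent
#'   start plus log-spaced magnitudes between 1e-4 and 1 MPa.
#' @param ftol,gtol Convergence tolerances on the relative SSR reduction and
#'   gradient; `maxfev` caps function evaluations.
#' @param maxfev Maximum residual evaluations per start.
#'
#' @return An object of class `yeoh_fit` with fields `params`
#'   ([yeoh_params()]), `r_squared`, `residual_sum_squares` (MPa^2),
#'   `n_points`, `converged`, `n_starts_used`, and `fitted` (predicted
#'   stresses).
#' @examples
#' p <- yeoh_params(0.0002, 0.009, 0.008)
#' lam <- seq(0.55, 1, length.out = 50)
#' crv <- stress_stretch_curve(lam, yeoh_uniaxial_stress(lam, p))
#' fit <- fit_yeoh(crv)
#' coef(fit$params)
#' @export
fit_yeoh <- function(curve, init = NULL, lower = NULL, upper = NULL,
                     nonneg = FALSE, n_starts = 5L,
                     ftol = 1e-12, gtol = 1e-10, maxfev = 10000L) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  lam <- curve$stretch
  sig <- curve$stress_MPa
  if (length(lam) < 4L)
    stop("at least 4 stress-stretch points are required", call. = FALSE)
  if (length(unique(lam)) < 4L)
    stop("at least 4 distinct stretch values are required (degenerate input)",
         call. = FALSE)
  if (nonneg) {
    if (is.null(lower)) lower <- c(0, 0, 0)
    lower <- pmax(lower, 0)
  }
  if (is.null(lower)) lower <- rep(-Inf, 3)
  if (is.null(upper)) upper <- rep(Inf, 3)
  stopifnot(length(lower) == 3L, length(upper) == 3L)

  B <- .yeoh_stress_basis(lam)
  resid_fn <- function(p) sig - drop(B %*% p)
  jac_fn <- function(p) -B  # residual Jacobian; constant in the coefficients

  # neutral multi-start: origin-adjacent plus log-spaced magnitudes
  starts <- list(c(1e-6, 1e-6, 1e-6))
  if (n_starts > 1L) {
    mags <- 10^seq(-4, 0, length.out = n_starts - 1L)
    starts <- c(starts, lapply(mags, function(m) rep(m, 3)))
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "yeoh_params"))
    starts <- c(starts, list(unname(coef(init))))
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  best <- NULL
  for (s in starts) {
    res <- minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper,
      fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        ftol = ftol, gtol = gtol, maxfev = maxfev))
    ssr <- sum(res$fvec^2)
    cand <- list(par = res$par, ssr = ssr,
                 converged = res$info %in% 1:4)
    if (is.null(best) || cand$ssr < best$ssr ||
        (cand$ssr == best$ssr &&
         sum(cand$par^2) < sum(best$par^2))) {
      best <- cand
    }
  }

  pred <- drop(B %*% best$par)
  structure(
    list(params = yeoh_params(best$par[1], best$par[2], best$par[3],
                              label = curve$label),
         r_squared = r_squared(sig, pred),
         residual_sum_squares = best$ssr,
         n_points = length(lam),
         converged = best$converged,
         n_starts_used = length(starts),
         fitted = pred),
    class = "yeoh_fit")
}

#' @export
print.yeoh_fit <- function(x, ...) {
  cat(sprintf(
    "<yeoh_fit> c = (%.4f, %.4f, %.4f) MPa, R^2 = %.6f, SSR = %.3e MPa^2, n = %d%s\n",
    x$params$c1, x$params$c2, x$params$c3, x$r_squared,
    x$residual_sum_squares, x$n_points,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Classify fit accuracy by the R^2 threshold rule
#'
#' A fit is flagged highly accurate when its R^2 strictly exceeds the
#' threshold (default 0.95).
#'
#' @param fit A `yeoh_fit` (or anything with an `r_squared` field) or a bare
#'   R^2 value.
#' @param threshold Strict lower R^2 bound; default 0.95.
#' @return Logical: TRUE if highly accurate.
#' @examples
#' classify_fit(0.978)  # TRUE
#' classify_fit(0.95)   # FALSE (strict inequality)
#' @export
classify_fit <- function(fit, threshold = 0.95) {
  r2 <- if (is.numeric(fit)) fit else fit$r_squared
  stopifnot(is.numeric(r2), length(r2) == 1L, is.finite(r2))
  r2 > threshold
}
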