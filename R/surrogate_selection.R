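#' Labeled force-strain curve
#'
#' A named force (N) versus compressive-strain-magnitude curve, the substrate
#' for the correlation-based surrogate selection. Strain must be strictly
#' increasing.
#'
#' @param label Composition or group name.
#' @param strain Dimensionless compressive strain magnitudes, strictly
#'   increasing.
#' @param force_N Forces (N), same length as `strain`.
#' @return An object of class `labeled_curve`.
#' @export
labeled_curve <- function(label, strain, force_N) {
  if (length(strain) != length(force_N))
    stop("strain and force must have equal length", call. = FALSE)
  if (length(strain) < 2L)
    stop("curve needs >= 2 points", call. = FALSE)
  if (any(!is.finite(strain)) || any(!is.finite(force_N)))
    stop("curve values must be finite", call. = FALSE)
  if (any(diff(strain) <= 0))
    stop("strain must be strictly increasing", call. = FALSE)
  structure(list(label = label, strain = as.numeric(strain),
                 force_N = as.numeric(force_N)),
            class = "labeled_curve")
}

#' @export
print.labeled_curve <- function(x, ...) {
  cat(sprintf("<labeled_curve> '%s': %d points, strain in [%.4g, %.4g], F in [%.4g, %.4g] N\n",
              x$label, length(x$strain), min(x$strain), max(x$strain),
              min(x$force_N), max(x$force_N)))
  invisible(x)
}

#' Resample a curve onto a strain grid by linear interpolation
#'
#' No extrapolation: every grid point must lie within the curve's strain
#' span.
#'
#' @param curve A [labeled_curve()].
#' @param grid Strictly increasing strain grid inside the curve's span.
#' @return A [labeled_curve()] on `grid` with the label preserved.
#' @export
resample_common_grid <- function(curve, grid) {
  stopifnot(inherits(curve, "labeled_curve"))
  if (min(grid) < min(curve$strain) - 1e-12 ||
      max(grid) > max(curve$strain) + 1e-12)
    stop("grid extends beyond the curve's strain span (no extrapolation)",
         call. = FALSE)
  grid <- pmin(pmax(grid, min(curve$strain)), max(curve$strain))
  labeled_curve(curve$label, grid,
                stats::approx(curve$strain, curve$force_N, xout = grid)$y)
}

#' Shared-span strain grid for two curves
#'
#' Evenly spaced points over [max of the two strain minima, min of the two
#' maxima].
#'
#' @param a,b [labeled_curve()]s with overlapping strain spans.
#' @param n_grid Number of grid points (default 21).
#' @return Numeric strain grid of length `n_grid`.
#' @export
shared_strain_grid <- function(a, b, n_grid = 21L) {
  lo <- max(min(a$strain), min(b$strain))
  hi <- min(max(a$strain), max(b$strain))
  if (hi <= lo)
    stop("curves have no overlapping strain span", call. = FALSE)
  seq(lo, hi, length.out = n_grid)
}

#' R^2 correlation between a candidate and a reference curve
#'
#' Both curves are resampled onto the shared-span grid (default 21 points)
#' and R^2 of the candidate forces against the reference forces is computed,
#' with the reference playing the role of the observed series.
#'
#' @param candidate,reference [labeled_curve()]s with overlapping spans.
#' @param n_grid Number of common-grid points (default 21).
#' @return R^2 (dimensionless, <= 1).
#' @export
correlate_curves <- function(candidate, reference, n_grid = 21L) {
  grid <- shared_strain_grid(candidate, reference, n_grid)
  cand <- resample_common_grid(candidate, grid)
  ref <- resample_common_grid(reference, grid)
  r_squared(observed = ref$force_N, predicted = cand$force_N)
}

#' Select surrogate compositions by R^2 threshold against reference groups
#'
#' Correlates every candidate curve against every reference group curve on a
#' common grid, admits candidates with R^2 >= `threshold`, and names the best
#' (argmax R^2) candidate per group. Ties on the maximum are broken
#' lexicographically by label and flagged.
#'
#' @param candidates List of [labeled_curve()]s (candidate surrogates).
#' @param references Named list of [labeled_curve()]s (one per reference
#'   group).
#' @param threshold Admission threshold on R^2 (default 0.8, inclusive).
#' @param n_grid Points on the shared correlation grid (default 21).
#' @return An object of class `selection_report` with fields `r_squared`
#'   (candidates x groups matrix), `admitted` (named list of admitted label
#'   vectors per group), `best` (named character of best labels), `tie`
#'   (named logical) and `threshold`.
#' @export
select_surrogates <- function(candidates, references, threshold = 0.8,
                              n_grid = 21L) {
  if (length(candidates) == 0L || length(references) == 0L)
    stop("need at least one candidate and one reference", call. = FALSE)
  stopifnot(all(vapply(candidates, inherits, logical(1), "labeled_curve")),
            all(vapply(references, inherits, logical(1), "labeled_curve")))
  cand_labels <- vapply(candidates, `[[`, "", "label")
  grp_labels <- if (!is.null(names(references)) &&
                    all(nzchar(names(references)))) names(references)
                else vapply(references, `[[`, "", "label")
  r2 <- matrix(NA_real_, length(candidates), length(references),
               dimnames = list(cand_labels, grp_labels))
  for (i in seq_along(candidates))
    for (j in seq_along(references))
      r2[i, j] <- correlate_curves(candidates[[i]], references[[j]], n_grid)

  admitted <- lapply(seq_along(references), function(j)
    cand_labels[r2[, j] >= threshold])
  names(admitted) <- grp_labels
  best <- character(length(references))
  tie <- logical(length(references))
  for (j in seq_along(references)) {
    mx <- max(r2[, j])
    winners <- sort(cand_labels[r2[, j] == mx])
    best[j] <- winners[1L]
    tie[j] <- length(winners) > 1L
  }
  names(best) <- names(tie) <- grp_labels
  structure(list(r_squared = r2, admitted = admitted, best = best,
                 tie = tie, threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d candidates x %d groups, threshold R^2 >= %g\n",
              nrow(x$r_squared), ncol(x$r_squared), x$threshold))
  for (g in colnames(x$r_squared)) {
    cat(sprintf("  %s: best = %s (R^2 = %.2f)%s; admitted: %s\n",
                g, x$best[[g]], max(x$r_squared[, g]),
                if (x$tie[[g]]) " [tie]" else "",
                if (length(x$admitted[[g]]))
                  paste(x$admitted[[g]], collapse = ", ") else "(none)"))
  }
  invisible(x)
}
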