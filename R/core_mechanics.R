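#' Cylindrical specimen geometry
#'
#' Describes the undeformed compression specimen: a cylinder of the stated
#' diameter and height. The cross-sectional area is derived and used to turn
#' measured force (N) into engineering stress (MPa, since N/mm^2 = MPa), and
#' the height to turn displacement (mm) into engineering strain.
#'
#' @param diameter_mm Specimen diameter in mm; must be > 0.
#' @param height_mm Undeformed specimen height (depth) in mm; must be > 0.
#'
#' @return An object of class `specimen_geometry` with fields `diameter_mm`,
#'   `height_mm` and the derived `area_mm2` (= pi * d^2 / 4).
#'
#' @examples
#' geo <- specimen_geometry(40, 18)
#' cross_section_area(geo)  # ~1256.637 mm^2
#' @export
specimen_geometry <- function(diameter_mm, height_mm) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L,
            is.numeric(height_mm), length(height_mm) == 1L)
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("`diameter_mm` must be finite and > 0", call. = FALSE)
  if (!is.finite(height_mm) || height_mm <= 0)
    stop("`height_mm` must be finite and > 0", call. = FALSE)
  structure(
    list(diameter_mm = diameter_mm,
         height_mm = height_mm,
         area_mm2 = pi * diameter_mm^2 / 4),
    class = "specimen_geometry")
}

#' @rdname specimen_geometry
#' @param geometry A `specimen_geometry` object.
#' @export
cross_section_area <- function(geometry) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  geometry$area_mm2
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("<specimen_geometry> cylinder d = %g mm, h = %g mm, A0 = %.4f mm^2\n",
              x$diameter_mm, x$height_mm, x$area_mm2))
  invisible(x)
}

#' Raw uniaxial compression record in machine coordinates
#'
#' A sampled (time, displacement, force) history from one compression test.
#' Displacement is compression-positive (mm), force is the resisting load (N);
#' both are signed magnitudes as a load frame reports them.
#'
#' @param time_s Sample times in seconds; monotone nondecreasing.
#' @param displacement_mm Piston displacement in mm, >= 0, never exceeding the
#'   specimen height (no through-compression).
#' @param force_N Resisting force in N; >= 0 up to sensor noise (small
#'   negatives within `force_tol` are accepted, e.g. load-cell noise at
#'   contact).
#' @param geometry A [specimen_geometry()].
#' @param rate_mm_per_s Nominal displacement rate (mm/s), metadata only.
#' @param label Free-text label (e.g. a composition name).
#' @param force_tol Tolerance for slightly negative forces (N).
#'
#' @return An object of class `compression_record`.
#' @export
compression_record <- function(time_s, displacement_mm, force_N, geometry,
                               rate_mm_per_s = NA_real_, label = "",
                               force_tol = 1e-9) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  n <- length(time_s)
  if (n < 2L)
    stop("compression record needs at least 2 samples", call. = FALSE)
  if (length(displacement_mm) != n || length(force_N) != n)
    stop("time, displacement and force must have equal length", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(displacement_mm)) ||
      any(!is.finite(force_N)))
    stop("record arrays must be finite", call. = FALSE)
  if (any(diff(time_s) < 0))
    stop("time must be monotone nondecreasing", call. = FALSE)
  if (any(displacement_mm < 0))
    stop("displacement must be >= 0 (compression-positive)", call. = FALSE)
  if (max(displacement_mm) > geometry$height_mm)
    stop("displacement exceeds specimen height (through-compression)",
         call. = FALSE)
  if (any(force_N < -force_tol))
    stop("force must be >= 0 up to noise tolerance", call. = FALSE)
  structure(
    list(time_s = as.numeric(time_s),
         displacement_mm = as.numeric(displacement_mm),
         force_N = pmax(as.numeric(force_N), 0),
         geometry = geometry,
         rate_mm_per_s = rate_mm_per_s,
         label = label),
    class = "compression_record")
}

#' @export
print.compression_record <- function(x, ...) {
  cat(sprintf(
    "<compression_record> '%s': %d samples, t in [%g, %g] s, d_max = %g mm, F_max = %g N, rate = %s mm/s\n",
    x$label, length(x$time_s), min(x$time_s), max(x$time_s),
    max(x$displacement_mm), max(x$force_N),
    ifelse(is.na(x$rate_mm_per_s), "?", format(x$rate_mm_per_s))))
  invisible(x)
}

#' Paired stress-stretch samples in material coordinates
#'
#' The fitting substrate: engineering stress sigma (MPa) against stretch
#' lambda, with engineering strain epsilon = lambda - 1. The package uses a
#' signed, tension-positive convention throughout: compression means
#' lambda < 1 and sigma < 0. Use [magnitude_view()] for reporting-style
#' magnitudes.
#'
#' @param stretch Stretch values lambda; all > 0 (and > 1e-6 to keep 1/lambda
#'   bounded).
#' @param stress_MPa Engineering stress values (MPa), signed.
#' @param geometry Optional [specimen_geometry()] retained for round trips.
#' @param label Free-text label.
#'
#' @return An object of class `stress_stretch_curve` with fields `stretch`,
#'   `stress_MPa` and derived `strain` (= stretch - 1).
#' @export
stress_stretch_curve <- function(stretch, stress_MPa, geometry = NULL,
                                 label = "") {
  if (length(stretch) != length(stress_MPa))
    stop("stretch and stress must have equal length", call. = FALSE)
  if (any(!is.finite(stretch)) || any(!is.finite(stress_MPa)))
    stop("stretch and stress must be finite", call. = FALSE)
  if (any(stretch <= 1e-6))
    stop("stretch must be > 1e-6 (1/lambda blow-up)", call. = FALSE)
  if (!is.null(geometry)) stopifnot(inherits(geometry, "specimen_geometry"))
  structure(
    list(stretch = as.numeric(stretch),
         stress_MPa = as.numeric(stress_MPa),
         strain = as.numeric(stretch) - 1,
         geometry = geometry,
         label = label),
    class = "stress_stretch_curve")
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf(
    "<stress_stretch_curve> '%s': %d points, lambda in [%.4g, %.4g], sigma in [%.4g, %.4g] MPa\n",
    x$label, length(x$stretch), min(x$stretch), max(x$stretch),
    min(x$stress_MPa), max(x$stress_MPa)))
  invisible(x)
}

#' Convert a machine record to an engineering stress-stretch curve
#'
#' Applies the engineering (undeformed-reference) maps: strain
#' eps_i = -d_i / h0, stretch lambda_i = 1 + eps_i, and stress
#' sigma_i = -F_i / A0 in MPa. The minus signs implement the signed
#' tension-positive convention: compression displacement/force are positive in
#' machine coordinates but map to lambda < 1, sigma < 0.
#'
#' @param record A [compression_record()].
#' @return A [stress_stretch_curve()] of the same length, carrying the
#'   record's geometry and label.
#' @examples
#' geo <- specimen_geometry(40, 18)
#' rec <- compression_record(c(0, 1), c(0, 9), c(0, 40), geo)
#' crv <- to_stress_stretch(rec)
#' crv$stretch   # 1.0, 0.5
#' crv$stress_MPa  # 0, -40/(pi*400)
#' @export
to_stress_stretch <- function(record) {
  stopifnot(inherits(record, "compression_record"))
  geo <- record$geometry
  if (geo$area_mm2 <= 0) stop("zero cross-section area", call. = FALSE)
  eps <- -record$displacement_mm / geo$height_mm
  stress_stretch_curve(stretch = 1 + eps,
                       stress_MPa = -record$force_N / geo$area_mm2,
                       geometry = geo, label = record$label)
}

#' Reconstruct machine coordinates from a stress-stretch curve
#'
#' Inverse of [to_stress_stretch()] given the geometry: displacement
#' d = -strain * h0 and force F = -sigma * A0. Exact round trip by
#' construction.
#'
#' @param curve A [stress_stretch_curve()].
#' @param geometry A [specimen_geometry()]; defaults to the one carried by the
#'   curve.
#' @return A data.frame with columns `displacement_mm` and `force_N`.
#' @export
to_machine_coordinates <- function(curve, geometry = curve$geometry) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  if (is.null(geometry))
    stop("a specimen_geometry is required to reconstruct machine coordinates",
         call. = FALSE)
  stopifnot(inherits(geometry, "specimen_geometry"))
  data.frame(displacement_mm = -curve$strain * geometry$height_mm,
             force_N = -curve$stress_MPa * geometry$area_mm2)
}

#' Magnitude view of a compression curve
#'
#' Reporting convenience mirroring the usual figures: compressive strain
#' magnitude (1 - lambda) against stress magnitude |sigma|. Only valid on a
#' compression-branch curve; any tensile point (lambda > 1) is an error.
#'
#' @param curve A [stress_stretch_curve()] with all stretches <= 1.
#' @return A data.frame with columns `strain` (in [0, 1)) and `stress_MPa`
#'   (>= 0), sample order preserved.
#' @export
magnitude_view <- function(curve) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  if (any(curve$stretch > 1 + 1e-12))
    stop("magnitude_view supports compression only (found lambda > 1)",
         call. = FALSE)
  data.frame(strain = 1 - curve$stretch,
             stress_MPa = abs(curve$stress_MPa))
}

#' Four-part elastomer composition record
#'
#' Weight fractions (wt %) of the four elastomer parts making up one
#' surrogate: Shore 00-10 part A and B, and Shore 30A part A and B. The
#' conventional name concatenates the fractions "A-B-C-D" in that order
#' (e.g. "60-20-10-10").
#'
#' @param shore0010_a,shore0010_b Shore 00-10 part A / part B (wt %).
#' @param shore30a_a,shore30a_b Shore 30A part A / part B (wt %).
#' @return An object of class `composition_record` with a `name` field.
#' @export
composition_record <- function(shore0010_a, shore0010_b, shore30a_a,
                               shore30a_b) {
  w <- c(shore0010_a, shore0010_b, shore30a_a, shore30a_b)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all four weight fractions must be finite and > 0", call. = FALSE)
  if (abs(sum(w) - 100) > 1e-6)
    stop(sprintf("weight fractions must sum to 100 wt %% (got %.8f)", sum(w)),
         call. = FALSE)
  fmt <- function(v) ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
                            sub("0+$", "", sprintf("%.2f", v)))
  structure(
    list(shore0010_a = shore0010_a, shore0010_b = shore0010_b,
         shore30a_a = shore30a_a, shore30a_b = shore30a_b,
         name = paste(vapply(w, fmt, ""), collapse = "-")),
    class = "composition_record")
}

#' @export
print.composition_record <- function(x, ...) {
  cat(sprintf(
    "<composition_record> %s (Shore 00-10 A/B = %g/%g, Shore 30A A/B = %g/%g wt %%)\n",
    x$name, x$shore0010_a, x$shore0010_b, x$shore30a_a, x$shore30a_b))
  invisible(x)
}
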