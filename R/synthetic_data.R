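# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic compression-test generator
#'
#' Bundles the constitutive plant and test protocol from which synthetic
#' machine records are produced: Yeoh parameters, specimen geometry, nominal
#' displacement rate, displacement amplitude, sampling rate, load-cell noise
#' level (as a fraction of the noise-free peak force), cycle count and the
#' prescribed hysteresis dissipation ratio. With `force_noise_sd = 0` the
#' generated forces lie exactly on the forward model.
#'
#' @param params A [yeoh_params()] plant.
#' @param geometry A [specimen_geometry()]; defaults to the 40 mm x 18 mm
#'   cylinder.
#' @param rate_mm_per_s Nominal displacement rate (mm/s).
#' @param max_displacement_mm Peak displacement (mm); must be smaller than the
#'   specimen height.
#' @param sampling_rate_hz Nominal sampling rate (Hz); the actual grid is
#'   adjusted so the ramp endpoints land exactly on samples.
#' @param force_noise_sd Gaussian force-noise standard deviation as a fraction
#'   of the noise-free peak force; >= 0.
#' @param n_cycles Number of triangular load-unload cycles for
#'   [generate_hysteresis_record()]; >= 1.
#' @param dissipation_q Prescribed energy dissipation ratio q in [0, 1): the
#'   unloading force equals (1 - q) times the loading force at equal
#'   displacement.
#' @param max_load_N Optional load cap (N); a monotonic record is truncated at
#'   the last sample not exceeding it.
#' @param seed Integer seed making generated noise reproducible; NA for the
#'   current RNG stream.
#' @param label Label stamped on generated records.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(params,
                           geometry = specimen_geometry(40, 18),
                           rate_mm_per_s = 1.96,
                           max_displacement_mm = 9,
                           sampling_rate_hz = 100,
                           force_noise_sd = 0,
                           n_cycles = 1L,
                           dissipation_q = 0,
                           max_load_N = NA_real_,
                           seed = NA_integer_,
                           label = params$label) {
  stopifnot(inherits(params, "yeoh_params"),
            inherits(geometry, "specimen_geometry"))
  if (!is.finite(rate_mm_per_s) || rate_mm_per_s <= 0)
    stop("rate must be > 0", call. = FALSE)
  if (!is.finite(max_displacement_mm) || max_displacement_mm <= 0 ||
      max_displacement_mm >= geometry$height_mm)
    stop("max displacement must lie in (0, specimen height)", call. = FALSE)
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling rate must be > 0", call. = FALSE)
  if (!is.finite(force_noise_sd) || force_noise_sd < 0)
    stop("force noise sd must be >= 0", call. = FALSE)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (!is.finite(dissipation_q) || dissipation_q < 0 || dissipation_q >= 1)
    stop("dissipation q must lie in [0, 1)", call. = FALSE)
  structure(
    list(params = params, geometry = geometry,
         rate_mm_per_s = rate_mm_per_s,
         max_displacement_mm = max_displacement_mm,
         sampling_rate_hz = sampling_rate_hz,
         force_noise_sd = force_noise_sd,
         n_cycles = as.integer(n_cycles),
         dissipation_q = dissipation_q,
         max_load_N = max_load_N,
         seed = seed, label = label),
    class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(
    "<generator_spec> '%s': rate %g mm/s, d_max %g mm, fs %g Hz, noise %g, %d cycle(s), q = %g, seed = %s\n",
    x$label, x$rate_mm_per_s, x$max_displacement_mm, x$sampling_rate_hz,
    x$force_noise_sd, x$n_cycles, x$dissipation_q,
    ifelse(is.na(x$seed), "NA", format(x$seed))))
  invisible(x)
}

# Noise-free resisting force (N) at compression displacement d (mm).
.plant_force <- function(d, spec) {
  lam <- 1 - d / spec$geometry$height_mm
  abs(yeoh_uniaxial_stress(pmax(lam, 1e-6), spec$params)) *
    spec$geometry$area_mm2
}

# Samples per loading ramp so that 0 and max_displacement land on the grid.
.ramp_points <- function(spec) {
  half_t <- spec$max_displacement_mm / spec$rate_mm_per_s
  max(2L, as.integer(round(spec$sampling_rate_hz * half_t)) + 1L)
}

#' Generate a monotonic compression record from the forward model
#'
#' Displacement ramps linearly at the nominal rate from 0 to the peak;
#' force is the forward-model resisting force |sigma_yeoh(lambda)| * A0 plus
#' seeded Gaussian noise (sd = `force_noise_sd` x noise-free peak force),
#' clipped at zero. With zero noise the record lies exactly on the model, so
#' converting back with [to_stress_stretch()] and fitting recovers the plant
#' parameters.
#'
#' @param spec A [generator_spec()].
#' @return A [compression_record()].
#' @examples
#' p <- yeoh_params(0.0002, 0.009, 0.008)
#' rec <- generate_compression_record(generator_spec(p, seed = 1))
#' @export
generate_compression_record <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  m <- .ramp_points(spec)
  d <- seq(0, spec$max_displacement_mm, length.out = m)
  t <- d / spec$rate_mm_per_s
  f0 <- .plant_force(d, spec)
  f <- if (spec$force_noise_sd > 0) {
    .with_seed(spec$seed,
               pmax(f0 + stats::rnorm(m, 0, spec$force_noise_sd * max(f0)), 0))
  } else f0
  if (is.finite(spec$max_load_N)) {
    keep <- which(f <= spec$max_load_N)
    last <- if (length(keep)) max(keep) else
      stop("all samples exceed the load cap", call. = FALSE)
    if (last < 2L) stop("load cap leaves fewer than 2 samples", call. = FALSE)
    d <- d[seq_len(last)]; t <- t[seq_len(last)]; f <- f[seq_len(last)]
  }
  compression_record(t, d, f, spec$geometry,
                     rate_mm_per_s = spec$rate_mm_per_s, label = spec$label)
}

#' Generate a multi-cycle triangular load-unload record
#'
#' Each cycle ramps the displacement linearly to the peak and back; the
#' loading force follows the forward model and the unloading force equals
#' (1 - q) times the loading force at the same displacement, so by
#' construction each cycle's energy dissipation ratio is exactly q (the
#' trapezoid rule is exact under pointwise scaling). Seeded Gaussian noise,
#' if any, is added after the scaling.
#'
#' @param spec A [generator_spec()] with `n_cycles >= 1` and `dissipation_q`
#'   set.
#' @return A [compression_record()] containing `n_cycles` triangular cycles.
#' @examples
#' p <- yeoh_params(0.0002, 0.009, 0.008)
#' rec <- generate_hysteresis_record(
#'   generator_spec(p, n_cycles = 5, dissipation_q = 0.22))
#' length(segment_cycles(rec))  # 5
#' @export
generate_hysteresis_record <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  m <- .ramp_points(spec)
  d_up <- seq(0, spec$max_displacement_mm, length.out = m)
  f_up <- .plant_force(d_up, spec)
  # apex sample duplicated: the unloading branch starts at (1 - q) * F_peak at
  # the same displacement, so the pointwise-scaled construction (and hence
  # EDR = q under the trapezoid rule) is exact in the sampled record
  d_cycle <- c(d_up, rev(d_up))
  f_cycle <- c(f_up, (1 - spec$dissipation_q) * rev(f_up))
  d <- c(rep(c(d_cycle[-length(d_cycle)]), spec$n_cycles), 0)
  f <- c(rep(c(f_cycle[-length(f_cycle)]), spec$n_cycles), f_cycle[length(f_cycle)])
  t <- cumsum(c(0, abs(diff(d)))) / spec$rate_mm_per_s
  if (spec$force_noise_sd > 0) {
    f <- .with_seed(spec$seed,
                    pmax(f + stats::rnorm(length(f),
                                          0, spec$force_noise_sd * max(f)), 0))
  }
  compression_record(t, d, f, spec$geometry,
                     rate_mm_per_s = spec$rate_mm_per_s, label = spec$label)
}

#' Generate a synthetic surrogate cohort of force-strain curves
#'
#' Emulates the structure of a surrogate-selection experiment: a panel of
#' candidate compositions, each represented by a constitutive parameter set,
#' measured as force-strain curves on several specimens, plus reference group
#' curves. Specimen-to-specimen variability is modelled as independent
#' lognormal multipliers (meanlog 0, sdlog = `variability_sd`) on each Yeoh
#' coefficient, which keeps positive coefficients positive; with
#' `variability_sd = 0` every specimen lies exactly on its composition's
#' plant, so a candidate sharing a reference's parameters correlates with it
#' at R^2 = 1.
#'
#' @param compositions Named list of [yeoh_params()], one per candidate
#'   composition.
#' @param references Named list of [yeoh_params()], one per reference group.
#' @param variability_sd Lognormal sdlog of the per-specimen coefficient
#'   multipliers; >= 0.
#' @param n_specimens Specimens per composition (>= 1).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param geometry A [specimen_geometry()].
#' @param max_strain Largest compressive strain magnitude on the curves.
#' @param n_points Samples per curve.
#' @return A list with `specimens` (list of [labeled_curve()]s, labels
#'   "composition [s<k>]"), `mean_curves` (per-composition specimen-average
#'   [labeled_curve()]s) and `references` (named list of [labeled_curve()]s).
#' @export
generate_cohort <- function(compositions, references,
                            variability_sd = 0, n_specimens = 3L,
                            seed = NA_integer_,
                            geometry = specimen_geometry(40, 18),
                            max_strain = 0.5, n_points = 50L) {
  if (length(compositions) == 0L || length(references) == 0L)
    stop("compositions and references must be nonempty", call. = FALSE)
  stopifnot(all(vapply(compositions, inherits, logical(1), "yeoh_params")),
            all(vapply(references, inherits, logical(1), "yeoh_params")),
            variability_sd >= 0, n_specimens >= 1L)
  eps <- seq(0, max_strain, length.out = n_points)
  force_of <- function(p)
    abs(yeoh_uniaxial_stress(pmax(1 - eps, 1e-6), p)) * geometry$area_mm2

  .with_seed(seed, {
    specimens <- list()
    mean_curves <- list()
    for (nm in names(compositions)) {
      base <- coef(compositions[[nm]])
      fmat <- matrix(NA_real_, n_specimens, length(eps))
      for (s in seq_len(n_specimens)) {
        mult <- if (variability_sd > 0)
          stats::rlnorm(3, meanlog = 0, sdlog = variability_sd)
        else rep(1, 3)
        cs <- base * mult
        fs <- force_of(yeoh_params(cs[1], cs[2], cs[3]))
        fmat[s, ] <- fs
        specimens[[length(specimens) + 1L]] <-
          labeled_curve(sprintf("%s [s%d]", nm, s), eps, fs)
      }
      mean_curves[[nm]] <- labeled_curve(nm, eps, colMeans(fmat))
    }
    refs <- lapply(references, function(p) NULL)
    for (g in names(references))
      refs[[g]] <- labeled_curve(g, eps, force_of(references[[g]]))
    list(specimens = specimens, mean_curves = mean_curves, references = refs)
  })
}
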