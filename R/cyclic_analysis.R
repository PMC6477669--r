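#' One load-unload hysteresis loop
#'
#' A single pass of a cyclic compression test in machine coordinates: the
#' loading branch (displacement nondecreasing, trough to peak) and the
#' unloading branch (displacement nonincreasing, peak to trough). A
#' loading-only loop (monotone ramp with no unloading) carries
#' `unloading = NULL` and `loading_only = TRUE`.
#'
#' @param loading data.frame with columns `displacement_mm`, `force_N`;
#'   displacement nondecreasing.
#' @param unloading Same shape, displacement nonincreasing, or NULL.
#' @param cycle_index 1-based index of the cycle in its source record.
#' @return An object of class `hysteresis_loop`.
#' @export
hysteresis_loop <- function(loading, unloading = NULL, cycle_index = 1L) {
  .check_branch <- function(df, dir) {
    stopifnot(is.data.frame(df),
              all(c("displacement_mm", "force_N") %in% names(df)))
    if (nrow(df) < 2L) stop("branch needs >= 2 samples", call. = FALSE)
    d <- diff(df$displacement_mm)
    ok <- if (dir > 0) all(d >= 0) else all(d <= 0)
    if (!ok)
      stop(sprintf("%s branch displacement must be %s",
                   if (dir > 0) "loading" else "unloading",
                   if (dir > 0) "nondecreasing" else "nonincreasing"),
           call. = FALSE)
    df
  }
  loading <- .check_branch(loading, +1)
  if (!is.null(unloading)) {
    unloading <- .check_branch(unloading, -1)
    dpk_l <- loading$displacement_mm[nrow(loading)]
    dpk_u <- unloading$displacement_mm[1L]
    spacing <- max(abs(diff(loading$displacement_mm)),
                   abs(diff(unloading$displacement_mm)))
    if (abs(dpk_l - dpk_u) > spacing + 1e-12)
      stop("branches must share the peak displacement to within one sample spacing",
           call. = FALSE)
  }
  structure(
    list(loading = loading, unloading = unloading,
         cycle_index = as.integer(cycle_index),
         loading_only = is.null(unloading)),
    class = "hysteresis_loop")
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("<hysteresis_loop> cycle %d: %d loading samples%s, peak F = %g N%s\n",
              x$cycle_index, nrow(x$loading),
              if (x$loading_only) "" else
                sprintf(", %d unloading samples", nrow(x$unloading)),
              peak_force(x),
              if (x$loading_only) " [loading-only]" else ""))
  invisible(x)
}

#' @rdname hysteresis_loop
#' @param loop A `hysteresis_loop`.
#' @export
peak_force <- function(loop) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  max(loop$loading$force_N,
      if (!is.null(loop$unloading)) loop$unloading$force_N else -Inf)
}

#' Segment a cyclic compression record into hysteresis loops
#'
#' Finds displacement peaks (strict local maxima with a minimum prominence,
#' default 1% of the overall maximum displacement, so sensor jitter does not
#' spawn spurious cycles) and cuts one loop per peak: loading runs from the
#' preceding trough to the peak, unloading from the peak to the following
#' trough. A record whose displacement is monotone nondecreasing yields a
#' single loading-only loop.
#'
#' @param record A [compression_record()] with at least one displacement
#'   maximum.
#' @param min_prominence Peak prominence threshold as a fraction of the
#'   maximum displacement.
#' @return A list of [hysteresis_loop()]s, one per displacement peak.
#' @export
segment_cycles <- function(record, min_prominence = 0.01) {
  stopifnot(inherits(record, "compression_record"))
  d <- record$displacement_mm
  f <- record$force_N
  dmax <- max(d)
  if (dmax <= 0)
    stop("flat zero displacement record cannot be segmented", call. = FALSE)
  n <- length(d)

  if (all(diff(d) >= 0)) {
    return(list(hysteresis_loop(
      data.frame(displacement_mm = d, force_N = f), NULL, 1L)))
  }

  prom_tol <- min_prominence * dmax
  # candidate peaks as plateau runs of equal displacement that are strict
  # local maxima (a duplicated apex sample, e.g. an instantaneous force drop
  # at the reversal, forms a 2-sample plateau)
  run_end <- which(c(diff(d) != 0, TRUE))
  run_start <- c(1L, head(run_end, -1L) + 1L)
  peak_runs <- which(vapply(seq_along(run_start), function(r) {
    i1 <- run_start[r]; i2 <- run_end[r]
    left <- if (i1 > 1L) d[i1 - 1L] else Inf
    right <- if (i2 < n) d[i2 + 1L] else -Inf
    d[i1] > left && d[i1] > right
  }, logical(1)))
  # prominence: drop on both sides relative to the neighbouring troughs
  keep <- vapply(peak_runs, function(r) {
    i1 <- run_start[r]; i2 <- run_end[r]
    (d[i1] - min(d[1:i1])) >= prom_tol &&
      (d[i1] - min(d[i2:n])) >= prom_tol
  }, logical(1))
  peak_runs <- peak_runs[keep]
  if (length(peak_runs) == 0L)
    stop("no displacement peak with the required prominence", call. = FALSE)

  loops <- vector("list", length(peak_runs))
  prev_trough <- 1L
  for (k in seq_along(peak_runs)) {
    pk_load <- run_start[peak_runs[k]]
    pk_unload <- run_end[peak_runs[k]]
    nxt <- if (k < length(peak_runs)) run_start[peak_runs[k + 1L]] else n
    trough_after <- pk_unload - 1L + which.min(d[pk_unload:nxt])
    load_idx <- prev_trough:pk_load
    unload_idx <- pk_unload:trough_after
    unloading <- if (length(unload_idx) >= 2L)
      data.frame(displacement_mm = cummin(d[unload_idx]),
                 force_N = f[unload_idx])
    loops[[k]] <- hysteresis_loop(
      loading = data.frame(displacement_mm = cummax(d[load_idx]),
                           force_N = f[load_idx]),
      unloading = unloading,
      cycle_index = k)
    prev_trough <- trough_after
  }
  loops
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Energy dissipation ratio of a hysteresis loop
#'
#' EDR = (area enclosed by the loop) / (area under the loading curve), with
#' both areas computed by trapezoidal integration of force over displacement
#' (N mm). The enclosed (hysteresis) area is the loading area minus the
#' unloading area; EDR = 1 means no energy is recovered on unloading, EDR = 0
#' means the branches coincide. Values outside [0, 1] by more than `tol` are
#' an error; values within `tol` of the bounds are clipped (integration noise
#' on nearly coincident branches).
#'
#' @param loop A two-branch [hysteresis_loop()].
#' @param tol Clipping tolerance beyond the [0, 1] bounds.
#' @return An object of class `edr_result` with fields `edr`,
#'   `loading_area_N_mm` and `hysteresis_area_N_mm`.
#' @export
energy_dissipation_ratio <- function(loop, tol = 1e-9) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  if (loop$loading_only)
    stop("loop has no unloading branch; EDR undefined", call. = FALSE)
  a_load <- .trapz(loop$loading$displacement_mm, loop$loading$force_N)
  if (a_load <= 0)
    stop("zero loading area; EDR degenerate", call. = FALSE)
  # unloading branch runs peak -> trough; integrate over increasing displacement
  a_unload <- .trapz(rev(loop$unloading$displacement_mm),
                     rev(loop$unloading$force_N))
  a_hyst <- a_load - a_unload
  edr <- a_hyst / a_load
  if (edr < -tol || edr > 1 + tol)
    stop(sprintf("EDR = %.6g outside [0, 1] beyond tolerance", edr),
         call. = FALSE)
  structure(
    list(edr = min(max(edr, 0), 1),
         loading_area_N_mm = a_load,
         hysteresis_area_N_mm = a_hyst),
    class = "edr_result")
}

#' @export
print.edr_result <- function(x, ...) {
  cat(sprintf("<edr_result> EDR = %.4f (loading %.4g N mm, hysteresis %.4g N mm)\n",
              x$edr, x$loading_area_N_mm, x$hysteresis_area_N_mm))
  invisible(x)
}

#' Peak-load repeatability check across cycles
#'
#' Cyclic tests are considered repeatable when the maximum variation of the
#' peak force — the peak-to-peak spread max(peaks) - min(peaks) — stays
#' within `tolerance` times the maximum load. Per-cycle deviations from the
#' mean peak force are reported as diagnostics under both normalizations
#' (by the overall maximum peak and by the mean peak), since the reference
#' convention is a matter of choice.
#'
#' @param loops List of >= 2 [hysteresis_loop()]s.
#' @param tolerance Allowed fractional deviation (default 0.10).
#' @param skip_cycles Number of initial cycles to exclude (e.g. idle
#'   conditioning trials); default 0.
#' @return An object of class `repeatability_result` with fields `pass`,
#'   `peak_forces_N`, `max_variation` (spread / max peak),
#'   `deviation_of_max` (per-cycle |peak - mean| / max peak),
#'   `deviation_of_mean` (normalized by the mean peak instead) and
#'   `tolerance`.
#' @export
repeatability_check <- function(loops, tolerance = 0.10, skip_cycles = 0L) {
  stopifnot(is.list(loops),
            all(vapply(loops, inherits, logical(1), "hysteresis_loop")))
  if (skip_cycles > 0L) {
    if (length(loops) <= skip_cycles)
      stop("skip_cycles leaves no loops", call. = FALSE)
    loops <- loops[-seq_len(skip_cycles)]
  }
  if (length(loops) < 2L)
    stop("repeatability needs at least 2 loops", call. = FALSE)
  peaks <- vapply(loops, peak_force, numeric(1))
  dev_abs <- abs(peaks - mean(peaks))
  structure(
    list(pass = (max(peaks) - min(peaks)) <= tolerance * max(peaks),
         peak_forces_N = peaks,
         max_variation = (max(peaks) - min(peaks)) / max(peaks),
         deviation_of_max = dev_abs / max(peaks),
         deviation_of_mean = dev_abs / mean(peaks),
         tolerance = tolerance),
    class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability_result> %s at +/-%g%%: peaks (N) %s, max variation %.2f%% of max load\n",
              if (x$pass) "PASS" else "FAIL", 100 * x$tolerance,
              paste(signif(x$peak_forces_N, 4), collapse = ", "),
              100 * x$max_variation))
  invisible(x)
}
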