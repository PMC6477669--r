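test_that("a five-period triangular record segments into five loops", {
  rec <- generate_hysteresis_record(generator_spec(
    control_params(), n_cycles = 5, dissipation_q = 0.3,
    sampling_rate_hz = 10))
  loops <- segment_cycles(rec)
  expect_length(loops, 5)
  expect_equal(vapply(loops, `[[`, 1L, "cycle_index"), 1:5)
  expect_false(any(vapply(loops, `[[`, logical(1), "loading_only")))
})

test_that("a monotone ramp yields a single flagged loading-only loop", {
  rec <- generate_compression_record(generator_spec(control_params(),
                                                    sampling_rate_hz = 10))
  loops <- segment_cycles(rec)
  expect_length(loops, 1)
  expect_true(loops[[1]]$loading_only)
  expect_error(energy_dissipation_ratio(loops[[1]]), "unloading")
})

test_that("flat zero displacement cannot be segmented", {
  geo <- specimen_geometry(40, 18)
  rec <- compression_record(0:5, rep(0, 6), rep(0, 6), geo)
  expect_error(segment_cycles(rec), "flat zero displacement")
})

test_that("EDR degenerate and identity cases behave as documented", {
  d <- seq(0, 9, length.out = 51)
  f <- 2 * d
  # coinciding branches dissipate nothing
  same <- hysteresis_loop(data.frame(displacement_mm = d, force_N = f),
                          data.frame(displacement_mm = rev(d),
                                     force_N = rev(f)))
  expect_equal(energy_dissipation_ratio(same)$edr, 0, tolerance = 1e-14)
  # zero unloading force dissipates everything
  dead <- hysteresis_loop(data.frame(displacement_mm = d, force_N = f),
                          data.frame(displacement_mm = rev(d),
                                     force_N = rep(0, 51)))
  expect_equal(energy_dissipation_ratio(dead)$edr, 1, tolerance = 1e-14)
  # pointwise scaling scales the area integral
  scaled <- hysteresis_loop(data.frame(displacement_mm = d, force_N = f),
                            data.frame(displacement_mm = rev(d),
                                       force_N = 0.78 * rev(f)))
  expect_equal(energy_dissipation_ratio(scaled)$edr, 0.22, tolerance = 1e-14)
})

test_that("generator round trip returns the prescribed dissipation exactly", {
  for (q in c(0, 0.22, 0.25, 0.6)) {
    rec <- generate_hysteresis_record(generator_spec(
      control_params(), n_cycles = 2, dissipation_q = q,
      sampling_rate_hz = 25))
    for (loop in segment_cycles(rec)) {
      res <- energy_dissipation_ratio(loop)
      expect_equal(res$edr, q, tolerance = 1e-10)
      expect_lte(res$hysteresis_area_N_mm, res$loading_area_N_mm)
    }
  }
})

test_that("EDR error at least halves when the sampling is doubled", {
  # loading d^3 (area 9^4/4), unloading d^4/9 (area 9^4/5): EDR = 1 - 4/5
  f_load <- function(d) d^3
  f_unload <- function(d) d^4 / 9
  edr_at <- function(n)
    energy_dissipation_ratio(analytic_loop(f_load, f_unload, n = n))$edr
  err_n <- abs(edr_at(51) - 0.2)
  err_2n <- abs(edr_at(101) - 0.2)
  expect_lt(err_2n, err_n / 2)
})

test_that("repeatability verdict follows the max-load band", {
  mk <- function(peak) {
    d <- seq(0, 9, length.out = 21)
    hysteresis_loop(data.frame(displacement_mm = d,
                               force_N = peak * d / 9),
                    data.frame(displacement_mm = rev(d),
                               force_N = 0.8 * peak * rev(d) / 9))
  }
  pass <- repeatability_check(lapply(c(40, 41, 39, 40, 40), mk))
  expect_true(pass$pass)
  expect_true(all(pass$deviation_of_max <= 0.025 + 1e-12))
  fail <- repeatability_check(lapply(c(40, 46), mk))
  expect_false(fail$pass)
  equal <- repeatability_check(lapply(c(40, 40, 40), mk))
  expect_true(equal$pass)
  expect_equal(max(equal$deviation_of_max), 0)
  expect_error(repeatability_check(list(mk(40))), "at least 2")
})

test_that("skip_cycles excludes initial conditioning loops", {
  mk <- function(peak) {
    d <- seq(0, 9, length.out = 11)
    hysteresis_loop(data.frame(displacement_mm = d, force_N = peak * d / 9),
                    data.frame(displacement_mm = rev(d),
                               force_N = 0.5 * peak * rev(d) / 9))
  }
  loops <- lapply(c(20, 40, 40, 41), mk)  # first loop is an idle trial
  expect_false(repeatability_check(loops)$pass)
  expect_true(repeatability_check(loops, skip_cycles = 1)$pass)
})
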