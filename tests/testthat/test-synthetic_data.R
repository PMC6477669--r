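test_that("generator spec validates the protocol invariants", {
  p <- control_params()
  expect_error(generator_spec(p, max_displacement_mm = 18), "height")
  expect_error(generator_spec(p, dissipation_q = 1), "0, 1")
  expect_error(generator_spec(p, dissipation_q = -0.1), "0, 1")
  expect_error(generator_spec(p, force_noise_sd = -1), ">= 0")
  expect_error(generator_spec(p, rate_mm_per_s = 0), "> 0")
})

test_that("ramp timing follows displacement over rate", {
  rec <- generate_compression_record(generator_spec(
    control_params(), rate_mm_per_s = 0.8, max_displacement_mm = 9,
    sampling_rate_hz = 20))
  expect_equal(max(rec$time_s), 9 / 0.8, tolerance = 1e-12)  # 11.25 s
  expect_equal(max(rec$displacement_mm), 9)
})

test_that("noise-free records lie exactly on the forward model (closed loop)", {
  for (p in all_parameter_rows()) {
    rec <- generate_compression_record(generator_spec(p, sampling_rate_hz = 5))
    crv <- to_stress_stretch(rec)
    expect_equal(crv$stress_MPa, yeoh_uniaxial_stress(crv$stretch, p),
                 tolerance = 1e-12)
  }
})

test_that("seeded generation is deterministic down to the CSV bytes", {
  spec <- generator_spec(control_params(), force_noise_sd = 0.02, seed = 42,
                         sampling_rate_hz = 10)
  r1 <- generate_compression_record(spec)
  r2 <- generate_compression_record(spec)
  expect_identical(r1$force_N, r2$force_N)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_record_csv(r1, f1); write_record_csv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the noise
  r3 <- generate_compression_record(generator_spec(
    control_params(), force_noise_sd = 0.02, seed = 43,
    sampling_rate_hz = 10))
  expect_false(identical(r1$force_N, r3$force_N))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_compression_record(generator_spec(
    control_params(), force_noise_sd = 0.05, seed = 7, sampling_rate_hz = 5)))
  expect_identical(runif(1), before)
})

test_that("EDR plant fidelity holds across sampling rates", {
  for (fs in c(10, 50, 200)) {
    rec <- generate_hysteresis_record(generator_spec(
      control_params(), n_cycles = 1, dissipation_q = 0.37,
      sampling_rate_hz = fs))
    loop <- segment_cycles(rec)[[1]]
    expect_equal(energy_dissipation_ratio(loop)$edr, 0.37, tolerance = 1e-10)
  }
})

test_that("the load cap truncates a monotonic record", {
  rec <- generate_compression_record(generator_spec(
    yeoh_params(0.72, 0.35, 0.88), max_load_N = 40, sampling_rate_hz = 50))
  expect_lte(max(rec$force_N), 40)
  full <- generate_compression_record(generator_spec(
    yeoh_params(0.72, 0.35, 0.88), sampling_rate_hz = 50))
  expect_gt(max(full$force_N), 40)
  expect_lt(length(rec$force_N), length(full$force_N))
})

test_that("cohorts are deterministic, sized and labelled as requested", {
  plants <- list(a = yeoh_params(0.001, 0.01, 0.01),
                 b = yeoh_params(0.002, 0.02, 0.01))
  refs <- list(grp = yeoh_params(0.001, 0.01, 0.01))
  c1 <- generate_cohort(plants, refs, variability_sd = 0.1,
                        n_specimens = 4, seed = 13)
  c2 <- generate_cohort(plants, refs, variability_sd = 0.1,
                        n_specimens = 4, seed = 13)
  expect_length(c1$specimens, 8)  # 2 compositions x 4 specimens
  expect_equal(names(c1$mean_curves), c("a", "b"))
  expect_identical(c1$specimens[[3]]$force_N, c2$specimens[[3]]$force_N)
  expect_error(generate_cohort(list(), refs), "nonempty")
  # zero variability: every specimen sits on its plant, R^2 = 1 vs the twin
  c0 <- generate_cohort(plants, refs, variability_sd = 0, n_specimens = 2,
                        seed = 1)
  expect_equal(correlate_curves(c0$mean_curves$a, c0$references$grp), 1)
})

test_that("a 15-composition cohort yields 15 selection columns", {
  tab <- composition_table()
  set.seed(21)
  plants <- lapply(seq_len(nrow(tab)), function(i)
    yeoh_params(1e-4 * i, 0.009 + 1e-3 * i, 0.008))
  names(plants) <- tab$name
  refs <- list(healthy = plants[["60-20-10-10"]])
  cohort <- generate_cohort(plants, refs, variability_sd = 0,
                            n_specimens = 1, seed = 2, n_points = 20)
  rep <- select_surrogates(cohort$mean_curves, cohort$references)
  expect_equal(nrow(rep$r_squared), 15)
  expect_equal(unname(rep$best["healthy"]), "60-20-10-10")
})
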