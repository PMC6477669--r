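test_that("resampling interpolates linearly and refuses extrapolation", {
  crv <- labeled_curve("lin", seq(0, 0.4, by = 0.05), 2 * seq(0, 0.4, by = 0.05))
  # resampling onto the curve's own abscissae is the identity
  same <- resample_common_grid(crv, crv$strain)
  expect_equal(same$force_N, crv$force_N)
  expect_equal(same$label, "lin")
  # linear interpolation is exact on linear data, anywhere in the span
  grid <- c(0.013, 0.101, 0.377)
  expect_equal(resample_common_grid(crv, grid)$force_N, 2 * grid,
               tolerance = 1e-14)
  expect_error(resample_common_grid(crv, c(0.2, 0.5)), "extrapolation")
})

test_that("the default shared grid has 21 evenly spaced points", {
  a <- labeled_curve("a", c(0, 0.4), c(0, 1))
  b <- labeled_curve("b", c(0, 0.45), c(0, 1))
  grid <- shared_strain_grid(a, b)
  expect_length(grid, 21)
  expect_equal(unique(round(diff(grid), 12)), 0.02)
  expect_equal(range(grid), c(0, 0.4))
})

test_that("self-correlation is exactly 1 and disjoint spans fail", {
  eps <- seq(0, 0.5, length.out = 30)
  crv <- labeled_curve("x", eps, exp(3 * eps) - 1)
  expect_equal(correlate_curves(crv, crv), 1)
  far <- labeled_curve("y", seq(0.6, 0.9, length.out = 10), 1:10)
  expect_error(correlate_curves(crv, far), "overlap")
})

test_that("a candidate sharing the reference plant attains the top R^2", {
  plants <- list(
    "60-20-10-10" = yeoh_params(0.0002, 0.009, 0.008),
    "55-20-15-10" = yeoh_params(0.0004, 0.009, 0.010),
    "45-20-20-15" = yeoh_params(0.0006, 0.015, 0.010))
  refs <- list("healthy" = plants[["60-20-10-10"]])
  cohort <- generate_cohort(plants, refs, variability_sd = 0,
                            n_specimens = 1, seed = 5)
  rep <- select_surrogates(cohort$mean_curves, cohort$references)
  expect_equal(unname(rep$best["healthy"]), "60-20-10-10")
  expect_equal(unname(rep$r_squared["60-20-10-10", "healthy"]), 1)
  # exhaustive check: the matching plant's column entry is the maximum
  expect_equal(which.max(rep$r_squared[, "healthy"]),
               c("60-20-10-10" = 1))
})

test_that("selection semantics: admission, best-in-admitted, ties, ordering", {
  eps <- seq(0, 0.5, length.out = 25)
  mk <- function(label, k) labeled_curve(label, eps, k * eps^2)
  cands <- list(mk("a", 1), mk("b", 1.05), mk("c", 5))
  refs <- list(grp = mk("ref", 1))
  rep <- select_surrogates(cands, refs, threshold = 0.8)
  expect_true(rep$best[["grp"]] %in% rep$admitted[["grp"]])
  expect_equal(rep$best[["grp"]], "a")
  expect_false("c" %in% rep$admitted[["grp"]])
  # invariant to candidate ordering
  rep2 <- select_surrogates(rev(cands), refs, threshold = 0.8)
  expect_equal(rep2$best, rep$best)
  expect_equal(sort(rep2$admitted[["grp"]]), sort(rep$admitted[["grp"]]))
  # duplicate winners tie, broken lexicographically and flagged
  tied <- select_surrogates(list(mk("z", 1), mk("a", 1)), refs)
  expect_true(tied$tie[["grp"]])
  expect_equal(tied$best[["grp"]], "a")
})

test_that("raising the threshold never grows the admitted set", {
  eps <- seq(0, 0.5, length.out = 25)
  set.seed(8)
  cands <- lapply(1:6, function(i)
    labeled_curve(paste0("c", i), eps, eps^2 * runif(1, 0.5, 2)))
  refs <- list(grp = labeled_curve("ref", eps, eps^2))
  prev <- NULL
  for (thr in c(0.2, 0.5, 0.8, 0.95, 1)) {
    adm <- select_surrogates(cands, refs, threshold = thr)$admitted[["grp"]]
    if (!is.null(prev)) expect_true(all(adm %in% prev))
    prev <- adm
  }
  # threshold 1 with no perfect candidate: empty admitted, best still named
  rep <- select_surrogates(cands, refs, threshold = 1)
  if (length(rep$admitted[["grp"]]) == 0L)
    expect_true(nzchar(rep$best[["grp"]]))
  # single candidate equal to the reference admits and wins
  solo <- select_surrogates(list(labeled_curve("only", eps, eps^2)), refs,
                            threshold = 1)
  expect_equal(solo$admitted[["grp"]], "only")
  expect_equal(unname(solo$best[["grp"]]), "only")
})

test_that("empty selection inputs are rejected", {
  eps <- seq(0, 0.5, length.out = 10)
  crv <- labeled_curve("x", eps, eps)
  expect_error(select_surrogates(list(), list(g = crv)), "at least one")
  expect_error(select_surrogates(list(crv), list()), "at least one")
})
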