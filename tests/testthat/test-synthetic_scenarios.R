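test_that("sampling is reproducible under a fixed seed and leaves RNG alone", {
  sp <- sampling_spec(n_draws = 50, seed = 11)
  a <- sample_nuclide_vectors(sp, nodules)
  b <- sample_nuclide_vectors(sp, nodules)
  expect_identical(a, b)
  # different seed gives different draws
  c <- sample_nuclide_vectors(sampling_spec(50, 12), nodules)
  expect_false(identical(a, c))
  # the caller's RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(sample_nuclide_vectors(sp, nodules))
  expect_identical(.Random.seed, before)
})

test_that("zero CV collapses to the base vector; draws stay positive", {
  degenerate <- nuclide_vector(
    nodules$activities,
    stats::setNames(rep(0, length(nodules$activities)),
                    names(nodules$activities))
  )
  draws <- sample_nuclide_vectors(sampling_spec(10, 3), degenerate)
  for (d in draws) expect_equal(d$activities, nodules$activities)

  draws2 <- sample_nuclide_vectors(sampling_spec(500, 4), nodules)
  for (d in draws2) expect_true(all(d$activities > 0))
})

test_that("a nuclide without stated uncertainty cannot be sampled", {
  partial <- nuclide_vector(c("Ra-226" = 2317, "Pb-210" = 1098),
                            rel_uncertainty = c("Ra-226" = 13))
  expect_error(sample_nuclide_vectors(sampling_spec(5, 1), partial),
               "Pb-210")
})

test_that("lognormal sampling recovers the measured mean and CV", {
  # law-of-large-numbers oracle at n = 10,000
  sp <- sampling_spec(n_draws = 10000, seed = 20)
  draws <- sample_nuclide_vectors(sp, nodules)
  ra <- vapply(draws, function(d) d$activities[["Ra-226"]], numeric(1))
  expect_equal(mean(ra), 2317, tolerance = 0.02)
  expect_equal(stats::sd(ra) / mean(ra), 0.13, tolerance = 0.10)
})

test_that("common-mode factor correlates nuclides without shifting means", {
  sp <- sampling_spec(n_draws = 4000, seed = 8, common_mode_cv = 0.5)
  draws <- sample_nuclide_vectors(sp, nodules)
  ra <- vapply(draws, function(d) d$activities[["Ra-226"]], numeric(1))
  th <- vapply(draws, function(d) d$activities[["Th-230"]], numeric(1))
  expect_gt(stats::cor(ra, th), 0.5)
  expect_equal(mean(ra), 2317, tolerance = 0.05)
})

test_that("degenerate Monte Carlo collapses to the deterministic doses", {
  inv <- default_inventory()
  # zero out all uncertainties
  inv0 <- lapply(inv, function(v) {
    nuclide_vector(v$activities,
                   stats::setNames(rep(0, length(v$activities)),
                                   names(v$activities)),
                   v$material_label)
  })
  sp1 <- sampling_spec(20, 5, surface_multiplier_range = c(1, 1))
  mc1 <- monte_carlo_dose(sp1, packaged_scenario("processing_plant"), inv0)
  sub <- mc1$summary[mc1$summary$quantity == "subtotal_excl_radon", ]
  expect_equal(sub$mean, 0.5987, tolerance = 1e-3)
  expect_equal(sub$sd, 0)
  expect_equal(sub$q05, sub$q95)

  sp3 <- sampling_spec(20, 5, surface_multiplier_range = c(3, 3))
  mc3 <- monte_carlo_dose(sp3, packaged_scenario("processing_plant"), inv0)
  sub3 <- mc3$summary[mc3$summary$quantity == "subtotal_excl_radon", ]
  expect_equal(round(sub3$mean, 1), 1.8)
})

test_that("mean-preserving sampling recovers the deterministic dose", {
  # brute-force MC oracle: with mean-preserving lognormals and linear
  # pathways, the expected gamma+dust dose equals the central 0.6 mSv/a
  sp <- sampling_spec(5000, 17, surface_multiplier_range = c(1, 1))
  mc <- monte_carlo_dose(sp, packaged_scenario("processing_plant"))
  sub <- mc$summary[mc$summary$quantity == "subtotal_excl_radon", ]
  expect_equal(sub$mean, 0.5987, tolerance = 0.05)
  expect_gt(sub$sd, 0)
  # radon concentration is a fixed input here: no spread
  rn <- mc$summary[mc$summary$quantity == "radon", ]
  expect_equal(rn$sd, 0)
  expect_equal(rn$mean, 1.872, tolerance = 1e-12)
})

test_that("widening the multiplier range widens the dose percentiles", {
  widths <- list(c(1, 1), c(1, 2), c(1, 3))
  spans <- vapply(widths, function(w) {
    sp <- sampling_spec(800, 33, surface_multiplier_range = w)
    mc <- monte_carlo_dose(sp, packaged_scenario("processing_plant"))
    sub <- mc$summary[mc$summary$quantity == "subtotal_excl_radon", ]
    sub$q95 - sub$q05
  }, numeric(1))
  expect_true(all(diff(spans) > 0))
})

test_that("parameter perturbations reach the pathway configs", {
  # pin t_exp to a single value via a zero-width range: transport gamma
  # time 2000 -> 1000 halves the dose
  sp <- sampling_spec(10, 2, surface_multiplier_range = c(1, 1),
                      parameter_perturbations = list(t_exp = c(1000, 1000)))
  inv <- default_inventory()
  inv0 <- lapply(inv, function(v) {
    nuclide_vector(v$activities,
                   stats::setNames(rep(0, length(v$activities)),
                                   names(v$activities)), v$material_label)
  })
  mc <- monte_carlo_dose(sp, packaged_scenario("transport"), inv0)
  tot <- mc$summary[mc$summary$quantity == "total", ]
  expect_equal(tot$mean, 0.6951 / 2, tolerance = 1e-3)
})

test_that("sampling spec validates ranges", {
  expect_error(sampling_spec(0, 1))
  expect_error(sampling_spec(10, 1, surface_multiplier_range = c(3, 1)),
               "well-ordered")
  expect_error(sampling_spec(10, 1,
                             parameter_perturbations = list(t_exp = c(2, 1))),
               "well-ordered")
})
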