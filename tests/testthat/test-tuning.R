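# Cheap analytic "engine": simulates curves from a closed-form model whose
# shape depends smoothly on the source parameters, plus seeded noise. This
# keeps the tuning-logic tests independent of transport-engine cost; the
# engine-backed recovery is exercised in the acceptance suite.
toy_simulator <- function(noise = 0.3) {
  function(source, seed) {
    withr::with_seed(seed, {
      zmax <- 2 * source$mean_energy - 1.5 * source$sigma_e
      r50 <- 4 * source$mean_energy
      pdd <- generate_parametric_pdd(zmax, r50,
                                     grid = seq(0, 60, by = 1))
      pdd$value <- pdd$value + noise * rnorm(nrow(pdd))
      width <- 50 + 3 * source$spot_fwhm + 8 * source$divergence
      pos <- seq(-60, 60, by = 2)
      prof <- 100 / (1 + exp((abs(pos) - width / 2) / 2))
      inp <- ioert_curve(pos, prof + noise * rnorm(length(pos)),
                         axis = "inplane")
      cro <- ioert_curve(pos, prof + noise * rnorm(length(pos)),
                         axis = "crossplane")
      list(pdd = pdd, inplane = inp, crossplane = cro)
    })
  }
}

toy_reference <- function(truth, seed = 500, noise = 0.3) {
  toy_simulator(noise)(truth, seed)
}

test_that("an initial source that already passes is returned unchanged", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  refs <- toy_reference(truth)
  spec <- search_spec(energy_box = 0.2, sigma_box = 0.03)
  res <- tune_energy(refs, truth, spec, toy_simulator())
  expect_equal(res$source$mean_energy, 9.8)
  expect_equal(res$source$sigma_e, 0.9)
  expect_true(res$converged)
  expect_equal(nrow(res$log), 1) # stopped at the first (initial) ring
})

test_that("energy tuning recovers the truth within one grid step", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  # the clinical 3%/3 mm gate cannot resolve 0.05 MeV steps on smooth toy
  # curves; a tight gate and low noise exercise the ring-ordered search
  # itself (engine-statistics recovery lives in the acceptance suite)
  refs <- toy_reference(truth, noise = 0.05)
  spec <- search_spec(energy_box = 0.3, sigma_box = 0.03)
  start <- beam_source(9.6, 0.92, 1.6, 0)
  res <- tune_energy(refs, start, spec, toy_simulator(noise = 0.05),
                     criteria = gamma_criteria(0.5, 0.2))
  expect_true(res$converged)
  expect_lte(abs(res$source$mean_energy - 9.8), spec$energy_step + 1e-9)
  expect_lte(abs(res$source$sigma_e - 0.9), spec$sigma_box + 1e-9)
})

test_that("geometry tuning handles boundaries and degenerate grids", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  refs <- toy_reference(truth)
  # divergence grid includes and accepts the 0 degree boundary
  spec <- search_spec(spot_range = c(0.5, 3), div_range = c(0, 2))
  start <- beam_source(9.8, 0.9, 2.0, 0.5)
  res <- tune_geometry(refs, start, spec, toy_simulator(),
                       criteria = gamma_criteria(1, 1))
  expect_true(res$converged)
  expect_lte(res$source$divergence, 0.5)
  # degenerate single-candidate spec returns that candidate with its rate
  spec1 <- search_spec(spot_range = c(1.6, 1.6), div_range = c(0, 0))
  res1 <- tune_geometry(refs, beam_source(9.8, 0.9, 1.6, 0), spec1,
                        toy_simulator())
  expect_equal(res1$source$spot_fwhm, 1.6)
  expect_equal(res1$source$divergence, 0)
  expect_equal(nrow(res1$log), 1)
})

test_that("full tuning alternates to convergence and logs every evaluation", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  refs <- toy_reference(truth)
  spec <- search_spec(energy_box = 0.2, sigma_box = 0.02,
                      spot_range = c(1, 3), div_range = c(0, 1),
                      max_iterations = 2)
  refs <- toy_reference(truth, noise = 0.05)
  start <- beam_source(9.7, 0.88, 2.2, 0.5)
  crit <- gamma_criteria(0.5, 0.2)
  sim <- toy_simulator(noise = 0.05)
  res <- tune_full(refs, start, spec, sim, criteria = crit)
  expect_s3_class(res, "tuning_result")
  expect_true(res$converged)
  expect_lte(res$iterations, 2)
  expect_true(all(unlist(res$pass_rates) > 95))
  expect_lte(abs(res$source$mean_energy - 9.8), spec$energy_step + 1e-9)
  # log completeness: seeds are unique, stages labeled, rates recorded
  expect_false(any(duplicated(res$log$seed)))
  expect_true(all(c("initial", "energy", "geometry") %in% res$log$stage))
  # determinism: the whole procedure reproduces exactly
  res2 <- tune_full(refs, start, spec, sim, criteria = crit)
  expect_identical(glance(res2), glance(res))
  expect_identical(res2$log, res$log)
})

test_that("max_iterations = 0 evaluates the initial source only", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  refs <- toy_reference(truth)
  spec <- search_spec(max_iterations = 0)
  start <- beam_source(9.0, 0.8, 4, 2)
  res <- tune_full(refs, start, spec, toy_simulator())
  expect_equal(res$iterations, 0)
  expect_false(res$converged)
  expect_equal(nrow(res$log), 1)
  expect_equal(res$source$mean_energy, 9.0)
})

test_that("noisier references degrade pass rates monotonically on average", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  rates <- vapply(c(0.5, 2, 6), function(noise) {
    sim <- toy_simulator(noise = 0)
    refs <- toy_simulator(noise = noise)(truth, seed = 808)
    g <- gamma_curve(refs$pdd, sim(truth, 1)$pdd)
    g$pass_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[3], 100)
})

test_that("tidy and glance expose the tuning log and summary", {
  truth <- beam_source(9.8, 0.9, 1.6, 0)
  refs <- toy_reference(truth)
  res <- tune_full(refs, truth, search_spec(max_iterations = 0),
                   toy_simulator())
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_named(g, c("mean_energy", "sigma_e", "spot_fwhm", "divergence",
                    "pass_pdd", "pass_inplane", "pass_crossplane",
                    "converged", "iterations", "n_evaluations"))
})
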