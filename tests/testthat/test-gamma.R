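# dense-grid brute-force oracle, independent of the implementation
gamma_bruteforce <- function(ref, ev, dose_pct = 3, dta_mm = 3,
                             step = 0.01) {
  d_norm <- max(ref$value)
  xs <- seq(min(ev$position_mm), max(ev$position_mm), by = step)
  ys <- approx(ev$position_mm, ev$value, xout = xs)$y
  vapply(seq_len(nrow(ref)), function(i) {
    min(sqrt((xs - ref$position_mm[i])^2 / dta_mm^2 +
               (ys - ref$value[i])^2 / (dose_pct / 100 * d_norm)^2))
  }, numeric(1))
}

test_that("identical curves give gamma zero and 100% pass rate", {
  cv <- fixture_pdd_curve()
  g <- gamma_curve(cv, cv)
  expect_true(all(g$data$gamma < 1e-12))
  expect_equal(g$pass_rate, 100)
})

test_that("a 3% uniform offset on a flat curve sits exactly on the pass boundary", {
  flat <- ioert_curve(seq(0, 50, 1), rep(100, 51))
  scaled <- ioert_curve(seq(0, 50, 1), rep(103, 51))
  g <- gamma_curve(flat, scaled)
  # gamma = 1 at every point; the boundary counts as passing
  expect_equal(g$data$gamma, rep(1, 51), tolerance = 1e-9)
  expect_equal(g$pass_rate, 100)
})

test_that("gamma equals the brute-force oracle on random curve pairs", {
  set.seed(2024)
  worst <- 0
  for (rep in 1:100) {
    n <- 50
    pos <- seq(0, n - 1)
    base <- 60 + 40 * sin(seq(0, 3, length.out = n) + runif(1, 0, 6)) *
      exp(-seq(0, 2, length.out = n))
    ref <- ioert_curve(pos, base + rnorm(n, 0, 2))
    ev <- ioert_curve(pos, base * runif(1, 0.95, 1.05) + rnorm(n, 0, 2))
    # search window widened to cover the whole curve so the comparison with
    # the global brute-force minimum is exact
    g <- gamma_curve(ref, ev, gamma_criteria(interp_step_mm = 0.01,
                                             search_factor = 20))
    oracle <- gamma_bruteforce(ref, ev)
    # identical 0.01 mm discretization: agreement to numerical precision
    worst <- max(worst, max(abs(g$data$gamma - oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("gamma is scale-invariant and monotone in the tolerances", {
  set.seed(9)
  pos <- seq(0, 40)
  ref <- ioert_curve(pos, 100 * exp(-(pos - 15)^2 / 120) + rnorm(41, 0, 1))
  ev <- ioert_curve(pos, 98 * exp(-(pos - 16)^2 / 110) + rnorm(41, 0, 1))
  g1 <- gamma_curve(ref, ev)
  # simultaneous rescaling of both curves leaves gamma unchanged
  ref2 <- ioert_curve(pos, ref$value * 7.3)
  ev2 <- ioert_curve(pos, ev$value * 7.3)
  g2 <- gamma_curve(ref2, ev2)
  expect_equal(g2$data$gamma, g1$data$gamma, tolerance = 1e-12)
  # shrinking either tolerance never decreases any gamma
  g_tight_d <- gamma_curve(ref, ev, gamma_criteria(dose_pct = 2))
  g_tight_r <- gamma_curve(ref, ev, gamma_criteria(dta_mm = 2))
  expect_true(all(g_tight_d$data$gamma >= g1$data$gamma - 1e-12))
  expect_true(all(g_tight_r$data$gamma >= g1$data$gamma - 1e-12))
})

test_that("degenerate inputs are rejected", {
  cv <- fixture_pdd_curve()
  empty <- ioert_curve(numeric(0), numeric(0))
  expect_error(gamma_curve(empty, cv), "non-empty")
  far <- ioert_curve(cv$position_mm + 1000, cv$value)
  expect_error(gamma_curve(cv, far), "disjoint")
})

test_that("configuration evaluation applies thresholds per curve set", {
  cv <- fixture_pdd_curve()
  prof <- ioert_curve(seq(-60, 60), 100 / (1 + exp((abs(seq(-60, 60)) - 50) / 3)),
                      axis = "inplane")
  refs <- list(pdd = cv, inplane = prof, crossplane = prof)
  res <- evaluate_configuration(refs, refs, threshold_pct = 95)
  expect_true(res$verdict)
  expect_equal(res$results$pass_rate, rep(100, 3))
  # one curve displaced by 10 mm in its gradient: gamma fails broadly
  shifted <- ioert_curve(prof$position_mm, approx(prof$position_mm - 10,
                         prof$value, xout = prof$position_mm, rule = 2)$y,
                         axis = "inplane")
  res2 <- evaluate_configuration(refs, list(pdd = cv, inplane = shifted,
                                            crossplane = prof),
                                 threshold_pct = 95)
  expect_false(res2$verdict)
  gam <- res2$gammas$inplane$data
  in_gradient <- abs(abs(gam$position_mm) - 50) < 8
  big_diff <- abs(gam$reference -
                    approx(shifted$position_mm, shifted$value,
                           gam$position_mm, rule = 2)$y) > 3
  expect_true(all(gam$gamma[in_gradient & big_diff] > 1))
  # a 92%-passing construction passes the 90% tuning gate but fails the
  # 95% final gate
  # step-offset evaluated curve (+10% for positions >= 21): reference
  # points 24 and 25 sit beyond the 3 mm DTA reach of any matching dose,
  # so exactly 2 of 25 fail
  flat <- ioert_curve(seq(1, 25), rep(100, 25))
  two_off <- ioert_curve(seq(1, 25), c(rep(100, 20), rep(110, 5)))
  r90 <- evaluate_configuration(list(a = flat), list(a = two_off),
                                threshold_pct = 90)
  r95 <- evaluate_configuration(list(a = flat), list(a = two_off),
                                threshold_pct = 95)
  expect_equal(r90$results$pass_rate, 92)
  expect_true(r90$verdict)
  expect_false(r95$verdict)
  expect_error(evaluate_configuration(refs[1:2], refs), "size")
})
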