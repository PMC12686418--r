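test_that("recording captures +z crossings with unit directions", {
  machine <- fixture_machine()
  ps <- record_phase_space(preset_source(9), machine,
                           fixture_phantom(c(8, 8, 4)),
                           transport_config(5e3, seed = 3))
  expect_gt(nrow(ps), 0)
  expect_true(all(ps$particle_type == 0))  # electron-only engine: no photons
  expect_true(all(ps$energy > 0))
  expect_lt(max(abs(ps$u^2 + ps$v^2 + ps$w^2 - 1)), 1e-9)
  expect_equal(attr(ps, "plane_z"), machine$phsp_plane_z)
})

test_that("zero histories record an empty list and invalid planes error", {
  machine <- fixture_machine()
  ps0 <- record_phase_space(preset_source(9), machine,
                            fixture_phantom(c(8, 8, 4)),
                            transport_config(0, seed = 3))
  expect_equal(nrow(ps0), 0)
  expect_error(run_simulation(preset_source(9), machine,
                              fixture_phantom(c(8, 8, 4)),
                              transport_config(10), record_plane_z = 50),
               "plane")
})

test_that("replay conserves record count and validates records", {
  machine <- fixture_machine()
  ps <- record_phase_space(preset_source(9), machine,
                           fixture_phantom(c(8, 8, 4)),
                           transport_config(5e3, seed = 3))
  src <- replay_phase_space(ps)
  g <- run_simulation(src, machine, fixture_phantom(c(8, 8, 4)),
                      transport_config(nrow(ps), seed = 4))
  # one replayed primary per record
  expect_equal(g$tallies[["injected"]], sum(ps$energy))
  # malformed direction rejected
  bad <- ps
  bad$u[1] <- bad$u[1] + 0.1
  expect_error(replay_phase_space(bad), "non-unit")
  empty <- ps[0, ]
  expect_error(replay_phase_space(empty), "empty")
})

test_that("single straight-down record deposits along its own column", {
  machine <- fixture_machine()
  rec <- ioertmc:::phase_space_tibble(
    matrix(c(9, 5, -3, 0, 0, 1, 1), nrow = 1), plane_z = -50)
  g <- run_simulation(replay_phase_space(rec), machine,
                      fixture_phantom(c(8, 8, 4), spacing_mm = 2),
                      transport_config(1, seed = 1))
  nz <- dim(g$energy)[3]
  hit <- which(g$energy > 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  # all deposits stay within a few voxels of the (5, -3) entry column
  xs <- grid_axis(g, 1)[hit[, 1]]
  ys <- grid_axis(g, 2)[hit[, 2]]
  expect_lt(max(abs(xs - 5)), 15)
  expect_lt(max(abs(ys + 3)), 15)
})

test_that("full run and phase-space replay agree downstream", {
  machine <- fixture_machine()
  phantom <- fixture_phantom(c(12, 12, 7))
  n <- 2.5e5
  g_full <- run_simulation(preset_source(9), machine, phantom,
                           transport_config(n, seed = 21),
                           record_plane_z = machine$phsp_plane_z)
  ps <- attr(g_full, "phase_space")
  g_replay <- run_simulation(replay_phase_space(ps), machine, phantom,
                             transport_config(nrow(ps), seed = 22))
  # global consistency: the replayed ensemble deposits the same fraction of
  # its energy in the phantom as the recorded particles did originally
  frac_full <- g_full$tallies[["deposited_phantom"]] / sum(ps$energy)
  frac_rep <- g_replay$tallies[["deposited_phantom"]] /
    g_replay$tallies[["injected"]]
  expect_equal(frac_rep, frac_full, tolerance = 0.01)
  # laterally integrated depth-dose curves (low-noise at this history
  # count) pass the 3%/3 mm gamma comparison completely
  idd <- function(g) ioert_curve(grid_axis(g, 3),
                                 apply(g$energy, 3, sum))
  g_idd <- gamma_curve(normalize_curve(idd(g_full)),
                       normalize_curve(idd(g_replay)))
  expect_equal(g_idd$pass_rate, 100)
  # central-axis PDDs agree within their combined counting uncertainty:
  # the normalized residuals must be of order one, not systematically large
  pdd_f <- normalize_curve(extract_pdd(g_full))
  pdd_r <- normalize_curve(extract_pdd(g_replay))
  ok <- pdd_f$sigma > 0 & pdd_r$sigma > 0 & pdd_f$value > 10
  zres <- (pdd_f$value[ok] - pdd_r$value[ok]) /
    sqrt(pdd_f$sigma[ok]^2 + pdd_r$sigma[ok]^2)
  expect_lt(mean(zres^2), 4)
  expect_lt(abs(mean(zres)), 1)
})

test_that("phase-space binary file roundtrip is bit-identical", {
  machine <- fixture_machine()
  ps <- record_phase_space(preset_source(9), machine,
                           fixture_phantom(c(8, 8, 4)),
                           transport_config(3e3, seed = 13))
  f1 <- tempfile(fileext = ".phsp")
  f2 <- tempfile(fileext = ".phsp")
  write_phase_space(ps, f1)
  back <- read_phase_space(f1)
  write_phase_space(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(nrow(back), nrow(ps))
  expect_equal(attr(back, "plane_z"), attr(ps, "plane_z"))
  # float32 storage: values agree to single precision
  expect_equal(back$energy, ps$energy, tolerance = 1e-6)
  # CSV debug dialect roundtrip
  fc <- tempfile(fileext = ".csv")
  write_phase_space_csv(back, fc)
  back2 <- read_phase_space_csv(fc)
  expect_equal(back2$energy, back$energy, tolerance = 1e-12)
  expect_equal(attr(back2, "plane_z"), attr(back, "plane_z"))
})
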