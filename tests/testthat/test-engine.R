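test_that("zero histories give an all-zero grid", {
  g <- run_simulation(preset_source(9), fixture_machine(),
                      fixture_phantom(c(4, 4, 4)), transport_config(0))
  expect_true(all(g$energy == 0))
  expect_true(all(g$entries == 0))
  expect_equal(g$tallies[["injected"]], 0)
})

test_that("energy bookkeeping closes on every run", {
  for (nominal in c(6, 9)) {
    g <- fixture_run(nominal, n = 2e4, seed = 11)
    eb <- energy_balance(g)
    expect_lt(eb$relative_error, 1e-6)
    # grid total matches the phantom tally and never exceeds injected energy
    expect_equal(sum(g$energy), g$tallies[["deposited_phantom"]],
                 tolerance = 1e-9)
    expect_lte(sum(g$energy), g$tallies[["injected"]])
  }
})

test_that("identical config and seed reproduce the grid bit for bit", {
  g1 <- run_simulation(preset_source(9), fixture_machine(),
                       fixture_phantom(c(8, 8, 6)), transport_config(5e3, seed = 99))
  g2 <- run_simulation(preset_source(9), fixture_machine(),
                       fixture_phantom(c(8, 8, 6)), transport_config(5e3, seed = 99))
  expect_identical(g1$energy, g2$energy)
  expect_identical(g1$entries, g2$entries)
  g3 <- run_simulation(preset_source(9), fixture_machine(),
                       fixture_phantom(c(8, 8, 6)), transport_config(5e3, seed = 100))
  expect_false(identical(g1$energy, g3$energy))
})

test_that("voxel uncertainty is 1/sqrt(entries) with zero-entry voxels flagged", {
  g <- fixture_run(9, n = 2e4, seed = 11)
  u <- voxel_uncertainty(g)
  expect_true(any(is.na(u)))          # empty voxels undefined, not zero
  i <- which(g$entries == 10000)
  if (length(i) == 0) i <- which(g$entries > 0)[1]
  expect_equal(u[i][1], 1 / sqrt(g$entries[i][1]))
  expect_true(all(is.na(u[g$entries == 0])))
})

test_that("central-axis uncertainty scales as 1/sqrt(N)", {
  dose_unc <- function(n) {
    g <- fixture_run(9, n = n, seed = 23)
    ic <- round(g$dims[1:2] / 2)
    iz <- which.min(abs(grid_axis(g, 3) - 15))
    cnt <- sum(g$entries[ic[1] + (-8:8), ic[2] + (-8:8), iz])
    1 / sqrt(cnt)
  }
  u1 <- dose_unc(5e4)
  u2 <- dose_unc(2e5)   # 4x histories
  u3 <- dose_unc(5e5)   # 10x histories
  expect_equal(u1 / u2, 2, tolerance = 0.15)
  expect_equal(u1 / u3, sqrt(10), tolerance = 0.15)
})

test_that("broad-beam depth dose shows build-up then monotone fall-off", {
  g <- fixture_run(9, n = 5e5, seed = 23)
  pdd <- normalize_curve(extract_pdd(g))
  sm <- pdd
  for (k in 1:10) sm$value <- ioertmc:::smooth3(sm$value)
  imax <- which.max(sm$value)
  expect_gt(imax, 1)                        # interior maximum
  expect_lt(sm$value[1], sm$value[imax])    # entrance below peak
  # monotone decrease through the fall-off (from below the peak plateau
  # down to the 5% level, where residual counting noise takes over),
  # allowing sub-percent smoothed-noise wiggles
  distal <- which(sm$position_mm > sm$position_mm[imax] &
                    sm$value < 0.8 * sm$value[imax] &
                    sm$value > 0.05 * sm$value[imax])
  expect_true(all(diff(sm$value[distal]) <= 0.01 * sm$value[imax]))
})

test_that("labeled phantoms transport through per-voxel materials", {
  # two-material slab phantom: 1 cm water then copper. A replayed on-axis
  # pencil (phase-space record just above the surface, so the head foils
  # play no role) must cross the water but stop within millimetres of
  # copper.
  ph <- water_phantom(c(6, 6, 4), spacing_mm = 2)
  mats <- ioert_materials()
  midx <- stats::setNames(seq_along(mats) - 1L, names(mats))
  mat_vox <- array(midx[["water"]], dim = ph$dims)
  zax <- ph$origin[3] + (seq_len(ph$dims[3]) - 0.5) * ph$spacing[3]
  mat_vox[, , zax > 10] <- midx[["copper"]]
  ph$labels <- array(0L, dim = ph$dims)
  ph$material_index <- as.integer(as.vector(mat_vox))
  ph$material <- "labeled"
  rec <- ioertmc:::phase_space_tibble(
    matrix(c(12, 0, 0, 0, 0, 1, 1), nrow = 1), plane_z = -5)
  g <- run_simulation(replay_phase_space(rec), fixture_machine(),
                      ph, transport_config(200, seed = 5))
  layer <- apply(g$energy, 3, sum)
  in_w <- zax < 10
  in_cu_deep <- zax > 18  # more than one range-in-copper past the interface
  expect_true(all(layer[in_w] > 0))
  expect_equal(sum(layer[in_cu_deep]), 0, tolerance = 1e-9)
  # energy per layer rises sharply in copper (density jump)
  expect_gt(max(layer[zax > 10 & zax < 18]), 2 * max(layer[in_w]))
})
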