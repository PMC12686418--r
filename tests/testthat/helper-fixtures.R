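# Shared fixtures: engine runs are cached per-session so several test files
# can reuse the same grids without re-simulating.

fixture_cache <- new.env(parent = emptyenv())

fixture_machine <- function(diameter_cm = 10, bevel = 0, gap_cm = 0,
                            nominal = 9) {
  build_machine(default_machine_stack(nominal), applicator(diameter_cm, bevel),
                gap_cm = gap_cm)
}

fixture_phantom <- function(size_cm = c(16, 16, 8), spacing_mm = 1) {
  water_phantom(size_cm, spacing_mm)
}

fixture_run <- function(nominal = 9, n = 2e5, seed = 42, diameter_cm = 10,
                        gap_cm = 0, size_cm = c(16, 16, 8)) {
  key <- paste(nominal, n, seed, diameter_cm, gap_cm,
               paste(size_cm, collapse = "x"), sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- run_simulation(
      preset_source(nominal),
      fixture_machine(diameter_cm, gap_cm = gap_cm, nominal = nominal),
      fixture_phantom(size_cm),
      transport_config(n, seed = seed))
  }
  fixture_cache[[key]]
}

# deterministic synthetic curve for gamma/tuning unit tests
fixture_pdd_curve <- function(zmax = 18, r50 = 36) {
  generate_parametric_pdd(zmax, r50)
}

# a small thorax phantom at coarse pitch for organ-dose tests: full registry,
# 4 mm voxels to keep memory/time down
fixture_thorax <- function(disk = shield_disk(), spacing_mm = 4) {
  key <- paste("thorax", spacing_mm, is.null(disk),
               if (!is.null(disk)) paste(disk$thickness, disk$offset[1]) else "",
               sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- build_thorax_phantom(spacing_mm = spacing_mm,
                                                 disk = disk)
  }
  fixture_cache[[key]]
}
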