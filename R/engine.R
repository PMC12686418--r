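#' Transport configuration
#'
#' Stepping controls for the condensed-history engine. The defaults — 1 mm
#' maximum step in the phantom (matching the 1 mm voxel pitch) and a 0.2 MeV
#' cutoff below which the residual energy deposits locally — are desk-scale
#' choices; they do not claim equivalence with a general-purpose transport
#' code's stepping.
#'
#' @param n_histories Number of primary electrons (>= 0).
#' @param seed Integer RNG seed for the engine's private generator.
#' @param max_step Maximum step in the phantom, mm (> 0).
#' @param cutoff Kinetic-energy cutoff, MeV (> 0).
#' @param max_step_air Maximum step in the machine/air region, mm.
#' @export
transport_config <- function(n_histories, seed = 1, max_step = 1,
                             cutoff = 0.2, max_step_air = 10) {
  stopifnot(n_histories >= 0, max_step > 0, cutoff > 0, max_step_air > 0)
  structure(list(n_histories = as.double(n_histories), seed = as.double(seed),
                 max_step = max_step, cutoff = cutoff,
                 max_step_air = max_step_air),
            class = "transport_config")
}

#' Voxelized water phantom specification
#'
#' A water cube with its entrance face at z = 0 and the beam axis through
#' (x, y) = (0, 0). Voxels use half-open intervals; the voxel count is always
#' derived from dimensions and spacing.
#'
#' @param size_cm Extent in cm along (x, y, z).
#' @param spacing_mm Voxel pitch in mm (scalar or length 3).
#' @export
#' @examples
#' water_phantom(c(20, 20, 6))
water_phantom <- function(size_cm = c(30, 30, 30), spacing_mm = 1) {
  stopifnot(all(size_cm > 0), all(spacing_mm > 0))
  spacing <- rep(spacing_mm, length.out = 3)
  dims <- as.integer(round(size_cm * 10 / spacing))
  structure(list(
    origin = c(-dims[1] * spacing[1] / 2, -dims[2] * spacing[2] / 2, 0),
    spacing = spacing, dims = dims, material = "water", labels = NULL),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d voxels at (%g, %g, %g) mm, material: %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2],
              x$spacing[3], if (is.null(x$labels)) x$material else "labeled"))
  invisible(x)
}

new_dose_grid <- function(energy, entries, origin, spacing, dims, tallies, meta) {
  dim(energy) <- dims
  dim(entries) <- dims
  structure(list(energy = energy, entries = entries, origin = origin,
                 spacing = spacing, dims = dims, tallies = tallies,
                 meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  deposited %.4g MeV in phantom from %.4g MeV injected (%g histories)\n",
              x$tallies[["deposited_phantom"]], x$tallies[["injected"]],
              x$meta$n_histories))
  invisible(x)
}

#' Run the condensed-history transport engine
#'
#' Transports electrons from a parametric source (or a replayed phase space)
#' through the machine geometry into a voxelized phantom, scoring deposited
#' energy (MeV) and distinct-electron entry counts per voxel. Radiative
#' (bremsstrahlung) losses are removed from the electron but not transported;
#' runs are bit-reproducible for a fixed config and seed.
#'
#' @param source A [beam_source()], or a phase-space record tibble from
#'   [record_phase_space()]/[read_phase_space()] replayed via
#'   [replay_phase_space()].
#' @param machine An [build_machine()] geometry.
#' @param phantom A [water_phantom()] or [build_thorax_phantom()] spec.
#' @param config A [transport_config()].
#' @param record_plane_z If non-`NULL`, record a phase space on the plane at
#'   this z (mm; must lie inside the geometry, upstream of the phantom).
#' @param materials Material set, by default [ioert_materials()].
#' @return A `dose_grid` with per-voxel energy and entry counts, energy
#'   tallies, and (if requested) the recorded phase space in
#'   `attr(, "phase_space")`.
#' @export
run_simulation <- function(source, machine, phantom, config,
                           record_plane_z = NULL,
                           materials = ioert_materials()) {
  stopifnot(inherits(machine, "ioert_machine"),
            inherits(phantom, "phantom_spec"),
            inherits(config, "transport_config"))

  geo <- machine_for_engine(machine, materials)
  mats <- geo$materials
  mat_index <- stats::setNames(seq_along(mats) - 1L, names(mats))

  if (is.null(phantom$labels)) {
    vox_mat <- mat_index[[phantom$material]]
  } else {
    vox_mat <- phantom$material_index # precomputed 0-based per-voxel indices
    mats <- c(mats, phantom$extra_materials %||% list())
    mat_index <- stats::setNames(seq_along(mats) - 1L, names(mats))
  }

  src <- source_for_engine(source, machine)

  record <- !is.null(record_plane_z)
  plane_z <- if (record) record_plane_z else -1e9
  if (record) {
    if (plane_z >= phantom$origin[3] || plane_z <= machine$stack$source_z_mm) {
      stop("phase-space plane must lie inside the geometry, upstream of the phantom")
    }
  }

  res <- cpp_run_transport(
    source = src,
    elements_list = as.list(geo$elements),
    phantom = list(origin = as.double(phantom$origin),
                   spacing = as.double(phantom$spacing),
                   dims = as.integer(phantom$dims),
                   material = as.integer(vox_mat)),
    materials = materials_for_engine(mats),
    config = c(unclass(config), list(air_material = as.integer(geo$air_index))),
    phsp_plane_z = plane_z, record_phsp = record)

  tallies <- c(injected = res$injected,
               deposited_phantom = res$deposited_phantom,
               deposited_upstream = res$deposited_upstream,
               radiative = res$radiative,
               escaped = res$escaped,
               wall_absorbed = res$wall_absorbed,
               n_escaped = res$n_escaped, n_wall = res$n_wall)

  grid <- new_dose_grid(res$energy, res$entries, phantom$origin,
                        phantom$spacing, phantom$dims, tallies,
                        meta = list(n_histories = config$n_histories,
                                    seed = config$seed,
                                    source = source_descriptor(source),
                                    applicator = sprintf("%gcm/%gdeg/gap%gcm",
                                      machine$applicator$diameter,
                                      machine$applicator$bevel, machine$gap_cm)))
  if (record) {
    ps <- res$phsp
    attr(grid, "phase_space") <- phase_space_tibble(ps, plane_z)
  }
  grid
}

source_descriptor <- function(source) {
  if (inherits(source, "beam_source")) {
    sprintf("beam E=%g sigma=%g spot=%g div=%g", source$mean_energy,
            source$sigma_e, source$spot_fwhm, source$divergence)
  } else if (inherits(source, "phase_space_replay")) {
    sprintf("phase-space replay (%d records)", nrow(source$records))
  } else "unknown"
}

source_for_engine <- function(source, machine) {
  if (inherits(source, "beam_source")) {
    list(kind = "beam", z = machine$stack$source_z_mm,
         mean_energy = source$mean_energy, sigma_e = source$sigma_e,
         sigma_spot = source$spot_fwhm * FWHM_TO_SIGMA,
         sigma_div = source$divergence * pi / 180)
  } else if (inherits(source, "phase_space_replay")) {
    rec <- source$records
    validate_phase_space(rec)
    list(kind = "phsp", z = source$plane_z,
         records = as.matrix(rec[, c("energy", "x", "y", "u", "v", "w",
                                     "weight")]))
  } else {
    stop("source must be a beam_source or a phase-space replay")
  }
}

#' Per-voxel relative statistical uncertainty
#'
#' Relative sigma modeled as 1/sqrt(entry count); voxels with zero entries
#' are flagged undefined (`NA`), not zero.
#'
#' @param grid A `dose_grid`.
#' @return Array of relative sigmas with the grid's dimensions; `NA` where no
#'   electron entered.
#' @export
voxel_uncertainty <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  out <- array(NA_real_, dim = grid$dims)
  pos <- grid$entries > 0
  out[pos] <- 1 / sqrt(grid$entries[pos])
  out
}

#' Energy bookkeeping of a run
#'
#' @param grid A `dose_grid`.
#' @return One-row tibble with the energy buckets (MeV) and the relative
#'   closure error of the identity injected = deposited + radiative +
#'   escaped + wall-absorbed.
#' @export
energy_balance <- function(grid) {
  t <- grid$tallies
  accounted <- t[["deposited_phantom"]] + t[["deposited_upstream"]] +
    t[["radiative"]] + t[["escaped"]] + t[["wall_absorbed"]]
  tibble::tibble(
    injected = t[["injected"]],
    deposited_phantom = t[["deposited_phantom"]],
    deposited_upstream = t[["deposited_upstream"]],
    radiative = t[["radiative"]],
    escaped = t[["escaped"]],
    wall_absorbed = t[["wall_absorbed"]],
    relative_error = if (t[["injected"]] > 0)
      abs(accounted - t[["injected"]]) / t[["injected"]] else 0
  )
}

#' Grid voxel-center coordinates along one axis
#' @param grid A `dose_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$spacing[axis]
}

#' Convert a dose grid to a long tibble
#'
#' @param x A `dose_grid`.
#' @param ... Unused.
#' @return Tibble with voxel-center coordinates, deposited energy and entry
#'   counts (zero-energy voxels retained).
#' @method as_tibble dose_grid
#' @export
as_tibble.dose_grid <- function(x, ...) {
  tibble::tibble(
    x = rep(grid_axis(x, 1), times = x$dims[2] * x$dims[3]),
    y = rep(rep(grid_axis(x, 2), each = x$dims[1]), times = x$dims[3]),
    z = rep(grid_axis(x, 3), each = x$dims[1] * x$dims[2]),
    energy_mev = as.vector(x$energy),
    entries = as.vector(x$entries)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
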