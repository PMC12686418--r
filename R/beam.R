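#' Parametric electron source
#'
#' A circular source with a 2D Gaussian intensity distribution (equal widths
#' in both transverse directions), a Gaussian energy spectrum truncated at
#' E > 0, and a Gaussian angular spread about the beam (+z) axis.
#'
#' @param mean_energy Mean kinetic energy in MeV (> 0).
#' @param sigma_e Energy-spectrum standard deviation in MeV (>= 0).
#' @param spot_fwhm Spot full width at half maximum in mm (>= 0).
#' @param divergence Half-angle sigma of the Gaussian angular spread, degrees
#'   (>= 0).
#' @return A `beam_source` object.
#' @export
#' @examples
#' beam_source(9.8, 0.9, spot_fwhm = 1.6, divergence = 0)
beam_source <- function(mean_energy, sigma_e = 0, spot_fwhm = 0, divergence = 0) {
  stopifnot(is.numeric(mean_energy), mean_energy > 0, sigma_e >= 0,
            spot_fwhm >= 0, divergence >= 0)
  structure(list(mean_energy = mean_energy, sigma_e = sigma_e,
                 spot_fwhm = spot_fwhm, divergence = divergence),
            class = "beam_source")
}

#' @export
print.beam_source <- function(x, ...) {
  cat(sprintf("<beam_source> E = %.3g +- %.3g MeV, spot FWHM %.3g mm, divergence %.3g deg\n",
              x$mean_energy, x$sigma_e, x$spot_fwhm, x$divergence))
  invisible(x)
}

# FWHM <-> sigma for a Gaussian, fixed convention
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Source presets per nominal operative energy
#'
#' Tuned source spectra for the three operative energies, together with the
#' reference depth of maximum dose used as the output-factor evaluation depth.
#'
#' @return A tibble with columns `nominal_mev`, `mean_energy`, `sigma_e`,
#'   `spot_fwhm`, `divergence`, `zmax_mm`.
#' @export
beam_presets <- function() {
  tibble::tibble(
    nominal_mev = c(6, 9, 12),
    mean_energy = c(7.2, 9.8, 12.35),
    sigma_e     = c(0.7, 0.9, 1.2),
    spot_fwhm   = 1.6,
    divergence  = 0,
    zmax_mm     = c(13, 18, 22)
  )
}

#' Look up the tuned source for a nominal energy
#'
#' @param nominal_mev One of 6, 9, 12.
#' @export
preset_source <- function(nominal_mev) {
  p <- beam_presets()
  row <- p[p$nominal_mev == nominal_mev, ]
  if (nrow(row) != 1) stop("no preset for nominal energy ", nominal_mev, " MeV")
  beam_source(row$mean_energy, row$sigma_e, row$spot_fwhm, row$divergence)
}

#' Reference depth of maximum dose for a nominal energy
#' @param nominal_mev One of 6, 9, 12.
#' @return Depth in mm.
#' @export
reference_zmax <- function(nominal_mev) {
  p <- beam_presets()
  row <- p[p$nominal_mev == nominal_mev, ]
  if (nrow(row) != 1) stop("no reference z_max for nominal energy ", nominal_mev)
  row$zmax_mm
}

#' Sample primary electrons from a source
#'
#' Draws particle states from the source distributions: position from the
#' circular Gaussian spot, energy from the truncated (> 0) Normal spectrum,
#' direction about +z with Gaussian angular spread. Uses R's RNG stream, so
#' wrap in `set.seed()` for reproducibility.
#'
#' @param source A [beam_source()].
#' @param n Number of primaries.
#' @return Tibble with columns `energy`, `x`, `y`, `u`, `v`, `w`, `weight`.
#' @export
sample_primary <- function(source, n) {
  stopifnot(inherits(source, "beam_source"), n >= 0)
  sig_spot <- source$spot_fwhm * FWHM_TO_SIGMA
  sig_div <- source$divergence * pi / 180
  e <- source$mean_energy + source$sigma_e * stats::rnorm(n)
  bad <- which(e <= 0)
  while (length(bad) > 0) {
    e[bad] <- source$mean_energy + source$sigma_e * stats::rnorm(length(bad))
    bad <- bad[e[bad] <= 0]
  }
  tx <- sig_div * stats::rnorm(n)
  ty <- sig_div * stats::rnorm(n)
  nrm <- sqrt(tx^2 + ty^2 + 1)
  tibble::tibble(
    energy = e,
    x = sig_spot * stats::rnorm(n),
    y = sig_spot * stats::rnorm(n),
    u = tx / nrm, v = ty / nrm, w = 1 / nrm,
    weight = 1
  )
}

#' Treatment applicator
#'
#' The applicator is modeled as an absorbing-walled cylinder whose exit plane
#' may be tilted by a bevel angle; the central axis remains the beam axis.
#'
#' @param diameter_cm Inner diameter in cm (> 0).
#' @param bevel_deg Bevel angle, one of 0, 15, 30 degrees.
#' @param length_cm Cylinder length in cm.
#' @param wall_material Material name (walls are perfect absorbers; the name
#'   is descriptive only).
#' @export
applicator <- function(diameter_cm, bevel_deg = 0, length_cm = 30,
                       wall_material = "steel") {
  stopifnot(diameter_cm > 0, length_cm > 0)
  if (!bevel_deg %in% c(0, 15, 30)) {
    stop("bevel must be one of 0, 15, 30 degrees")
  }
  structure(list(diameter = diameter_cm, bevel = bevel_deg,
                 length = length_cm, wall_material = wall_material),
            class = "ioert_applicator")
}

#' @export
print.ioert_applicator <- function(x, ...) {
  cat(sprintf("<applicator> %g cm diameter, %g deg bevel, %g cm long\n",
              x$diameter, x$bevel, x$length))
  invisible(x)
}

#' Machine-head element stack
#'
#' Ordered slab/aperture elements of the accelerator head, upstream of the
#' applicator: exit window, dual scattering foils, primary collimator. The
#' true machine dimensions are proprietary; [default_machine_stack()] is this
#' package's calibrated stand-in whose free thicknesses were tuned once so the
#' broad-beam reference depths of maximum dose (13/18/22 mm at 6/9/12 MeV)
#' are reproduced.
#'
#' @param elements Tibble with columns `material` (name in
#'   [ioert_materials()]), `z_mm` (upstream face position, mm; phantom surface
#'   is z = 0, source is at negative z), `thickness_mm` (> 0), `aperture_mm`
#'   (aperture radius in mm, `NA` for a full slab).
#' @param ssf_density Secondary-scattering-foil density in g/cm^3; the SSF is
#'   the element flagged `ssf = TRUE` in `elements`.
#' @param source_z_mm Source plane position, mm.
#' @export
machine_stack <- function(elements, ssf_density = NULL, source_z_mm = -450) {
  stopifnot(is.data.frame(elements),
            all(c("material", "z_mm", "thickness_mm", "aperture_mm") %in%
                  names(elements)))
  if (!"ssf" %in% names(elements)) elements$ssf <- FALSE
  if (any(elements$thickness_mm <= 0)) stop("element thicknesses must be > 0")
  if (is.unsorted(elements$z_mm, strictly = TRUE)) {
    stop("stack elements must be ordered by strictly increasing z")
  }
  z1 <- elements$z_mm + elements$thickness_mm
  if (any(utils::head(z1, -1) > elements$z_mm[-1] + 1e-9)) {
    stop("stack elements overlap")
  }
  if (!is.null(ssf_density)) {
    stopifnot(ssf_density > 0)
  }
  structure(list(elements = tibble::as_tibble(elements),
                 ssf_density = ssf_density, source_z_mm = source_z_mm),
            class = "machine_stack")
}

#' Default calibrated machine stack
#'
#' Exit window (Ti), primary scattering foil (Ta), secondary scattering foil
#' (Al, density adjustable), and a primary collimator aperture, followed by
#' an air column down to the applicator. Thicknesses are this package's
#' calibration stand-in for the proprietary head geometry: the SSF thickness
#' is energy-specific (the head inserts a different secondary foil per
#' operative energy) and was calibrated once so the broad-beam reference
#' depths of maximum dose come out at 13/18/22 mm for the 6/9/12 MeV
#' spectra.
#'
#' @param nominal_mev Nominal operative energy selecting the calibrated SSF
#'   thickness (6, 9 or 12).
#' @param ssf_density Secondary-foil density override, g/cm^3.
#' @param ssf_thickness_mm Explicit SSF thickness override, mm.
#' @export
default_machine_stack <- function(nominal_mev = 9, ssf_density = 2.699,
                                  ssf_thickness_mm = NULL) {
  calibrated <- c("6" = 2.63, "9" = 4.45, "12" = 6.5)
  if (is.null(ssf_thickness_mm)) {
    key <- as.character(nominal_mev)
    if (!key %in% names(calibrated)) {
      stop("no calibrated SSF thickness for nominal energy ", nominal_mev)
    }
    ssf_thickness_mm <- calibrated[[key]]
  }
  elements <- tibble::tibble(
    material    = c("titanium", "tantalum", "aluminum", "steel_collimator"),
    z_mm        = c(-445, -440, -430, -380),
    thickness_mm = c(0.05, 0.115, ssf_thickness_mm, 10),
    aperture_mm = c(NA, NA, NA, 30),
    ssf         = c(FALSE, FALSE, TRUE, FALSE)
  )
  machine_stack(elements, ssf_density = ssf_density, source_z_mm = -450)
}

#' Assemble machine geometry for the transport engine
#'
#' Combines the head stack, an applicator, and an optional air gap between
#' the applicator end and the phantom surface into the ordered slab/aperture
#' sequence the engine consumes. The applicator is an absorbing cylinder;
#' its exit plane is tilted by the bevel angle (rotation about the y axis),
#' so for a beveled applicator the wall extends further on one side.
#'
#' @param stack A [machine_stack()].
#' @param applicator An [applicator()].
#' @param gap_cm Air gap between applicator end and phantom surface, cm.
#' @return An `ioert_machine` geometry object.
#' @export
build_machine <- function(stack, applicator, gap_cm = 0) {
  stopifnot(inherits(stack, "machine_stack"),
            inherits(applicator, "ioert_applicator"), gap_cm >= 0)
  gap_mm <- gap_cm * 10
  # an air gap means the docked machine sits higher above the skin: the
  # whole head (source included) shifts up with the applicator
  stack$source_z_mm <- stack$source_z_mm - gap_mm
  stack$elements$z_mm <- stack$elements$z_mm - gap_mm
  app_len <- applicator$length * 10
  app_z1 <- -gap_mm
  app_z0 <- app_z1 - app_len
  el <- stack$elements
  if (max(el$z_mm + el$thickness_mm) > app_z0) {
    stop("machine stack overlaps the applicator; shorten the stack or applicator")
  }
  if (stack$source_z_mm >= min(el$z_mm)) {
    stop("source plane must sit upstream of the first stack element")
  }
  structure(list(stack = stack, applicator = applicator, gap_cm = gap_cm,
                 app_z0 = app_z0, app_z1 = app_z1,
                 # default recording plane: beneath the collimation system,
                 # above the applicator
                 phsp_plane_z = (max(el$z_mm + el$thickness_mm) + app_z0) / 2),
            class = "ioert_machine")
}

#' @export
print.ioert_machine <- function(x, ...) {
  cat(sprintf("<ioert_machine> %d head elements, %g cm / %g deg applicator, %g cm air gap\n",
              nrow(x$stack$elements), x$applicator$diameter, x$applicator$bevel,
              x$gap_cm))
  cat(sprintf("  source z = %g mm, applicator [%g, %g] mm, phase-space plane z = %g mm\n",
              x$stack$source_z_mm, x$app_z0, x$app_z1, x$phsp_plane_z))
  invisible(x)
}

#' Total geometric length of a machine assembly
#'
#' Sum of element thicknesses plus the intervening air gaps, from the first
#' stack element to the phantom surface.
#' @param machine An `ioert_machine`.
#' @return Length in mm.
#' @export
machine_length <- function(machine) {
  stopifnot(inherits(machine, "ioert_machine"))
  -min(machine$stack$elements$z_mm)
}

# internal: element table in engine form. Materials list gains the wall/SSF
# entries; returns list(elements = df, materials = list, air_index).
machine_for_engine <- function(machine, mats = ioert_materials()) {
  el <- machine$stack$elements
  ssf_density <- machine$stack$ssf_density
  mat_names <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    m <- el$material[i]
    if (identical(m, "steel_collimator")) next # absorber, transport medium is air
    if (!m %in% names(mats)) stop("unknown stack material: ", m)
    if (isTRUE(el$ssf[i]) && !is.null(ssf_density)) {
      nm <- paste0(m, "_ssf")
      mats[[nm]] <- material_with_density(mats[[m]], ssf_density)
      mat_names[i] <- nm
    } else mat_names[i] <- m
  }
  mat_index <- stats::setNames(seq_along(mats) - 1L, names(mats))
  rows <- list()
  for (i in seq_len(nrow(el))) {
    is_ap <- !is.na(el$aperture_mm[i])
    rows[[i]] <- data.frame(
      type = if (is_ap) 1L else 0L,
      z0 = el$z_mm[i], z1 = el$z_mm[i] + el$thickness_mm[i],
      mat = if (is_ap) mat_index[["air"]] else mat_index[[mat_names[i]]],
      ap_r = if (is_ap) el$aperture_mm[i] else Inf,
      tanb = 0
    )
  }
  rows[[length(rows) + 1]] <- data.frame(
    type = 1L, z0 = machine$app_z0, z1 = machine$app_z1,
    mat = mat_index[["air"]],
    ap_r = machine$applicator$diameter * 10 / 2,
    tanb = tan(machine$applicator$bevel * pi / 180)
  )
  list(elements = do.call(rbind, rows), materials = mats,
       air_index = mat_index[["air"]])
}
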