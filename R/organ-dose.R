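MEV_TO_J <- 1.602176634e-13

#' Score organ doses from an engine run
#'
#' Sums deposited energy over each organ's labeled voxels, converts to mean
#' organ dose D = E/m, and reports dose relative to the left-breast (target)
#' dose. The relative uncertainty combines the organ-level and reference
#' entry counts as 1/sqrt(n) in quadrature; the reference row itself is
#' exactly 100% with its own counting uncertainty.
#'
#' @param phantom The labeled `phantom_spec` the run was scored on.
#' @param grid The `dose_grid` returned by [run_simulation()] on that
#'   phantom.
#' @param reference_organ Name of the reference organ (default
#'   "Left Breast").
#' @return An `organ_dose_table` tibble: `organ`, `energy_mev`, `e_j`,
#'   `mass_g`, `dose_gy`, `relative_pct`, `rel_unc_pct`, `entries`.
#' @export
score_organ_doses <- function(phantom, grid, reference_organ = "Left Breast") {
  stopifnot(!is.null(phantom$labels), inherits(grid, "dose_grid"))
  if (!identical(dim(phantom$labels), as.integer(grid$dims))) {
    stop("grid was not scored on this phantom (dimension mismatch)")
  }
  reg <- phantom$registry
  if (!reference_organ %in% reg$organ) {
    stop("reference organ not in the registry: ", reference_organ)
  }
  nb <- max(reg$id, DISK_LABEL) + 1L
  lab <- as.vector(phantom$labels) + 1L
  e_by <- rowsum(as.vector(grid$energy), lab)
  n_by <- rowsum(as.double(as.vector(grid$entries)), lab)
  e_org <- rep(0, nb); n_org <- rep(0, nb)
  idx <- as.integer(rownames(e_by))
  e_org[idx] <- e_by[, 1]; n_org[idx] <- n_by[, 1]

  energy_mev <- e_org[reg$id + 1L]
  entries <- n_org[reg$id + 1L]
  e_j <- energy_mev * MEV_TO_J
  dose_gy <- e_j / (reg$mass_g / 1000)

  i_ref <- which(reg$organ == reference_organ)
  d_ref <- dose_gy[i_ref]
  if (d_ref <= 0) stop("reference organ received no dose")
  n_ref <- entries[i_ref]
  relative_pct <- 100 * dose_gy / d_ref
  relative_pct[i_ref] <- 100 # exact by definition
  rel_unc_pct <- 100 * sqrt(ifelse(entries > 0, 1 / entries, NA_real_) +
                              1 / n_ref)
  rel_unc_pct[i_ref] <- 100 / sqrt(n_ref)
  rel_unc_pct[entries == 0] <- NA_real_

  out <- tibble::tibble(organ = reg$organ, energy_mev = energy_mev,
                        e_j = e_j, mass_g = reg$mass_g, dose_gy = dose_gy,
                        relative_pct = relative_pct,
                        rel_unc_pct = rel_unc_pct, entries = entries)
  attr(out, "reference_organ") <- reference_organ
  class(out) <- c("organ_dose_table", class(out))
  out
}

#' Absolute organ doses under a prescription
#'
#' Scales relative organ doses by the prescribed target dose:
#' absolute = prescription x relative/100, reported in mGy with the relative
#' uncertainty propagated multiplicatively.
#'
#' @param table An `organ_dose_table` (or any tibble with `organ`,
#'   `relative_pct` and optionally `rel_unc_pct`).
#' @param prescription_gy Prescribed dose to the reference organ, Gy
#'   (default 21, the usual single-fraction prescription at z_max).
#' @return Tibble with `organ`, `relative_pct`, `dose_mgy`, `unc_mgy`.
#' @export
absolute_doses <- function(table, prescription_gy = 21) {
  stopifnot(prescription_gy > 0, all(c("organ", "relative_pct") %in%
                                       names(table)))
  unc <- if ("rel_unc_pct" %in% names(table)) table$rel_unc_pct else NA_real_
  dose_mgy <- prescription_gy * table$relative_pct / 100 * 1000
  tibble::tibble(organ = table$organ, relative_pct = table$relative_pct,
                 dose_mgy = dose_mgy, unc_mgy = dose_mgy * unc / 100)
}

#' Shielding-disk misalignment comparison
#'
#' Runs two identical organ-dose simulations differing only in the shielding
#' disk (present/offset/absent) with paired seeds, and tabulates per-organ
#' relative doses with and without the disk and their differences.
#'
#' @param phantom_disk,phantom_nodisk Labeled phantoms that must be identical
#'   except for disk voxels (checked); e.g. built with
#'   `build_thorax_phantom(disk = shield_disk())` and
#'   `build_thorax_phantom(disk = NULL)`.
#' @param source A [beam_source()].
#' @param machine An [build_machine()] geometry.
#' @param config A [transport_config()]; the same seed is used for both arms.
#' @return List with the two `organ_dose_table`s and `deltas` (tibble:
#'   organ, relative_pct_disk, relative_pct_nodisk, delta_pct,
#'   combined_unc_pct).
#' @export
misalignment_study <- function(phantom_disk, phantom_nodisk, source, machine,
                               config) {
  stopifnot(inherits(config, "transport_config"))
  if (!identical(phantom_disk$dims, phantom_nodisk$dims) ||
      !identical(phantom_disk$spacing, phantom_nodisk$spacing) ||
      !identical(phantom_disk$registry, phantom_nodisk$registry)) {
    stop("phantoms differ in more than the shielding disk")
  }
  differing <- phantom_disk$labels != phantom_nodisk$labels
  # every differing voxel must involve the disk in one of the two arms
  not_disk <- differing & phantom_disk$labels != DISK_LABEL &
    phantom_nodisk$labels != DISK_LABEL
  if (any(not_disk)) {
    stop("phantoms differ in more than the shielding disk")
  }
  g1 <- run_simulation(source, machine, phantom_disk, config)
  g2 <- run_simulation(source, machine, phantom_nodisk, config)
  t1 <- score_organ_doses(phantom_disk, g1)
  t2 <- score_organ_doses(phantom_nodisk, g2)
  deltas <- tibble::tibble(
    organ = t1$organ,
    relative_pct_disk = t1$relative_pct,
    relative_pct_nodisk = t2$relative_pct,
    delta_pct = t2$relative_pct - t1$relative_pct,
    combined_unc_pct = sqrt(
      (t1$relative_pct * t1$rel_unc_pct / 100)^2 +
      (t2$relative_pct * t2$rel_unc_pct / 100)^2)
  )
  list(with_disk = t1, without_disk = t2, deltas = deltas)
}

#' Write an organ dose table as CSV
#' @param table An `organ_dose_table`.
#' @param path Output path.
#' @export
write_organ_table_csv <- function(table, path) {
  df <- data.frame(organ = table$organ,
                   E_J = format_repr(table$e_j),
                   mass_g = format_repr(table$mass_g),
                   dose_mGy = format_repr(table$dose_gy * 1000),
                   relative_pct = format_repr(table$relative_pct),
                   rel_unc_pct = format_repr(table$rel_unc_pct))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_repr <- function(x) sprintf("%.17g", x)
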