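#' 1D dose curve
#'
#' A sampled percentage-depth-dose (PDD) or lateral profile: positions,
#' values, and per-point uncertainties, as a tibble with curve metadata in
#' attributes (`axis`, `normalization`, `energy`, `applicator`).
#'
#' @param position_mm Strictly increasing positions, mm.
#' @param value Dose values (relative or MeV).
#' @param sigma Per-point uncertainties, same units (>= 0).
#' @param axis One of "depth", "inplane", "crossplane".
#' @param normalization Optional list(position, value) recording the
#'   normalization reference.
#' @param energy,applicator Optional descriptors carried as metadata.
#' @export
ioert_curve <- function(position_mm, value, sigma = 0,
                        axis = c("depth", "inplane", "crossplane"),
                        normalization = NULL, energy = NULL,
                        applicator = NULL) {
  axis <- match.arg(axis)
  sigma <- rep(sigma, length.out = length(position_mm))
  stopifnot(length(value) == length(position_mm), all(sigma >= 0))
  if (is.unsorted(position_mm, strictly = TRUE)) {
    stop("curve positions must be strictly increasing")
  }
  out <- tibble::tibble(position_mm = as.double(position_mm),
                        value = as.double(value), sigma = as.double(sigma))
  attr(out, "axis") <- axis
  attr(out, "normalization") <- normalization
  attr(out, "energy") <- energy
  attr(out, "applicator") <- applicator
  class(out) <- c("ioert_curve", class(out))
  out
}

curve_axis <- function(curve) attr(curve, "axis") %||% "depth"

rebuild_curve <- function(template, position_mm, value, sigma,
                          normalization = attr(template, "normalization")) {
  ioert_curve(position_mm, value, sigma, axis = curve_axis(template),
              normalization = normalization,
              energy = attr(template, "energy"),
              applicator = attr(template, "applicator"))
}

#' Detector scoring volume
#'
#' Rectangular scoring footprint in mm. Two presets match the commissioning
#' detectors emulated here: [scoring_pdd()] — a 1 x 6 x 6 mm^3 = 36 mm^3
#' parallel-plate-chamber-like volume (1 mm along depth) — and
#' [scoring_profile()] — a 1 x 3 x 6 mm^3 = 18 mm^3 diode-like volume with
#' the 1 mm axis along the scan direction.
#'
#' @param scan_mm Extent along the scanned axis.
#' @param lateral_mm Extent along the other lateral axis.
#' @param depth_mm Extent along depth (profiles) or the averaging depth
#'   window (PDD uses `scan_mm` along depth).
#' @export
scoring_volume <- function(scan_mm, lateral_mm, depth_mm) {
  stopifnot(scan_mm > 0, lateral_mm > 0, depth_mm > 0)
  structure(list(scan = scan_mm, lateral = lateral_mm, depth = depth_mm),
            class = "scoring_volume")
}

#' @rdname scoring_volume
#' @export
scoring_pdd <- function() scoring_volume(1, 6, 6)

#' @rdname scoring_volume
#' @export
scoring_profile <- function() scoring_volume(1, 3, 6)

# centered index window of width `extent_mm` around coordinate `center`
# on axis `axis` of the grid; half-open ([lo, hi)) like the voxel grid
# itself, so the footprint always covers exactly `extent_mm` of voxels;
# errors if it falls outside the grid
axis_window <- function(grid, axis, center, extent_mm) {
  ax <- grid_axis(grid, axis)
  half <- extent_mm / 2
  idx <- which(ax >= center - half - 1e-9 & ax < center + half - 1e-9)
  if (length(idx) == 0 ||
      center - half < grid$origin[axis] - 1e-9 ||
      center + half > grid$origin[axis] +
        grid$dims[axis] * grid$spacing[axis] + 1e-9) {
    stop("scoring footprint exceeds the dose grid")
  }
  idx
}

#' Extract the central-axis depth-dose curve
#'
#' At each depth voxel layer, the value is the mean deposited energy over the
#' centered x-y scoring footprint (detector-volume averaging); the relative
#' uncertainty combines the entry counts of the covered voxels as
#' 1/sqrt(total entries).
#'
#' @param grid A `dose_grid`.
#' @param scoring A [scoring_volume()]; default the 36 mm^3 chamber-like
#'   volume with 1 mm depth resolution.
#' @return An `ioert_curve` with axis "depth" (unnormalized, MeV units).
#' @export
extract_pdd <- function(grid, scoring = scoring_pdd()) {
  stopifnot(inherits(grid, "dose_grid"))
  ix <- axis_window(grid, 1, 0, scoring$lateral)
  iy <- axis_window(grid, 2, 0, scoring$depth)
  zax <- grid_axis(grid, 3)
  nzwin <- max(1L, as.integer(round(scoring$scan / grid$spacing[3])))
  vals <- numeric(grid$dims[3]); sig <- numeric(grid$dims[3])
  for (iz in seq_len(grid$dims[3])) {
    izwin <- iz:min(grid$dims[3], iz + nzwin - 1L)
    block_e <- grid$energy[ix, iy, izwin, drop = FALSE]
    block_n <- grid$entries[ix, iy, izwin, drop = FALSE]
    vals[iz] <- mean(block_e)
    n <- sum(block_n)
    sig[iz] <- if (n > 0) vals[iz] / sqrt(n) else NA_real_
  }
  ioert_curve(zax, vals, ifelse(is.na(sig), 0, sig), axis = "depth")
}

#' Extract a lateral profile at a depth
#'
#' The scanned direction gets the short (1 mm) scoring axis; the remaining
#' lateral axis and depth are averaged over the detector extents.
#'
#' @param grid A `dose_grid`.
#' @param depth_mm Depth of the scan plane, mm; must lie inside the grid.
#' @param axis "inplane" (x) or "crossplane" (y).
#' @param scoring A [scoring_volume()]; default the 18 mm^3 diode-like volume.
#' @return An `ioert_curve` on the requested axis.
#' @export
extract_profile <- function(grid, depth_mm, axis = c("inplane", "crossplane"),
                            scoring = scoring_profile()) {
  stopifnot(inherits(grid, "dose_grid"))
  axis <- match.arg(axis)
  zext <- grid$origin[3] + c(0, grid$dims[3] * grid$spacing[3])
  if (depth_mm < zext[1] || depth_mm > zext[2]) {
    stop("depth outside the dose grid")
  }
  iz <- axis_window(grid, 3, depth_mm, scoring$depth)
  scan_ax <- if (axis == "inplane") 1L else 2L
  other_ax <- if (axis == "inplane") 2L else 1L
  iother <- axis_window(grid, other_ax, 0, scoring$lateral)
  pos <- grid_axis(grid, scan_ax)
  nswin <- max(1L, as.integer(round(scoring$scan / grid$spacing[scan_ax])))
  n_scan <- grid$dims[scan_ax]
  vals <- numeric(n_scan); sig <- numeric(n_scan)
  for (i in seq_len(n_scan)) {
    iwin <- i:min(n_scan, i + nswin - 1L)
    if (scan_ax == 1L) {
      be <- grid$energy[iwin, iother, iz, drop = FALSE]
      bn <- grid$entries[iwin, iother, iz, drop = FALSE]
    } else {
      be <- grid$energy[iother, iwin, iz, drop = FALSE]
      bn <- grid$entries[iother, iwin, iz, drop = FALSE]
    }
    vals[i] <- mean(be)
    n <- sum(bn)
    sig[i] <- if (n > 0) vals[i] / sqrt(n) else 0
  }
  ioert_curve(pos, vals, sig, axis = axis)
}

#' Depth of maximum dose
#'
#' Position of the curve maximum; ties break toward the smallest position.
#' Optional 3-point moving-average smoothing passes suppress voxel noise
#' before the argmax; an optional local quadratic-vertex refinement
#' (`fit_window_mm`) fits a parabola around the smoothed argmax and returns
#' its vertex, the estimator of choice for noisy Monte Carlo depth-dose
#' curves whose peak region is flat.
#'
#' @param pdd An `ioert_curve` (typically axis "depth").
#' @param smoothing_passes Number of 3-point smoothing passes (default 0).
#' @param fit_window_mm Half-width of the quadratic refinement window, mm;
#'   `NULL` (default) disables refinement and returns the argmax position.
#' @return Depth in mm.
#' @export
find_zmax <- function(pdd, smoothing_passes = 0, fit_window_mm = NULL) {
  stopifnot(inherits(pdd, "ioert_curve"), nrow(pdd) > 0)
  if (all(pdd$value == 0)) stop("all-zero curve has no maximum")
  v <- pdd$value
  for (k in seq_len(smoothing_passes)) v <- smooth3(v)
  i <- which.max(v) # which.max takes the first (smallest-position) maximum
  z0 <- pdd$position_mm[i]
  if (is.null(fit_window_mm)) return(z0)
  # iterated local parabola: fit around the current estimate, move to the
  # vertex, re-center; stabilizes the estimate when the peak plateau is
  # flat relative to the point noise
  zc <- z0
  for (it in 1:3) {
    sel <- which(abs(pdd$position_mm - zc) <= fit_window_mm)
    if (length(sel) < 5) return(zc)
    d <- pdd$position_mm[sel] - zc
    a <- stats::coef(stats::lm(pdd$value[sel] ~ d + I(d^2)))
    if (!is.finite(a[3]) || a[3] >= 0) return(zc)
    vertex <- zc - a[2] / (2 * a[3])
    vertex <- min(max(vertex, zc - fit_window_mm), zc + fit_window_mm)
    if (abs(vertex - zc) < 0.05) return(vertex)
    zc <- vertex
  }
  zc
}

smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

#' Normalize a curve
#'
#' Scales values (and sigmas) so the reference value is 100. By default the
#' reference is the curve maximum, so a normalized PDD has maximum exactly
#' 100.
#'
#' @param curve An `ioert_curve`.
#' @param at_position Position at which to take the reference value (linear
#'   interpolation); `NULL` (default) uses the maximum.
#' @export
normalize_curve <- function(curve, at_position = NULL) {
  stopifnot(inherits(curve, "ioert_curve"))
  ref <- if (is.null(at_position)) {
    max(curve$value)
  } else {
    stats::approx(curve$position_mm, curve$value, xout = at_position)$y
  }
  if (!is.finite(ref) || ref == 0) stop("cannot normalize: zero/undefined reference")
  rebuild_curve(curve, curve$position_mm, curve$value / ref * 100,
                curve$sigma / ref * 100,
                normalization = list(position = at_position, value = ref))
}

#' Resample a curve to the commissioning measurement scheme
#'
#' Emulates the sampling of the measured reference curves: profiles are
#' sampled at 1 mm steps outside the central flat region and 4 mm inside it,
#' then linearly interpolated back to 2 mm in that region; depth-dose curves
#' are sampled at 1 mm through the build-up and 2 mm beyond it. The central
#' flat region is defined as |x| <= 0.35 x field diameter.
#'
#' @param curve An `ioert_curve` sampled at <= 1 mm pitch.
#' @param field_diameter_mm Field diameter for the central-region boundary
#'   (profiles).
#' @param zmax_mm End of the build-up region (depth curves); default: argmax.
#' @return The resampled `ioert_curve`.
#' @export
resample_to_measurement <- function(curve, field_diameter_mm = 100,
                                    zmax_mm = NULL) {
  stopifnot(inherits(curve, "ioert_curve"))
  p <- curve$position_mm
  interp <- function(x) stats::approx(p, curve$value, xout = x)$y
  interp_s <- function(x) stats::approx(p, curve$sigma, xout = x)$y
  if (curve_axis(curve) == "depth") {
    if (is.null(zmax_mm)) zmax_mm <- find_zmax(curve)
    grid <- measurement_grid_depth(min(p), max(p), zmax_mm)
    return(rebuild_curve(curve, grid, interp(grid), interp_s(grid)))
  }
  g <- measurement_grid_profile(min(p), max(p), field_diameter_mm)
  coarse_vals <- interp(g$sample)
  vals <- stats::approx(g$sample, coarse_vals, xout = g$out)$y
  rebuild_curve(curve, g$out, vals, interp_s(g$out))
}

# the documented sampling grids, constructed independently of any curve
measurement_grid_depth <- function(zmin, zmax_curve, zmax_buildup) {
  fine <- seq(ceiling(zmin), floor(min(zmax_buildup, zmax_curve)), by = 1)
  coarse <- seq(floor(min(zmax_buildup, zmax_curve)) + 2, floor(zmax_curve),
                by = 2)
  sort(unique(c(fine, coarse)))
}

measurement_grid_profile <- function(xmin, xmax, field_diameter_mm) {
  half_flat <- 0.35 * field_diameter_mm
  left <- seq(ceiling(xmin), -ceiling(half_flat), by = 1)
  right <- seq(ceiling(half_flat), floor(xmax), by = 1)
  central4 <- seq(-ceiling(half_flat), ceiling(half_flat), by = 4)
  sample_grid <- sort(unique(c(left, central4, right)))
  central2 <- seq(-ceiling(half_flat), ceiling(half_flat), by = 2)
  out_grid <- sort(unique(c(left, central2, right)))
  list(sample = sample_grid, out = out_grid,
       central = function(x) abs(x) <= half_flat)
}

#' Output factor from a pair of dose grids
#'
#' OF = D_nonref(z_max) / D_ref(z_max), with both doses read on the central
#' axis at the energy's reference z_max. By default the reading averages the
#' 36 mm^3 chamber-like volume (stabler ratio); `mode = "voxel"` reads the
#' single central-axis voxel. Uncertainty propagates the entry-count relative
#' sigmas of numerator and denominator in quadrature.
#'
#' @param ref_grid Dose grid of the reference (10 cm, 0 deg) applicator.
#' @param nonref_grid Dose grid of the non-reference configuration.
#' @param zmax_mm Reference depth of maximum dose, mm (frozen per nominal
#'   energy: see [reference_zmax()]).
#' @param scoring Scoring volume for `mode = "volume"`.
#' @param mode "volume" (default) or "voxel".
#' @param applicator,energy Optional descriptors for the result.
#' @return An `ioert_of` object (value, uncertainty, descriptors).
#' @export
compute_of <- function(ref_grid, nonref_grid, zmax_mm,
                       scoring = scoring_pdd(), mode = c("volume", "voxel"),
                       applicator = NULL, energy = NULL) {
  mode <- match.arg(mode)
  ref <- central_axis_dose(ref_grid, zmax_mm, scoring, mode)
  nonref <- central_axis_dose(nonref_grid, zmax_mm, scoring, mode)
  if (ref$value == 0) stop("zero reference dose at z_max")
  value <- nonref$value / ref$value
  unc <- value * sqrt(ref$rel_sigma^2 + nonref$rel_sigma^2)
  structure(list(value = value, uncertainty = unc, zmax_mm = zmax_mm,
                 mode = mode, applicator = applicator, energy = energy),
            class = "ioert_of")
}

central_axis_dose <- function(grid, zmax_mm, scoring, mode) {
  stopifnot(inherits(grid, "dose_grid"))
  if (mode == "voxel") {
    ix <- axis_window(grid, 1, 0, grid$spacing[1])
    iy <- axis_window(grid, 2, 0, grid$spacing[2])
    iz <- axis_window(grid, 3, zmax_mm, grid$spacing[3])
  } else {
    ix <- axis_window(grid, 1, 0, scoring$lateral)
    iy <- axis_window(grid, 2, 0, scoring$depth)
    iz <- axis_window(grid, 3, zmax_mm, scoring$scan)
  }
  e <- grid$energy[ix, iy, iz, drop = FALSE]
  n <- sum(grid$entries[ix, iy, iz])
  list(value = mean(e), rel_sigma = if (n > 0) 1 / sqrt(n) else NA_real_)
}

#' @export
print.ioert_of <- function(x, ...) {
  cat(sprintf("<output factor> %.4f +- %.4f (z_max %g mm, %s readout)\n",
              x$value, x$uncertainty, x$zmax_mm, x$mode))
  invisible(x)
}

#' Full width at half maximum of a profile
#'
#' Linear-interpolated width at half of the maximum value; used e.g. to check
#' field size against the applicator diameter.
#' @param curve An `ioert_curve`.
#' @return Width in mm.
#' @export
curve_fwhm <- function(curve) {
  v <- curve$value; p <- curve$position_mm
  half <- max(v) / 2
  above <- which(v >= half)
  if (length(above) == 0) return(0)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 > 1) {
    stats::approx(v[c(i1 - 1, i1)], p[c(i1 - 1, i1)], xout = half)$y
  } else p[i1]
  right <- if (i2 < length(v)) {
    stats::approx(v[c(i2 + 1, i2)], p[c(i2 + 1, i2)], xout = half)$y
  } else p[i2]
  right - left
}
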