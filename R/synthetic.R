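#' Generate a synthetic commissioning reference set
#'
#' Stands in for measured commissioning curves: runs the engine at the truth
#' source parameters, applies detector-volume scoring (36 mm^3 PDD, 18 mm^3
#' profiles), resamples to the measurement sampling scheme, normalizes, and
#' adds independent per-point Gaussian noise. The default noise level, 2.1%,
#' matches the typical experimental uncertainty of such measurements. A
#' machine-readable provenance record (truth parameters, noise, seed) is
#' attached; regeneration from identical provenance is bit-identical.
#'
#' @param truth A [beam_source()] — the "true" parameters the reference
#'   embodies.
#' @param machine An [build_machine()] geometry (reference applicator).
#' @param phantom Phantom spec for the engine run.
#' @param n_histories History budget for the underlying run.
#' @param noise_pct Per-point Gaussian noise, % of the normalized value
#'   scale (>= 0).
#' @param seed Seed for both the engine run and the noise stream.
#' @param zmax_mm Profile depth; default: the depth of the PDD maximum of
#'   the noiseless run.
#' @param smoothing_passes 3-point smoothing passes applied before
#'   resampling (see [make_curve_simulator()]); keep consistent with the
#'   simulator used for tuning. Default 0.
#' @return A `reference_set`: named list of curves (`pdd`, `inplane`,
#'   `crossplane`) with `provenance` attribute.
#' @export
generate_reference_set <- function(truth, machine, phantom, n_histories,
                                   noise_pct = 2.1, seed = 1,
                                   zmax_mm = NULL, smoothing_passes = 0,
                                   pdd_scoring = scoring_pdd(),
                                   profile_scoring = scoring_profile()) {
  stopifnot(inherits(truth, "beam_source"))
  if (noise_pct < 0) stop("noise_pct must be >= 0")
  grid <- run_simulation(truth, machine, phantom,
                         transport_config(n_histories, seed = seed))
  if (is.null(zmax_mm)) {
    zmax_mm <- find_zmax(extract_pdd(grid), smoothing_passes = 2)
  }
  curves <- simulated_curve_set(grid, zmax_mm,
                                machine$applicator$diameter * 10,
                                smoothing_passes = smoothing_passes,
                                pdd_scoring = pdd_scoring,
                                profile_scoring = profile_scoring)
  noisy <- withr::with_seed(seed + 1L, {
    purrr::map(curves, function(cv) {
      # additive Gaussian noise in % of the normalization scale (value 100)
      rebuild_curve(cv, cv$position_mm,
                    cv$value + noise_pct * stats::rnorm(nrow(cv)),
                    sqrt(cv$sigma^2 + noise_pct^2))
    })
  })
  structure(noisy, class = "reference_set",
            provenance = list(
              truth = unclass(truth), noise_pct = noise_pct, seed = seed,
              n_histories = n_histories, zmax_mm = zmax_mm,
              smoothing_passes = smoothing_passes,
              applicator = unclass(machine$applicator),
              gap_cm = machine$gap_cm))
}

#' @export
print.reference_set <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<reference_set> %s (truth E = %g MeV, noise %g%%, seed %d)\n",
              paste(names(x), collapse = " + "), pv$truth$mean_energy,
              pv$noise_pct, pv$seed))
  invisible(x)
}

#' Parametric depth-dose fixture
#'
#' Engine-free closed-form PDD for unit tests: a smooth quadratic build-up
#' peaking at exactly 100 at `zmax_mm`, joined to a logistic fall-off that
#' crosses 50 at `r50_mm` and decreases monotonically beyond the peak. Only
#' the constraints (peak position/value, half-value depth, monotone tail)
#' are contractual; the functional form is internal.
#'
#' @param zmax_mm Depth of maximum, mm (0 < zmax < r50).
#' @param r50_mm Half-value depth, mm.
#' @param surface_ratio Entrance dose as a fraction of the maximum, in
#'   (0, 1).
#' @param grid Depth sampling positions, mm.
#' @return An `ioert_curve` (axis "depth").
#' @export
generate_parametric_pdd <- function(zmax_mm, r50_mm, surface_ratio = 0.85,
                                    grid = seq(0, 2.5 * r50_mm, by = 1)) {
  if (!(zmax_mm > 0 && zmax_mm < r50_mm)) {
    stop("need 0 < zmax_mm < r50_mm")
  }
  if (!(surface_ratio > 0 && surface_ratio < 1)) {
    stop("surface_ratio must be in (0, 1)")
  }
  # fall-off: half-Gaussian through (zmax, 100) and (r50, 50) exactly,
  # flat-tangent at the peak so it joins the build-up smoothly
  fall <- function(z) 100 * exp(-log(2) * ((z - zmax_mm) / (r50_mm - zmax_mm))^2)
  val <- ifelse(grid <= zmax_mm,
                100 * (surface_ratio + (1 - surface_ratio) *
                         (1 - ((grid - zmax_mm) / zmax_mm)^2)),
                fall(grid))
  ioert_curve(grid, val, axis = "depth",
              normalization = list(position = zmax_mm, value = 100))
}

#' Film-like fluence image
#'
#' 2D fluence map emulating a radiochromic-film exposure without applicator:
#' either recorded from an engine phase-space run or (default) a parametric
#' circular Gaussian, with optional pixel noise. Row/column integrals serve
#' as profile extractions.
#'
#' @param fwhm_mm Beam FWHM at the film plane.
#' @param mm_per_px Pixel pitch.
#' @param size_mm Image side length.
#' @param noise Additive Gaussian pixel noise as a fraction of the central
#'   intensity.
#' @param seed RNG seed for the noise.
#' @param depth_mm Acquisition depth tag carried as metadata (the 9 MeV
#'   no-applicator film sits at z_max = 18 mm).
#' @return An `ioert_film`: matrix with attributes `mm_per_px`, `depth_mm`.
#' @export
generate_film_image <- function(fwhm_mm = 1.6, mm_per_px = 0.2, size_mm = 20,
                                noise = 0, seed = 1, depth_mm = 18) {
  stopifnot(mm_per_px > 0, size_mm > 0, noise >= 0)
  n <- as.integer(round(size_mm / mm_per_px))
  ax <- (seq_len(n) - (n + 1) / 2) * mm_per_px
  sig <- fwhm_mm * FWHM_TO_SIGMA
  img <- exp(-outer(ax^2, ax^2, "+") / (2 * sig^2))
  if (noise > 0) {
    img <- img + withr::with_seed(seed, noise * stats::rnorm(length(img)))
  }
  structure(img, class = "ioert_film", mm_per_px = mm_per_px,
            depth_mm = depth_mm, axis_mm = ax)
}

#' Profile through a film image
#' @param film An `ioert_film`.
#' @param direction "row" (central row) or "col".
#' @return An `ioert_curve` (axis "inplane").
#' @export
film_profile <- function(film, direction = c("row", "col")) {
  direction <- match.arg(direction)
  n <- nrow(film)
  ic <- as.integer(ceiling(n / 2))
  v <- if (direction == "row") unclass(film)[ic, ] else unclass(film)[, ic]
  ioert_curve(attr(film, "axis_mm"), as.double(v), axis = "inplane")
}
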