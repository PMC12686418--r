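#' Gamma-index acceptance criteria
#'
#' Global dose-difference / distance-to-agreement criteria. Defaults are the
#' clinical 3% / 3 mm with global normalization to the maximum of the
#' reference curve and no low-dose threshold.
#'
#' @param dose_pct Dose-difference tolerance, % of the global normalization
#'   (> 0).
#' @param dta_mm Distance-to-agreement tolerance, mm (> 0).
#' @param low_dose_threshold_pct Reference points below this % of the global
#'   normalization are excluded; `NULL` (default) applies no threshold.
#' @param search_factor Search window half-width as a multiple of `dta_mm`.
#' @param interp_step_mm Interpolation step for the evaluated curve, mm.
#' @export
gamma_criteria <- function(dose_pct = 3, dta_mm = 3,
                           low_dose_threshold_pct = NULL,
                           search_factor = 3, interp_step_mm = 0.1) {
  stopifnot(dose_pct > 0, dta_mm > 0, search_factor > 0, interp_step_mm > 0)
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 search_factor = search_factor,
                 interp_step_mm = interp_step_mm),
            class = "gamma_criteria")
}

#' Gamma-index comparison of two curves
#'
#' For each reference point, gamma is the minimum over the densely
#' interpolated evaluated curve of
#' sqrt(dr^2 / dta^2 + dD^2 / (dose_pct * D_norm)^2), where D_norm is the
#' global maximum of the reference curve. The evaluated curve is linearly
#' interpolated at `interp_step_mm` inside a +-`search_factor * dta_mm`
#' window around each reference position. A point passes when gamma <= 1
#' (the boundary counts as passing).
#'
#' By convention the measured curve is the reference (expected) distribution
#' and the simulated curve the evaluated (tested) one.
#'
#' @param reference,evaluated `ioert_curve`s (or tibbles with `position_mm`,
#'   `value`), consistently normalized.
#' @param criteria A [gamma_criteria()].
#' @return An `ioert_gamma` object: per-point tibble (`position_mm`, `gamma`,
#'   `pass`) plus `pass_rate` (%).
#' @export
gamma_curve <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  if (nrow(reference) == 0 || nrow(evaluated) == 0) {
    stop("gamma comparison requires non-empty curves")
  }
  rp <- reference$position_mm; rv <- reference$value
  ep <- evaluated$position_mm; ev <- evaluated$value
  if (max(ep) < min(rp) || min(ep) > max(rp)) {
    stop("reference and evaluated curves cover disjoint position ranges")
  }
  d_norm <- max(rv)
  if (d_norm <= 0) stop("reference curve has non-positive global maximum")
  dd_tol <- criteria$dose_pct / 100 * d_norm
  dta <- criteria$dta_mm
  win <- criteria$search_factor * dta

  keep <- rep(TRUE, length(rp))
  if (!is.null(criteria$low_dose_threshold_pct)) {
    keep <- rv >= criteria$low_dose_threshold_pct / 100 * d_norm
  }

  gam <- vapply(seq_along(rp), function(i) {
    if (!keep[i]) return(NA_real_)
    xs <- seq(max(min(ep), rp[i] - win), min(max(ep), rp[i] + win),
              by = criteria$interp_step_mm)
    if (length(xs) == 0) xs <- rp[i]
    ys <- stats::approx(ep, ev, xout = xs, rule = 2)$y
    min(sqrt((xs - rp[i])^2 / dta^2 + (ys - rv[i])^2 / dd_tol^2))
  }, numeric(1))

  data <- tibble::tibble(position_mm = rp, reference = rv, gamma = gam,
                         pass = !is.na(gam) & gam <= 1 + 1e-12)
  eval_n <- sum(!is.na(gam))
  pass_rate <- if (eval_n > 0) 100 * sum(data$pass) / eval_n else NA_real_
  structure(list(data = data, pass_rate = pass_rate, n_points = eval_n,
                 criteria = criteria, d_norm = d_norm),
            class = "ioert_gamma")
}

#' @export
print.ioert_gamma <- function(x, ...) {
  cat(sprintf("<gamma analysis> %.1f%% of %d points pass (%g%%/%g mm, global)\n",
              x$pass_rate, x$n_points, x$criteria$dose_pct, x$criteria$dta_mm))
  invisible(x)
}

#' Gamma verdict over a matched set of curves
#'
#' Compares matched reference/evaluated curve sets (typically PDD, inplane
#' and crossplane) and reports each pass rate together with a combined
#' verdict against a threshold: 90% is the per-stage tuning gate, 95% the
#' final validation gate.
#'
#' @param ref_set,eval_set Named lists of curves of equal length and names.
#' @param criteria A [gamma_criteria()].
#' @param threshold_pct Pass-rate threshold in (0, 100].
#' @return List with `results` (tibble: curve, pass_rate, n_points, pass)
#'   and `verdict` (all curves at or above threshold).
#' @export
evaluate_configuration <- function(ref_set, eval_set,
                                   criteria = gamma_criteria(),
                                   threshold_pct = 95) {
  if (length(ref_set) != length(eval_set)) {
    stop("reference and evaluated sets differ in size")
  }
  nm <- names(ref_set) %||% as.character(seq_along(ref_set))
  res <- purrr::map2(ref_set, eval_set, gamma_curve, criteria = criteria)
  results <- tibble::tibble(
    curve = unname(nm),
    pass_rate = unname(purrr::map_dbl(res, "pass_rate")),
    n_points = unname(purrr::map_int(res, ~ as.integer(.x$n_points))),
    pass = unname(purrr::map_lgl(res, ~ .x$pass_rate >= threshold_pct))
  )
  list(results = results, verdict = all(results$pass),
       threshold_pct = threshold_pct, gammas = res)
}
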