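#' Tidy a gamma result
#'
#' One row per reference point: position, reference dose, gamma value, pass
#' flag.
#' @param x An `ioert_gamma`.
#' @param ... Unused.
#' @method tidy ioert_gamma
#' @export
tidy.ioert_gamma <- function(x, ...) x$data

#' One-row gamma summary
#' @param x An `ioert_gamma`.
#' @param ... Unused.
#' @method glance ioert_gamma
#' @export
glance.ioert_gamma <- function(x, ...) {
  tibble::tibble(pass_rate = x$pass_rate, n_points = x$n_points,
                 dose_pct = x$criteria$dose_pct, dta_mm = x$criteria$dta_mm,
                 d_norm = x$d_norm)
}

#' Tidy a tuning result: the complete evaluation log
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @method tidy tuning_result
#' @export
tidy.tuning_result <- function(x, ...) x$log

#' One-row tuning summary
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @method glance tuning_result
#' @export
glance.tuning_result <- function(x, ...) {
  tibble::tibble(mean_energy = x$source$mean_energy,
                 sigma_e = x$source$sigma_e,
                 spot_fwhm = x$source$spot_fwhm,
                 divergence = x$source$divergence,
                 pass_pdd = x$pass_rates$pdd,
                 pass_inplane = x$pass_rates$inplane,
                 pass_crossplane = x$pass_rates$crossplane,
                 converged = x$converged, iterations = x$iterations,
                 n_evaluations = nrow(x$log))
}

#' One-row output-factor summary
#' @param x An `ioert_of`.
#' @param ... Unused.
#' @method glance ioert_of
#' @export
glance.ioert_of <- function(x, ...) {
  tibble::tibble(of = x$value, uncertainty = x$uncertainty,
                 zmax_mm = x$zmax_mm, mode = x$mode,
                 applicator = x$applicator %||% NA_character_,
                 energy = x$energy %||% NA_real_)
}

#' @rdname glance.ioert_of
#' @method tidy ioert_of
#' @export
tidy.ioert_of <- function(x, ...) glance.ioert_of(x)
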