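#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a worm-like-chain segment fit
#'
#' @param x A `wlc_segment_fit` from [fit_wlc_segments()].
#' @param ... Unused.
#' @return A tibble with one row per segment (`segment`, `contour_nm`,
#'   `offset_nm`, `delta_L_nm`, `n_samples`).
#' @export
tidy.wlc_segment_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c("segment", "contour_nm", "offset_nm",
                                    "delta_L_nm", "n_samples")]
}

#' One-row summary of a worm-like-chain segment fit
#'
#' @param x A `wlc_segment_fit`.
#' @param ... Unused.
#' @return A tibble with `n_segments`, `mean_delta_L_nm`,
#'   `sd_delta_L_nm`, `n_increments`.
#' @export
glance.wlc_segment_fit <- function(x, ...) {
  dl <- x$delta_L_nm[!is.na(x$delta_L_nm)]
  tibble::tibble(
    n_segments = nrow(x),
    mean_delta_L_nm = if (length(dl)) mean(dl) else NA_real_,
    sd_delta_L_nm = if (length(dl) > 1) stats::sd(dl) else NA_real_,
    n_increments = length(dl)
  )
}

#' Tidy a Gaussian peak set
#'
#' @param x A `peak_set` from [fit_peak_spacing()].
#' @param ... Unused.
#' @return The peak component tibble (`mean_nm`, `sd_nm`, `weight`).
#' @export
tidy.peak_set <- function(x, ...) x$peaks

#' One-row summary of a Gaussian peak set
#'
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return A tibble with `n_peaks` and `spacing_nm`.
#' @export
glance.peak_set <- function(x, ...) {
  tibble::tibble(n_peaks = x$n_peaks, spacing_nm = x$spacing_nm)
}

#' Tidy a detected event table
#'
#' @param x An `unfolding_events` tibble.
#' @param ... Unused.
#' @return A plain tibble of events.
#' @export
tidy.unfolding_events <- function(x, ...) tibble::as_tibble(unclass(x))
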