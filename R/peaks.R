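#' Gaussian peak-spacing analysis of a contour-length series
#'
#' Histograms the contour-length series, initialises one Gaussian
#' component per local histogram maximum above a prominence threshold
#' (mirroring visual peak counting on a contour-length histogram), fits
#' the sum of Gaussians by nonlinear least squares, and reports the mean
#' peak-to-peak spacing of the fitted component means.
#'
#' @param series A `contour_length_series` from
#'   [contour_length_transform()], or any numeric vector of contour
#'   lengths (nm).
#' @param n_peaks Optional hint: keep only the `n_peaks` most prominent
#'   local maxima as starting components.
#' @param bin_width Histogram bin width, nm.
#' @param prominence Minimum height of a local maximum, as a fraction of
#'   the tallest bin.
#' @return A list of class `peak_set` with `peaks` (tibble: `mean_nm`,
#'   `sd_nm`, `weight`, means strictly increasing), `spacing_nm` (mean of
#'   successive mean differences; `NA` when fewer than two peaks
#'   resolve), `n_peaks`, and the fitted histogram (`histogram` tibble
#'   with `mid`, `count`, `fitted`).
#' @examples
#' x <- c(rnorm(300, 40, 1), rnorm(300, 46, 1), rnorm(300, 52, 1))
#' fit_peak_spacing(x)
#' @export
fit_peak_spacing <- function(series, n_peaks = NULL, bin_width = 0.75,
                             prominence = 0.1) {
  x <- if (is.data.frame(series)) series$contour_nm else as.numeric(series)
  x <- x[is.finite(x)]
  if (!length(x)) stop("`series` is empty")
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  sm <- if (length(counts) >= 5) stats::filter(counts, rep(1 / 3, 3), sides = 2) else counts
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  n_b <- length(sm)
  is_max <- vapply(seq_len(n_b), function(i) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < n_b) sm[i + 1] else -Inf
    sm[i] >= l && sm[i] > r && sm[i] >= prominence * max(sm)
  }, logical(1))
  cand <- which(is_max)
  # merge maxima closer than 2 bins (flat tops)
  if (length(cand) > 1) {
    grp <- cumsum(c(1, diff(cand) > 2))
    cand <- vapply(split(cand, grp), function(ii) ii[which.max(sm[ii])], numeric(1))
  }
  if (!is.null(n_peaks) && length(cand) > n_peaks) {
    cand <- sort(cand[order(sm[cand], decreasing = TRUE)][seq_len(n_peaks)])
  }
  k <- length(cand)
  if (k == 0) stop("no histogram maxima found")
  mu0 <- mids[cand]
  a0 <- counts[cand]
  s0 <- rep(max(bin_width, min(diff(sort(mu0)), 3) / 4, na.rm = TRUE), k)
  if (k == 1) s0 <- stats::sd(x)

  gauss_sum <- function(par, m) {
    a <- par[seq_len(k)]
    mu <- par[k + seq_len(k)]
    s <- par[2 * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(j) a[j] * exp(-(m - mu[j])^2 / (2 * s[j]^2)),
                   numeric(length(m))))
  }
  par0 <- c(a0, mu0, pmax(s0, 0.25))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      fn = function(p) counts - gauss_sum(abs_par(p, k), mids),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  par <- if (is.null(fit)) par0 else abs_par(fit$par, k)
  a <- par[seq_len(k)]; mu <- par[k + seq_len(k)]; s <- par[2 * k + seq_len(k)]
  ord <- order(mu)
  peaks <- tibble::tibble(mean_nm = mu[ord], sd_nm = abs(s[ord]),
                          weight = pmax(a[ord], 0) * abs(s[ord]))
  # drop components that collapsed onto each other (< half bin apart)
  if (nrow(peaks) > 1) {
    keep <- c(TRUE, diff(peaks$mean_nm) > bin_width / 2)
    peaks <- peaks[keep, ]
  }
  spacing <- if (nrow(peaks) >= 2) mean(diff(peaks$mean_nm)) else NA_real_
  structure(
    list(
      peaks = peaks,
      spacing_nm = spacing,
      n_peaks = nrow(peaks),
      histogram = tibble::tibble(mid = mids, count = counts,
                                 fitted = gauss_sum(par, mids))
    ),
    class = "peak_set"
  )
}

abs_par <- function(p, k) {
  p[2 * k + seq_len(k)] <- abs(p[2 * k + seq_len(k)])
  p
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", x$n_peaks, " Gaussian component(s)",
      if (!is.na(x$spacing_nm)) sprintf(", mean spacing %.2f nm", x$spacing_nm)
      else ", spacing undefined", "\n", sep = "")
  print(x$peaks, ...)
  invisible(x)
}
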