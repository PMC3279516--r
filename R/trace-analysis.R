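#' Detect unfolding events in a saw-tooth force-extension trace
#'
#' An unfolding event is a sample where the (lightly median-smoothed)
#' force falls by at least `min_drop` within `window` samples while the
#' stage advances. Candidate samples are grouped into runs; each run
#' contributes one event at its force maximum. Because reversible helix
#' flicker near the plateau also produces fast force drops, events whose
#' peak force is below `min_peak_force` are discarded (Ig unfolding
#' peaks sit far above the ~30 pN plateau).
#'
#' @param trace A force-extension tibble with columns `time_s`,
#'   `stage_nm`, `extension_nm`, `force_pN`.
#' @param min_drop Minimum force drop, pN.
#' @param window Look-ahead window in samples; default the number of
#'   samples in 1 ms (from the time column).
#' @param min_peak_force Discard events whose peak force is below this, pN.
#' @return A tibble of class `unfolding_events`: `index`, `time_s`,
#'   `peak_force_pN`, `drop_pN`, `segment_start` (index opening the
#'   rising segment that precedes the event).
#' @examples
#' arch <- canonical_architecture()
#' tr <- simulate_pull(arch, constant_velocity_protocol(400, 1000, seed = 7))
#' detect_events(tr)
#' @export
detect_events <- function(trace, min_drop = 10, window = NULL,
                          min_peak_force = 50) {
  check_trace(trace)
  n <- nrow(trace)
  if (is.null(window)) {
    dt <- stats::median(diff(trace$time_s))
    window <- max(3L, round(1e-3 / dt))
  }
  f <- stats::runmed(trace$force_pN, k = 5, endrule = "constant")
  # minimum of f over the next `window` samples
  fwd_min <- rev(-zoo::rollapplyr(rev(-f), width = window, FUN = max,
                                  partial = TRUE))
  drop <- f - fwd_min
  advancing <- c(diff(trace$stage_nm) > 0, FALSE)
  cand <- which(drop >= min_drop & advancing & f >= min_peak_force)
  if (!length(cand)) {
    return(empty_events())
  }
  runs <- cumsum(c(1, diff(cand) > window))
  idx <- vapply(split(cand, runs), function(ii) ii[which.max(f[ii])], numeric(1))
  idx <- sort(unname(idx))
  # merge events closer than one window, keeping the higher peak
  keep <- rep(TRUE, length(idx))
  if (length(idx) > 1) {
    for (j in 2:length(idx)) {
      if (idx[j] - idx[j - 1] <= window && keep[j - 1]) {
        if (f[idx[j]] > f[idx[j - 1]]) keep[j - 1] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  idx <- idx[keep]
  seg_start <- c(1L, utils::head(idx, -1) + window)
  out <- tibble::tibble(
    index = as.integer(idx),
    time_s = trace$time_s[idx],
    peak_force_pN = f[idx],
    drop_pN = drop[idx],
    segment_start = as.integer(pmin(seg_start, idx))
  )
  class(out) <- c("unfolding_events", class(out))
  out
}

empty_events <- function() {
  out <- tibble::tibble(index = integer(0), time_s = numeric(0),
                        peak_force_pN = numeric(0), drop_pN = numeric(0),
                        segment_start = integer(0))
  class(out) <- c("unfolding_events", class(out))
  out
}

check_trace <- function(trace) {
  req <- c("time_s", "stage_nm", "extension_nm", "force_pN")
  miss <- setdiff(req, names(trace))
  if (length(miss)) stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trace) == 0) stop("trace is empty")
  invisible(trace)
}

#' Fit worm-like chains to the rising segments of a saw-tooth trace
#'
#' Each rising segment (between consecutive unfolding events, plus the
#' final segment after the last event) is fitted with a worm-like chain
#' of fixed persistence length; the fitted contour length per segment and
#' the successive contour-length increments Delta-L are returned. The fit
#' model is `extension = L * phi(F)`, with `phi(F)` the Marko-Siggia
#' fractional extension at the fixed persistence length: the tether is
#' treated as a single effective worm-like chain, `L` obtained by linear
#' least squares and refined against the force residuals. With
#' `offset = TRUE` the model becomes `extension = c0 + L * phi(F)`,
#' which absorbs the axial extent of rigid folded modules in traces
#' generated with `folded_compliance = "rigid"` (the affine fit is much
#' less well conditioned over a narrow force range, so it is not the
#' default). Only samples with force at or above `min_force` enter a
#' fit, which keeps the reversible helix plateau out of the Ig segment
#' fits.
#'
#' @param trace A force-extension tibble.
#' @param events An event table from [detect_events()] (computed if
#'   omitted).
#' @param persistence_length Fixed persistence length, nm (never free).
#' @param min_force Lower force bound for samples entering a fit, pN.
#' @param min_samples Segments with fewer usable samples are skipped with
#'   a warning.
#' @param offset Also fit an additive extension offset per segment?
#' @return A tibble of class `wlc_segment_fit` with one row per fitted
#'   segment: `segment`, `n_samples`, `contour_nm`, `offset_nm`,
#'   `delta_L_nm` (the increment over the immediately preceding segment;
#'   NA for the first fitted segment and after a skipped one).
#' @export
fit_wlc_segments <- function(trace, events = NULL,
                             persistence_length = 0.5,
                             min_force = 40,
                             min_samples = 10,
                             offset = FALSE) {
  check_trace(trace)
  if (is.null(events)) events <- detect_events(trace)
  bounds <- c(0L, events$index, nrow(trace))
  fits <- purrr::map(seq_len(length(bounds) - 1), function(s) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1]
    seg <- trace[lo:hi, ]
    seg <- seg[seg$force_pN >= min_force & seg$force_pN < Inf, ]
    if (nrow(seg) < min_samples) {
      warning("segment ", s, " has fewer than ", min_samples,
              " samples above ", min_force, " pN; skipped")
      return(NULL)
    }
    phi <- ms_frac_at_force(seg$force_pN, persistence_length)
    if (offset) {
      cf <- stats::lm.fit(cbind(1, phi), seg$extension_nm)$coefficients
      c0 <- cf[1]; L0 <- max(cf[2], 1)
    } else {
      c0 <- 0; L0 <- sum(seg$extension_nm * phi) / sum(phi^2)
    }
    # refine on force residuals (the noise lives in force, not extension)
    refined <- tryCatch({
      frac <- function(L, c0) pmin(pmax((seg$extension_nm - c0) / L, 1e-9), 0.999)
      fit <- if (offset) {
        minpack.lm::nls.lm(
          par = c(L0, c0),
          fn = function(p) seg$force_pN - ms_force_frac(frac(p[1], p[2]),
                                                        persistence_length)
        )
      } else {
        minpack.lm::nls.lm(
          par = L0,
          fn = function(p) seg$force_pN - ms_force_frac(frac(p[1], 0),
                                                        persistence_length)
        )
      }
      c(L = fit$par[1], c0 = if (offset) fit$par[2] else 0)
    }, error = function(e) c(L = unname(L0), c0 = unname(c0)))
    tibble::tibble(segment = s, n_samples = nrow(seg),
                   contour_nm = unname(refined["L"]),
                   offset_nm = unname(refined["c0"]))
  })
  out <- dplyr::bind_rows(fits)
  if (nrow(out)) {
    out$delta_L_nm <- c(NA_real_, diff(out$contour_nm))
    consecutive <- c(FALSE, diff(out$segment) == 1)
    out$delta_L_nm[!consecutive] <- NA_real_
  }
  class(out) <- c("wlc_segment_fit", class(out))
  out
}

#' Contour-length transformation of a force-extension trace
#'
#' Maps every sample with force at or above `force_floor` to the contour
#' length of the (fixed-persistence) worm-like chain passing through its
#' (extension, force) point: `L = x / phi(F)`. On data generated by a
#' single worm-like chain the series is constant; sequential unfolding
#' produces a stepped series whose histogram peaks are spaced by the
#' per-element contour gain. Below the floor the inversion amplifies
#' noise, so those samples are excluded (their count is reported in the
#' `n_below_floor` attribute).
#'
#' @param trace A force-extension tibble.
#' @param persistence_length Fixed persistence length, nm.
#' @param force_floor Minimum force for a sample to be transformed, pN.
#' @param range Optional extension range `c(lo, hi)` (nm) restricting the
#'   transformation, e.g. to a detected plateau.
#' @return A tibble of class `contour_length_series`: `index`, `time_s`,
#'   `force_pN`, `extension_nm`, `contour_nm`.
#' @export
contour_length_transform <- function(trace, persistence_length = 0.5,
                                     force_floor = 5, range = NULL) {
  check_trace(trace)
  if (persistence_length <= 0) stop("`persistence_length` must be positive")
  if (force_floor <= 0) stop("`force_floor` must be positive")
  keep <- trace$force_pN >= force_floor
  if (!is.null(range)) {
    keep <- keep & trace$extension_nm >= range[1] & trace$extension_nm <= range[2]
  }
  n_below <- sum(trace$force_pN < force_floor)
  idx <- which(keep)
  phi <- ms_frac_at_force(trace$force_pN[idx], persistence_length)
  out <- tibble::tibble(
    index = idx,
    time_s = trace$time_s[idx],
    force_pN = trace$force_pN[idx],
    extension_nm = trace$extension_nm[idx],
    contour_nm = trace$extension_nm[idx] / phi
  )
  structure(out, class = c("contour_length_series", class(out)),
            n_below_floor = n_below)
}

#' Detect a force plateau in a force-extension trace
#'
#' Reduces the trace to median force per small extension bin, smooths
#' the profile with a rolling median whose window matches the scale of
#' the plateau's two-state substructure, and then searches for the
#' longest extension interval of span at least `min_span` in which
#' (a) the linear fit of force against extension has absolute slope at
#' most `slope_tol`, (b) the smoothed force at both endpoints deviates
#' from the interval mean by at most `dev_tol` (this rejects the steep
#' rise bordering a plateau as well as the slowly rising toe of a long
#' worm-like chain, both of which can pass a bare slope criterion), and
#' (c) the median force is at least `min_force`. The reported plateau
#' force is the median over all raw samples inside the interval.
#'
#' @param trace A force-extension tibble.
#' @param slope_tol Maximum absolute fitted slope, pN/nm.
#' @param min_span Minimum extension span of a plateau, nm.
#' @param min_force Minimum median force of a plateau, pN.
#' @param bin_width Extension bin width used for the scan, nm.
#' @param smooth_span Rolling-median smoothing window, nm.
#' @param dev_tol Maximum deviation of the smoothed endpoint forces from
#'   the interval mean, pN.
#' @return A one-row tibble (`plateau_force_pN`, `ext_lo_nm`,
#'   `ext_hi_nm`, `span_nm`, `slope_pN_per_nm`) or a zero-row tibble when
#'   no interval qualifies.
#' @export
detect_plateau <- function(trace, slope_tol = 0.3, min_span = 10,
                           min_force = 10, bin_width = 0.5,
                           smooth_span = 5.5, dev_tol = 2.5) {
  check_trace(trace)
  ext <- trace$extension_nm
  keep <- ext > 0
  d <- tibble::tibble(ext = ext[keep], force = trace$force_pN[keep])
  if (nrow(d) < 10) return(empty_plateau())
  d$bin <- floor(d$ext / bin_width)
  prof <- dplyr::summarise(dplyr::group_by(d, .data$bin),
                           ext = stats::median(.data$ext),
                           force = stats::median(.data$force), .groups = "drop")
  prof <- prof[order(prof$ext), ]
  m <- nrow(prof)
  k <- max(3L, round(smooth_span / bin_width))
  if (k %% 2 == 0) k <- k + 1L
  if (m < k + 2) return(empty_plateau())
  sm <- as.numeric(zoo::rollmedian(prof$force, k = k, fill = NA))
  ok <- which(!is.na(sm))
  if (!length(ok)) return(empty_plateau())
  x <- prof$ext[ok]; y <- sm[ok]
  mm <- length(x)
  # prefix sums for O(1) interval regression
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x^2); cxy <- cumsum(x * y)
  int_stats <- function(i, j) {
    n_ <- j - i + 1
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    den <- n_ * sxx - sx^2
    slope <- if (den > 0) (n_ * sxy - sx * sy) / den else Inf
    c(slope = slope, mean = sy / n_)
  }
  valid <- function(i, j) {
    st <- int_stats(i, j)
    abs(st["slope"]) <= slope_tol &&
      abs(y[i] - st["mean"]) <= dev_tol &&
      abs(y[j] - st["mean"]) <= dev_tol
  }
  # longest interval (span >= min_span) satisfying the criteria; the
  # slope/endpoint tests only make sense at plateau scale, so they are
  # never applied to sub-min_span intervals
  best <- NULL
  for (i in seq_len(mm)) {
    if (!is.null(best) && x[mm] - x[i] <= best$span_nm) break
    for (j in mm:i) {
      span <- x[j] - x[i]
      if (span < min_span) break
      if (!is.null(best) && span <= best$span_nm) break
      if (!valid(i, j)) next
      in_range <- d$ext >= x[i] & d$ext <= x[j]
      med <- stats::median(d$force[in_range])
      if (med < min_force) next
      st <- int_stats(i, j)
      best <- tibble::tibble(plateau_force_pN = med,
                             ext_lo_nm = x[i], ext_hi_nm = x[j],
                             span_nm = span,
                             slope_pN_per_nm = unname(st["slope"]))
      break
    }
  }
  if (is.null(best)) empty_plateau() else best
}

empty_plateau <- function() {
  tibble::tibble(plateau_force_pN = numeric(0), ext_lo_nm = numeric(0),
                 ext_hi_nm = numeric(0), span_nm = numeric(0),
                 slope_pN_per_nm = numeric(0))
}

#' Hysteresis between stretch and relax force-extension curves
#'
#' Signed area between the two curves over their common extension range,
#' computed by linear interpolation onto a common grid and trapezoidal
#' integration. Identical curves give 0; a rectangular loop of height
#' `h` pN and width `w` nm gives `h * w` pN nm.
#'
#' @param stretch,relax Force-extension tibbles.
#' @param n_grid Number of interpolation points.
#' @return Signed enclosed area (stretch minus relax), pN nm.
#' @export
hysteresis <- function(stretch, relax, n_grid = 2000) {
  check_trace(stretch); check_trace(relax)
  lo <- max(min(stretch$extension_nm), min(relax$extension_nm))
  hi <- min(max(stretch$extension_nm), max(relax$extension_nm))
  if (hi <= lo) stop("stretch and relax extension ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  fs <- stats::approx(stretch$extension_nm, stretch$force_pN, xout = grid,
                      ties = mean)$y
  fr <- stats::approx(relax$extension_nm, relax$force_pN, xout = grid,
                      ties = mean)$y
  diff_f <- fs - fr
  sum((diff_f[-1] + diff_f[-n_grid]) / 2 * diff(grid))
}
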