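#' Detect the onset of the high-frequency spectral plateau
#'
#' Slides a fixed-width window across the spectrum, fits the aperiodic
#' exponent inside each window (peak fitting disabled), and reports the
#' lowest window start whose exponent falls below a small threshold. The
#' scan stops at the first sub-threshold window; the full slope trace is
#' returned for inspection.
#'
#' @param psd A \code{"psd"} object extending at least one window beyond
#'   \code{start_hz}.
#' @param start_hz First window start in Hz.
#' @param window_hz Window width in Hz (default 50).
#' @param step_hz Step between window starts in Hz (default 1).
#' @param beta_thresh Exponent threshold below which the spectrum counts as
#'   flat (default 0.05).
#' @return Object of class \code{"plateau_report"}: \code{onset_hz} (NA if
#'   no window is flat), \code{window_slopes} (data frame of start
#'   frequencies and fitted exponents; the trace ends at the first
#'   sub-threshold window) and the detector settings.
#' @export
detect_plateau_onset <- function(psd, start_hz = 1, window_hz = 50,
                                 step_hz = 1, beta_thresh = 0.05) {
  stopifnot(inherits(psd, "psd"), start_hz > 0, window_hz > 0, step_hz > 0)
  f_max <- max(psd$freq)
  if (start_hz + window_hz > f_max)
    stop("spectrum band is narrower than one detection window")
  starts <- seq(start_hz, f_max - window_hz, by = step_hz)
  slopes <- rep(NA_real_, length(starts))
  onset <- NA_real_
  for (i in seq_along(starts)) {
    band <- psd_band(psd, starts[i], starts[i] + window_hz)
    pos <- band$power > 0
    if (sum(pos) < 3) next
    slopes[i] <- ols_aperiodic(log10(band$freq[pos]),
                               log10(band$power[pos]))[[2]]
    if (slopes[i] < beta_thresh) {
      onset <- starts[i]
      break
    }
  }
  done <- seq_len(if (is.na(onset)) length(starts) else i)
  structure(list(onset_hz = onset,
                 window_slopes = data.frame(start_hz = starts[done],
                                            exponent = slopes[done]),
                 window_hz = window_hz, step_hz = step_hz,
                 beta_thresh = beta_thresh), class = "plateau_report")
}

#' @export
print.plateau_report <- function(x, ...) {
  if (is.na(x$onset_hz))
    cat("No spectral plateau detected (no ", x$window_hz,
        " Hz window with exponent < ", x$beta_thresh, ")\n", sep = "")
  else
    cat("Spectral plateau onset at ", x$onset_hz, " Hz (", x$window_hz,
        " Hz window, threshold ", x$beta_thresh, ")\n", sep = "")
  invisible(x)
}

#' Logarithmic width of a spectral peak
#'
#' \code{log10(f2/f1)} between the lower and upper bounds of a peak. The
#' logarithmic, not the absolute, width determines how large the maximum
#' resampling factor must be for the resampling separator to remove the
#' peak; the measure is invariant under rescaling both bounds.
#'
#' @param f1 Lower peak bound in Hz (> 0).
#' @param f2 Upper peak bound in Hz (>= f1).
#' @return The logarithmic width in log10(Hz) units.
#' @export
log_peak_width <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0)) stop("peak bounds must be positive")
  if (any(f2 < f1)) stop("f2 must not be smaller than f1")
  log10(f2 / f1)
}

#' Locate peak bounds relative to an aperiodic ground truth
#'
#' Finds contiguous runs of bins whose relative deviation
#' \code{(power - truth)/truth} exceeds a threshold, and returns the first
#' and last frequency of each run. This is the bound rule used to measure
#' logarithmic peak widths on simulated spectra.
#'
#' @param psd Estimated or simulated \code{"psd"}.
#' @param aperiodic_truth A \code{"psd"} on the identical grid holding the
#'   aperiodic ground truth.
#' @param threshold Relative deviation threshold (default 0.001).
#' @return Data frame with one row per peak (columns \code{f1}, \code{f2}).
#' @export
peak_bounds <- function(psd, aperiodic_truth, threshold = 0.001) {
  stopifnot(inherits(psd, "psd"), inherits(aperiodic_truth, "psd"))
  if (length(psd$freq) != length(aperiodic_truth$freq) ||
      any(abs(psd$freq - aperiodic_truth$freq) > 1e-9))
    stop("frequency grids differ between the spectrum and the ground truth")
  keep <- psd$freq > 0 & aperiodic_truth$power > 0
  dev <- (psd$power[keep] - aperiodic_truth$power[keep]) /
    aperiodic_truth$power[keep]
  f <- psd$freq[keep]
  above <- dev > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  data.frame(f1 = f[starts[hit]], f2 = f[ends[hit]])
}

#' Straight-line exponent between two spectral points
#'
#' The naive reference estimator: the negative slope of the line connecting
#' two PSD values in double-logarithmic space,
#' \code{-(log10 P(f_hi) - log10 P(f_lo)) / (log10 f_hi - log10 f_lo)}.
#' Equals the least-squares slope exactly when the spectrum is an exact
#' power law.
#'
#' @param psd A \code{"psd"}.
#' @param f_lo,f_hi Endpoint frequencies in Hz; must be on the grid unless
#'   \code{nearest = TRUE}.
#' @param nearest If \code{TRUE}, snap off-grid endpoints to the nearest bin
#'   with a warning instead of failing.
#' @return The exponent estimate.
#' @export
straight_line_exponent <- function(psd, f_lo, f_hi, nearest = FALSE) {
  stopifnot(inherits(psd, "psd"), f_lo > 0, f_hi > f_lo)
  pick <- function(f) {
    i <- which(abs(psd$freq - f) < 1e-9)
    if (length(i) == 1) return(i)
    if (!nearest)
      stop("frequency ", f, " Hz is not on the PSD grid ",
           "(use nearest = TRUE to snap to the closest bin)")
    i <- which.min(abs(psd$freq - f))
    warning("snapping ", f, " Hz to nearest grid bin ", psd$freq[i], " Hz")
    i
  }
  i1 <- pick(f_lo); i2 <- pick(f_hi)
  if (psd$power[i1] <= 0 || psd$power[i2] <= 0)
    stop("non-positive power at an endpoint")
  -(log10(psd$power[i2]) - log10(psd$power[i1])) /
    (log10(psd$freq[i2]) - log10(psd$freq[i1]))
}

#' Sweep the lower fitting border and track the estimation error
#'
#' Estimates the 1/f exponent for every fitting range
#' \code{(border, upper_hz)} with the chosen method and tabulates the
#' absolute deviation from the ground truth. Per-border fit failures are
#' recorded as NA, never aborting the sweep. For the resampling separator
#' the expensive decomposition is computed once and only the line refit
#' varies per border.
#'
#' @param ts A \code{"neuro_ts"} (simulation provenance supplies the ground
#'   truth unless \code{beta_truth} is given).
#' @param method \code{"specparam"}, \code{"irasa"} or \code{"straight"}.
#' @param upper_hz Fixed upper border in Hz.
#' @param borders Lower borders in Hz (default 1-80 in 1 Hz steps).
#' @param beta_truth Ground-truth exponent; defaults to the provenance.
#' @param h_set Resampling set (irasa method).
#' @param segment_s Welch segment length; defaults to 1 s (specparam,
#'   straight) or 4 s (irasa).
#' @param ... Further arguments passed to the fitting routine.
#' @return Data frame of class \code{"sweep_result"} with columns
#'   \code{lower_hz}, \code{beta_hat}, \code{abs_error} and attribute
#'   \code{method}.
#' @export
sweep_lower_border <- function(ts, method = c("specparam", "irasa",
                                              "straight"),
                               upper_hz = 100, borders = 1:80,
                               beta_truth = NULL, h_set = irasa_hset(),
                               segment_s = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "neuro_ts"), all(borders < upper_hz))
  if (is.null(beta_truth)) {
    if (is.null(ts$spec))
      stop("beta_truth is required when the series has no simulation ",
           "provenance")
    beta_truth <- ts$spec$beta
  }
  if (is.null(segment_s))
    segment_s <- if (method == "irasa") 4 else 1
  est <- switch(method,
    specparam = {
      psd <- welch_psd(ts, segment_s = segment_s)
      vapply(borders, function(b)
        tryCatch(unname(coef(specparam(psd, c(b, upper_hz), ...))["exponent"]),
                 error = function(e) NA_real_), numeric(1))
    },
    irasa = {
      dec <- irasa(ts, c(min(borders), upper_hz), h_set = h_set,
                   segment_s = segment_s, ...)
      vapply(borders, function(b)
        tryCatch(unname(coef(irasa_refit(dec, c(b, upper_hz)))["exponent"]),
                 error = function(e) NA_real_), numeric(1))
    },
    straight = {
      psd <- welch_psd(ts, segment_s = segment_s)
      vapply(borders, function(b)
        tryCatch(straight_line_exponent(psd, b, upper_hz, nearest = TRUE),
                 error = function(e) NA_real_), numeric(1))
    })
  out <- data.frame(lower_hz = borders, beta_hat = est,
                    abs_error = abs(beta_truth - est))
  attr(out, "method") <- method
  attr(out, "beta_truth") <- beta_truth
  class(out) <- c("sweep_result", "data.frame")
  out
}
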