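#' Welch power spectral density estimate
#'
#' Averages modified periodograms of overlapping, windowed segments. Each
#' segment is demeaned, windowed and Fourier transformed; the one-sided
#' density is normalized so that the integral of power over frequency
#' approximates the series variance. The last incomplete segment is dropped.
#'
#' @param ts A \code{"neuro_ts"} (see \code{\link{as_timeseries}}).
#' @param segment_s Segment length in seconds; the grid spacing of the
#'   returned PSD is \code{1/segment_s} Hz.
#' @param overlap Overlap fraction between consecutive segments.
#' @param window Taper name; \code{"hann"} or \code{"rectangular"}.
#' @return Object of class \code{"psd"}: list with \code{freq} (Hz, from 0
#'   to Nyquist), \code{power} (units^2/Hz) and \code{meta}.
#' @export
welch_psd <- function(ts, segment_s = 1, overlap = 0.5, window = "hann") {
  stopifnot(inherits(ts, "neuro_ts"))
  nperseg <- round(segment_s * ts$f_sample)
  welch_core(ts$samples, ts$f_sample, nperseg, overlap, window,
             meta = list(segment_s = segment_s, window = window,
                         overlap = overlap, f_sample = ts$f_sample))
}

# Welch on a bare sample vector; `f_sample` is the rate the samples are
# *assumed* to have (the irregular-resampling separator deliberately feeds
# resampled series in here under the original rate).
welch_core <- function(x, f_sample, nperseg, overlap = 0.5,
                       window = "hann", meta = list()) {
  n <- length(x)
  if (nperseg < 2) stop("segment must contain at least 2 samples")
  if (n < nperseg)
    stop("series (", n, " samples) is shorter than one segment (",
         nperseg, " samples)")
  step <- max(1L, nperseg - floor(nperseg * overlap))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- switch(window,
    hann = 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg)),
    rectangular = rep(1, nperseg),
    stop("unknown window: ", window))
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nperseg))
  ff <- stats::mvfft(segs)
  nfreq <- nperseg %/% 2 + 1L
  pxx <- rowMeans(Mod(ff[seq_len(nfreq), , drop = FALSE])^2)
  scale <- 1 / (f_sample * sum(w^2))
  pxx <- pxx * scale
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- 2:(if (nperseg %% 2 == 0) nfreq - 1L else nfreq)
  pxx[dbl] <- 2 * pxx[dbl]
  freq <- (seq_len(nfreq) - 1L) * f_sample / nperseg
  meta$n_segments <- length(starts)
  structure(list(freq = freq, power = pxx, meta = meta), class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat("PSD: ", length(x$freq), " bins, ", x$freq[2] - x$freq[1],
      " Hz resolution, 0-", max(x$freq), " Hz", sep = "")
  if (!is.null(x$meta$n_segments))
    cat(" (", x$meta$n_segments, " segments)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.psd <- function(x, ...) {
  data.frame(freq = x$freq, power = x$power)
}

#' @export
plot.psd <- function(x, ..., log = "xy") {
  keep <- x$freq > 0 & x$power > 0
  graphics::plot(x$freq[keep], x$power[keep], type = "l", log = log,
                 xlab = "Frequency (Hz)", ylab = "PSD", ...)
  invisible(x)
}

# Extract the bins of a psd falling inside [f_lo, f_hi] (inclusive).
psd_band <- function(psd, f_lo, f_hi) {
  keep <- psd$freq >= f_lo - 1e-9 & psd$freq <= f_hi + 1e-9
  list(freq = psd$freq[keep], power = psd$power[keep])
}
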