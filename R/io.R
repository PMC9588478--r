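# Plain-text serialization. All files are delimited text with "#" comment
# headers so they remain diffable and platform independent.

header_lines <- function(meta) {
  vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), character(1))
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Write / read a PSD as two-column delimited text
#'
#' Columns \code{freq_hz} and \code{power}; estimation metadata travels in a
#' comment header.
#'
#' @param psd A \code{"psd"} object.
#' @param path File path.
#' @return \code{read_psd} returns a \code{"psd"} object.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "psd"))
  meta <- psd$meta[vapply(psd$meta, is.atomic, logical(1))]
  lines <- c(header_lines(meta), "freq_hz\tpower",
             sprintf("%.10g\t%.10g", psd$freq, psd$power))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_psd
#' @export
read_psd <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  for (k in c("segment_s", "overlap", "f_sample", "n_segments"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  structure(list(freq = df$freq_hz, power = df$power, meta = meta),
            class = "psd")
}

#' Write / read a time series as two-column delimited text
#'
#' Columns \code{time_s} and \code{value}; the sampling rate is carried in
#' the comment header and cross-checked against the time column on read.
#'
#' @param ts A \code{"neuro_ts"}.
#' @param path File path.
#' @return \code{read_timeseries} returns a \code{"neuro_ts"}.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "neuro_ts"))
  t_s <- (seq_along(ts$samples) - 1) / ts$f_sample
  lines <- c(sprintf("# f_sample: %.10g", ts$f_sample), "time_s\tvalue",
             sprintf("%.10g\t%.10g", t_s, ts$samples))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  fs <- if (!is.null(meta$f_sample)) as.numeric(meta$f_sample) else
    1 / stats::median(diff(df$time_s))
  as_timeseries(df$value, fs)
}

#' Write / read a simulation recipe as a flat key-value config file
#'
#' Keys use SI units (Hz, seconds). Peaks and transients are flattened as
#' \code{peak<i>.<field>} and \code{transient<i>.<field>}.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param path File path.
#' @return \code{read_sim_spec} returns a \code{\link{sim_spec}}.
#' @export
write_sim_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sim_spec"))
  kv <- c(beta = spec$beta, duration_s = spec$duration_s,
          f_sample = spec$f_sample,
          white_noise_scale = spec$white_noise_scale, seed = spec$seed)
  if (!is.null(spec$highpass_hz)) kv <- c(kv, highpass_hz = spec$highpass_hz)
  if (!is.null(spec$lowpass_hz)) kv <- c(kv, lowpass_hz = spec$lowpass_hz)
  for (i in seq_along(spec$peaks)) {
    p <- spec$peaks[[i]]
    kv <- c(kv, stats::setNames(c(p$f_center, p$amplitude, p$sigma_f),
      paste0("peak", i, ".", c("f_center", "amplitude", "sigma_f"))))
  }
  for (i in seq_along(spec$transients)) {
    tr <- spec$transients[[i]]
    kv <- c(kv, stats::setNames(
      c(tr$frequency, tr$amplitude, tr$start_s, tr$end_s),
      paste0("transient", i, ".",
             c("frequency", "amplitude", "start_s", "end_s"))))
  }
  writeLines(sprintf("%s = %.10g", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- as.numeric(trimws(sub("^[^=]*=", "", lines)))
  kv <- stats::setNames(as.list(vals), keys)
  grab_group <- function(prefix, fields, ctor) {
    idx <- 1
    out <- list()
    repeat {
      nms <- paste0(prefix, idx, ".", fields)
      if (!all(nms %in% keys)) break
      out[[idx]] <- do.call(ctor, unname(kv[nms]))
      idx <- idx + 1
    }
    out
  }
  peaks <- grab_group("peak", c("f_center", "amplitude", "sigma_f"),
                      peak_spec)
  transients <- grab_group("transient",
                           c("frequency", "amplitude", "start_s", "end_s"),
                           transient_spec)
  sim_spec(beta = kv$beta, duration_s = kv$duration_s,
           f_sample = kv$f_sample, peaks = peaks,
           white_noise_scale = kv$white_noise_scale,
           transients = transients, highpass_hz = kv$highpass_hz,
           lowpass_hz = kv$lowpass_hz, seed = kv$seed)
}

#' Write / read a fitted spectral model as delimited text
#'
#' One comment-header block with the aperiodic parameters and goodness of
#' fit, then one row per peak (\code{cf}, \code{pw}, \code{bw},
#' \code{sigma}).
#'
#' @param model A \code{"specparam"} fit.
#' @param path File path.
#' @return \code{read_spectral_model} returns a list with elements
#'   \code{aperiodic} (named numeric vector) and \code{peaks} (data frame).
#' @export
write_spectral_model <- function(model, path) {
  stopifnot(inherits(model, "specparam"))
  hdr <- c(offset = model$aperiodic$offset,
           exponent = model$aperiodic$exponent,
           knee = if (is.null(model$aperiodic$knee)) NA else
             model$aperiodic$knee,
           r_squared = model$goodness$r_squared,
           rmse = model$goodness$rmse,
           fit_lo_hz = model$aperiodic$fit_range[1],
           fit_hi_hz = model$aperiodic$fit_range[2])
  lines <- c(header_lines(as.list(round(hdr, 10))), "cf\tpw\tbw\tsigma")
  if (nrow(model$peaks))
    lines <- c(lines, sprintf("%.10g\t%.10g\t%.10g\t%.10g", model$peaks$cf,
                              model$peaks$pw, model$peaks$bw,
                              model$peaks$sigma))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectral_model
#' @export
read_spectral_model <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!grepl("^#", lines)]
  peaks <- utils::read.table(text = body, header = TRUE, sep = "\t")
  ap <- vapply(meta, function(v)
    if (identical(v, "NA")) NA_real_ else as.numeric(v), numeric(1))
  list(aperiodic = ap, peaks = peaks)
}

#' Write a separation result as three-column delimited text
#'
#' Columns \code{freq_hz}, \code{aperiodic}, \code{periodic}; the aperiodic
#' fit, resampling set and evaluated range go into the comment header.
#'
#' @param result An \code{"irasa"} object.
#' @param path File path.
#' @export
write_irasa_result <- function(result, path) {
  stopifnot(inherits(result, "irasa"))
  meta <- list(offset = result$fit$offset, exponent = result$fit$exponent,
               fit_lo_hz = result$fit$fit_range[1],
               fit_hi_hz = result$fit$fit_range[2],
               f_eval_min = result$evaluated$f_eval_min,
               f_eval_max = result$evaluated$f_eval_max,
               h_set = paste(signif(result$h_set$factors, 6),
                             collapse = ","),
               segment_s = result$segment_s)
  lines <- c(header_lines(meta), "freq_hz\taperiodic\tperiodic",
             sprintf("%.10g\t%.10g\t%.10g", result$aperiodic_psd$freq,
                     result$aperiodic_psd$power, result$periodic_psd$power))
  writeLines(lines, path)
  invisible(path)
}
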