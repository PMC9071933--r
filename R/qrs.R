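# QRS detection: threshold the summed D3+D4+D5 detail components at 15% of
# the maximum, open a 160 ms window around each supra-threshold run's peak,
# and take the largest denoised-signal amplitude in each window as the
# R-peak, enforcing a 200 ms physiological refractory period.

#' QRS detector parameters
#'
#' @param threshold_frac Detection threshold as a fraction of the maximum
#'   absolute value of the D3+D4+D5 region signal. Default 0.15.
#' @param window_ms Width of the search window opened around each
#'   supra-threshold run's peak. Default 160 ms.
#' @param refractory_ms Minimum spacing between R-peaks; closer detections
#'   are merged keeping the larger amplitude. Default 200 ms (ventricular
#'   refractory period).
#' @param polarity `"positive"` picks the maximum signal value in a window
#'   (upright R waves); `"absolute"` picks the maximum absolute value
#'   (handles inverted leads).
#' @return An object of class `"detector_params"`.
#' @export
detector_params <- function(threshold_frac = 0.15, window_ms = 160,
                            refractory_ms = 200,
                            polarity = c("positive", "absolute")) {
  polarity <- match.arg(polarity)
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("threshold_frac must be in (0, 1)")
  }
  if (window_ms <= 0 || refractory_ms <= 0) {
    stop("window_ms and refractory_ms must be positive")
  }
  structure(list(threshold_frac = threshold_frac, window_ms = window_ms,
                 refractory_ms = refractory_ms, polarity = polarity),
            class = "detector_params")
}

#' QRS region signal: sum of the D3, D4 and D5 components
#'
#' @param decomp A `"wavelet_decomposition"` with at least 5 levels.
#' @return Numeric vector of length `decomp$original_length`.
#' @export
qrs_region_signal <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  if (decomp$spec$levels < 5L) {
    stop("QRS region signal needs a decomposition depth of at least 5")
  }
  dwt_reconstruct(decomp, c("D3", "D4", "D5"))
}

#' Candidate QRS windows from the region signal
#'
#' Thresholds `|region|` at `threshold_frac * max(|region|)`; each maximal
#' supra-threshold run contributes one window of `window_ms` centred on the
#' run's absolute peak, clipped to the signal bounds.
#'
#' @param region Numeric vector, typically from [qrs_region_signal()].
#' @param fs Sampling frequency in Hz.
#' @param params A [detector_params()].
#' @return Integer matrix with columns `start`, `end` (inclusive, 1-based);
#'   zero rows if the region signal is identically zero.
#' @export
detect_candidate_windows <- function(region, fs, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"), length(region) > 0)
  a <- abs(region)
  mx <- max(a)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (mx == 0) {
    message("region signal is identically zero: no candidate windows")
    return(empty)
  }
  theta <- params$threshold_frac * mx
  above <- a > theta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  half <- as.integer(round(params$window_ms / 1000 * fs / 2))
  n <- length(region)
  out <- t(vapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    peak <- s + which.max(a[s:e]) - 1L
    c(max(1L, peak - half), min(n, peak + half))
  }, integer(2)))
  colnames(out) <- c("start", "end")
  out
}

#' Locate R-peaks within candidate windows
#'
#' Per window the R-peak is the index of the maximum denoised-signal value
#' (`polarity = "positive"`) or maximum absolute value (`"absolute"`).
#' Peaks closer than the refractory period are merged, keeping the one with
#' the larger amplitude.
#'
#' @param denoised Numeric vector (the denoised ECG).
#' @param windows Integer matrix of `start`,`end` windows, as returned by
#'   [detect_candidate_windows()].
#' @param fs Sampling frequency in Hz.
#' @param params A [detector_params()].
#' @return Strictly increasing integer vector of R-peak sample indices.
#' @export
locate_r_peaks <- function(denoised, windows, fs, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"))
  if (NROW(windows) == 0L) return(integer(0))
  if (any(windows < 1L) || any(windows > length(denoised))) {
    stop("candidate windows exceed signal bounds")
  }
  val <- if (params$polarity == "absolute") abs(denoised) else denoised
  peaks <- vapply(seq_len(nrow(windows)), function(i) {
    s <- windows[i, 1L]; e <- windows[i, 2L]
    s + which.max(val[s:e]) - 1L
  }, integer(1))
  o <- order(peaks)
  peaks <- peaks[o]
  refr <- round(params$refractory_ms / 1000 * fs)
  kept <- integer(0)
  for (p in peaks) {
    if (length(kept) && p - kept[length(kept)] < refr) {
      if (val[p] > val[kept[length(kept)]]) kept[length(kept)] <- p
    } else {
      kept <- c(kept, p)
    }
  }
  unique(kept)
}

#' Detect R-peaks in an ECG record
#'
#' Runs the full detection chain: db6 decomposition, denoising (D1, D2 and
#' final approximation removed), D3+D4+D5 region thresholding, windowed peak
#' search and refractory merging.
#'
#' @param record An [ecg_record()].
#' @param params A [detector_params()].
#' @param spec A [wavelet_spec()].
#' @return An object of class `"qrs_detection"`: list with `rlocs` (1-based
#'   R-peak indices), `denoised`, `fs`, `params`, `spec`, `record_id`.
#' @export
#' @examples
#' sim <- generate_ecg(synthesis_config(duration_s = 15, seed = 7))
#' det <- detect_r_peaks(sim$record)
#' det
detect_r_peaks <- function(record, params = detector_params(),
                           spec = wavelet_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  decomp <- dwt_decompose(record, spec)
  denoised <- denoise_ecg(record, spec, decomp = decomp)
  region <- qrs_region_signal(decomp)
  windows <- detect_candidate_windows(region, record$fs, params)
  rlocs <- locate_r_peaks(denoised, windows, record$fs, params)
  structure(list(rlocs = rlocs, denoised = denoised, fs = record$fs,
                 params = params, spec = spec, record_id = record$record_id),
            class = "qrs_detection")
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf("QRS detection%s: %d R-peaks in %.1f s",
              if (nzchar(x$record_id)) paste0(" '", x$record_id, "'") else "",
              length(x$rlocs), length(x$denoised) / x$fs))
  if (length(x$rlocs) > 1L) {
    cat(sprintf(" (mean HR %.0f bpm)",
                60 / mean(diff(x$rlocs) / x$fs)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.qrs_detection <- function(x, from = 1L,
                               to = min(length(x$denoised),
                                        from + as.integer(10 * x$fs) - 1L),
                               ...) {
  idx <- from:to
  graphics::plot((idx - 1) / x$fs, x$denoised[idx], type = "l",
                 xlab = "time (s)", ylab = "denoised amplitude (mV)",
                 main = x$record_id, ...)
  r <- x$rlocs[x$rlocs >= from & x$rlocs <= to]
  graphics::points((r - 1) / x$fs, x$denoised[r], col = 2, pch = 19)
  invisible(x)
}
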