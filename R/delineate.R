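# Fiducial delineation around each R-peak: Q and S troughs, QRS onset/offset
# by the flattest-slope rule, T peak and its flanking minima. Search-window
# widths are stored in milliseconds; the defaults correspond exactly to the
# sample counts 30 / 50 / 20 / 30..160 / 35 / 50 at 360 Hz.

.ms2samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Delineator parameters
#'
#' All windows are durations in milliseconds, converted to samples at the
#' record's sampling frequency; the defaults reproduce the canonical
#' 360 Hz sample counts (Q search 30, S search 50, onset/offset 20, T range
#' 30--160, T-on 35, T-off 50 samples).
#'
#' @param q_search_ms Window left of the R-peak searched for the Q trough.
#' @param s_search_ms Window right of the R-peak searched for the S trough.
#' @param onoff_search_ms Window left of Q (right of S) searched for the
#'   flattest slope, taken as QRS onset (offset).
#' @param t_range_ms Two-element range right of the R-peak searched for the
#'   T peak.
#' @param t_on_search_ms Window left of the T peak searched for its minimum
#'   (T onset).
#' @param t_off_search_ms Window right of the T peak searched for its
#'   minimum (T offset).
#' @param t_polarity `"positive"` takes the largest signed value as the T
#'   peak (default); `"absolute"` handles inverted T waves.
#' @return An object of class `"delineator_params"`.
#' @export
delineator_params <- function(q_search_ms = 30 * 1000 / 360,
                              s_search_ms = 50 * 1000 / 360,
                              onoff_search_ms = 20 * 1000 / 360,
                              t_range_ms = c(30, 160) * 1000 / 360,
                              t_on_search_ms = 35 * 1000 / 360,
                              t_off_search_ms = 50 * 1000 / 360,
                              t_polarity = c("positive", "absolute")) {
  t_polarity <- match.arg(t_polarity)
  stopifnot(q_search_ms > 0, s_search_ms > 0, onoff_search_ms > 0,
            length(t_range_ms) == 2L, t_range_ms[1] < t_range_ms[2],
            t_on_search_ms > 0, t_off_search_ms > 0)
  structure(list(q_search_ms = q_search_ms, s_search_ms = s_search_ms,
                 onoff_search_ms = onoff_search_ms, t_range_ms = t_range_ms,
                 t_on_search_ms = t_on_search_ms,
                 t_off_search_ms = t_off_search_ms, t_polarity = t_polarity),
            class = "delineator_params")
}

# argmin with explicit tie rules: "first" keeps the smallest index among
# tied minima, "last" the largest.
.argmin_first <- function(v) which.min(v)
.argmin_last <- function(v) length(v) - which.min(rev(v)) + 1L

#' Locate the Q trough left of an R-peak
#'
#' The Q point is the minimum signal value in the window of
#' `q_search_ms` immediately left of `rloc`; ties resolve to the index
#' closest to `rloc`.
#'
#' @param denoised Numeric vector (denoised ECG).
#' @param rloc R-peak sample index (1-based).
#' @param fs Sampling frequency in Hz.
#' @param params A [delineator_params()].
#' @return Integer index, or `NA` if the window leaves the record.
#' @export
locate_q <- function(denoised, rloc, fs, params = delineator_params()) {
  w <- .ms2samp(params$q_search_ms, fs)
  lo <- rloc - w
  if (lo < 1L) {
    message("Q search window precedes record start at rloc=", rloc)
    return(NA_integer_)
  }
  idx <- lo:(rloc - 1L)
  idx[.argmin_last(denoised[idx])]
}

#' Locate the S trough right of an R-peak
#'
#' Mirror of [locate_q()]: minimum over `s_search_ms` right of `rloc`,
#' ties resolving to the index closest to `rloc`.
#'
#' @inheritParams locate_q
#' @return Integer index, or `NA` if the window leaves the record.
#' @export
locate_s <- function(denoised, rloc, fs, params = delineator_params()) {
  w <- .ms2samp(params$s_search_ms, fs)
  hi <- rloc + w
  if (hi > length(denoised)) {
    message("S search window exceeds record end at rloc=", rloc)
    return(NA_integer_)
  }
  idx <- (rloc + 1L):hi
  idx[.argmin_first(denoised[idx])]
}

#' Locate QRS onset and offset by the flattest slope
#'
#' Onset is the index with minimum `|first difference|` in the window of
#' `onoff_search_ms` left of Q; offset likewise right of S. Ties resolve
#' away from the QRS complex.
#'
#' @inheritParams locate_q
#' @param qloc,sloc Q and S indices (from [locate_q()] / [locate_s()]).
#' @return Integer vector `c(qrs_on, qrs_off)`; either may be `NA` near the
#'   record edges.
#' @export
locate_qrs_bounds <- function(denoised, qloc, sloc, fs,
                              params = delineator_params()) {
  w <- .ms2samp(params$onoff_search_ms, fs)
  n <- length(denoised)
  d <- function(i) abs(denoised[i + 1L] - denoised[i])
  qrs_on <- NA_integer_
  if (!is.na(qloc)) {
    lo <- qloc - w
    if (lo >= 1L) {
      idx <- lo:(qloc - 1L)
      qrs_on <- idx[.argmin_first(d(idx))]
    } else {
      message("QRS onset window precedes record start at qloc=", qloc)
    }
  }
  qrs_off <- NA_integer_
  if (!is.na(sloc)) {
    hi <- sloc + w
    if (hi + 1L <= n) {
      idx <- (sloc + 1L):hi
      qrs_off <- idx[.argmin_last(d(idx))]
    } else {
      message("QRS offset window exceeds record end at sloc=", sloc)
    }
  }
  c(qrs_on = qrs_on, qrs_off = qrs_off)
}

#' Locate the T peak right of an R-peak
#'
#' The T peak is the largest signal value (or largest absolute value for
#' `t_polarity = "absolute"`) in `t_range_ms` right of `rloc`; ties resolve
#' to the earliest index. A range truncated by the record end is searched as
#' far as it goes.
#'
#' @inheritParams locate_q
#' @return Integer index, or `NA` if the range lies wholly outside.
#' @export
locate_t <- function(denoised, rloc, fs, params = delineator_params()) {
  r <- .ms2samp(params$t_range_ms, fs)
  lo <- rloc + r[1]
  hi <- min(rloc + r[2], length(denoised))
  if (lo > length(denoised)) {
    message("T search range lies beyond record end at rloc=", rloc)
    return(NA_integer_)
  }
  idx <- lo:hi
  v <- denoised[idx]
  if (params$t_polarity == "absolute") v <- abs(v)
  idx[which.max(v)]
}

#' Locate T onset and offset as the flanking minima
#'
#' T onset is the minimum signal value in `t_on_search_ms` left of the T
#' peak; T offset the minimum in `t_off_search_ms` right of it. Ties resolve
#' away from the T peak.
#'
#' @inheritParams locate_q
#' @param tloc T-peak index (from [locate_t()]).
#' @return Integer vector `c(t_on, t_off)`; either may be `NA` at the edges.
#' @export
locate_t_bounds <- function(denoised, tloc, fs, params = delineator_params()) {
  t_on <- NA_integer_
  t_off <- NA_integer_
  if (!is.na(tloc)) {
    w1 <- .ms2samp(params$t_on_search_ms, fs)
    if (tloc - w1 >= 1L) {
      idx <- (tloc - w1):(tloc - 1L)
      t_on <- idx[.argmin_first(denoised[idx])]
    } else {
      message("T-onset window precedes record start at tloc=", tloc)
    }
    w2 <- .ms2samp(params$t_off_search_ms, fs)
    if (tloc + w2 <= length(denoised)) {
      idx <- (tloc + 1L):(tloc + w2)
      t_off <- idx[.argmin_last(denoised[idx])]
    } else {
      message("T-offset window exceeds record end at tloc=", tloc)
    }
  }
  c(t_on = t_on, t_off = t_off)
}

#' Delineate every beat of a record
#'
#' Applies [locate_q()], [locate_s()], [locate_qrs_bounds()], [locate_t()]
#' and [locate_t_bounds()] around each R-peak. Beats whose search windows
#' leave the record carry `NA` in the affected fields.
#'
#' @param denoised Numeric vector (denoised ECG), or a `"qrs_detection"`
#'   object (in which case `rlocs` and `fs` are taken from it).
#' @param rlocs Integer vector of R-peak indices.
#' @param fs Sampling frequency in Hz.
#' @param params A [delineator_params()].
#' @return A data frame of class `"fiducial_set"` with one row per beat and
#'   integer columns `rloc`, `qloc`, `sloc`, `qrs_on`, `qrs_off`, `tloc`,
#'   `t_on`, `t_off`.
#' @export
#' @examples
#' sim <- generate_ecg(synthesis_config(duration_s = 15, seed = 7))
#' det <- detect_r_peaks(sim$record)
#' fid <- delineate_record(det)
#' head(fid)
delineate_record <- function(denoised, rlocs = NULL, fs = NULL,
                             params = delineator_params()) {
  if (inherits(denoised, "qrs_detection")) {
    if (is.null(rlocs)) rlocs <- denoised$rlocs
    if (is.null(fs)) fs <- denoised$fs
    denoised <- denoised$denoised
  }
  stopifnot(is.numeric(denoised), is.numeric(fs))
  rlocs <- as.integer(rlocs)
  rows <- lapply(rlocs, function(r) {
    qloc <- locate_q(denoised, r, fs, params)
    sloc <- locate_s(denoised, r, fs, params)
    qb <- locate_qrs_bounds(denoised, qloc, sloc, fs, params)
    tloc <- locate_t(denoised, r, fs, params)
    tb <- locate_t_bounds(denoised, tloc, fs, params)
    data.frame(rloc = r, qloc = qloc, sloc = sloc,
               qrs_on = qb[["qrs_on"]], qrs_off = qb[["qrs_off"]],
               tloc = tloc, t_on = tb[["t_on"]], t_off = tb[["t_off"]])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rloc = integer(), qloc = integer(), sloc = integer(),
               qrs_on = integer(), qrs_off = integer(), tloc = integer(),
               t_on = integer(), t_off = integer())
  class(out) <- c("fiducial_set", "data.frame")
  out
}
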