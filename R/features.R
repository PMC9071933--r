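# Per-beat feature extraction: the eight-dimensional descriptor (previous RR
# interval; Q, R, S, T amplitudes; QRS duration; QT and ST intervals) used
# by the beat classifiers.

.feature_names <- c("rr_interval", "q_amp", "r_amp", "s_amp", "t_amp",
                    "qrs_duration", "qt_interval", "st_interval")

#' Extract per-beat feature vectors
#'
#' Builds one 8-dimensional feature vector per delineated beat:
#' `rr_interval` (ms, to the previous R-peak; the first beat receives the
#' record-mean RR), amplitudes (mV) of the denoised signal at the Q, R, S
#' and T fiducials, `qrs_duration` (`qrs_off - qrs_on`), `qt_interval`
#' (`t_off - qrs_on`, the conventional QT) and `st_interval`
#' (`t_off - qrs_off`), all in milliseconds. Beats missing any required
#' fiducial are dropped with a warning.
#'
#' @param fiducials A `"fiducial_set"` from [delineate_record()].
#' @param denoised Numeric vector the fiducials refer to.
#' @param fs Sampling frequency in Hz.
#' @param labels Optional character vector of beat class labels, one per row
#'   of `fiducials`; carried through (subset to kept beats) as a `label`
#'   column.
#' @return A data frame with the eight feature columns (and `label` if
#'   given), one row per retained beat.
#' @export
extract_features <- function(fiducials, denoised, fs, labels = NULL) {
  stopifnot(is.data.frame(fiducials), is.numeric(denoised))
  if (nrow(fiducials) < 2L) {
    stop("need at least 2 beats to define RR intervals")
  }
  if (!is.null(labels) && length(labels) != nrow(fiducials)) {
    stop("labels length must match the number of beats")
  }
  rr <- c(NA_real_, diff(fiducials$rloc)) / fs * 1000
  rr[1] <- mean(rr[-1], na.rm = TRUE)
  need <- c("qloc", "sloc", "qrs_on", "qrs_off", "tloc", "t_off")
  ok <- !Reduce(`|`, lapply(fiducials[need], is.na))
  if (any(!ok)) {
    warning(sprintf("dropping %d beat(s) with missing fiducials", sum(!ok)))
  }
  f <- fiducials[ok, , drop = FALSE]
  out <- data.frame(
    rr_interval = rr[ok],
    q_amp = denoised[f$qloc],
    r_amp = denoised[f$rloc],
    s_amp = denoised[f$sloc],
    t_amp = denoised[f$tloc],
    qrs_duration = (f$qrs_off - f$qrs_on) / fs * 1000,
    qt_interval = (f$t_off - f$qrs_on) / fs * 1000,
    st_interval = (f$t_off - f$qrs_off) / fs * 1000
  )
  if (!is.null(labels)) out$label <- labels[ok]
  out
}

#' Z-score feature normalization
#'
#' Centres and scales columns using statistics of the training matrix only,
#' so the same transform can be persisted and re-applied to new data.
#' Constant columns pass through unscaled with a warning.
#'
#' @param x Numeric matrix or feature data frame to transform.
#' @param center,scale Optional persisted statistics from a previous call;
#'   when `NULL` they are computed from `x`.
#' @return Numeric matrix with attributes `center` and `scale`.
#' @export
#' @examples
#' tr <- matrix(rnorm(40), 10)
#' z <- normalize_features(tr)
#' znew <- normalize_features(matrix(rnorm(8), 2),
#'                            center = attr(z, "center"),
#'                            scale = attr(z, "scale"))
normalize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x[, setdiff(colnames(x), "label"), drop = FALSE])
  storage.mode(x) <- "double"
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    if (nrow(x) < 2L) {
      warning("single-row input: standard deviation undefined, passing through")
      scale[] <- 1
    }
    if (any(scale == 0, na.rm = TRUE)) {
      warning("constant feature column(s) pass through unscaled: ",
              paste(colnames(x)[which(scale == 0)], collapse = ", "))
      scale[scale == 0] <- 1
    }
  }
  if (length(center) != ncol(x) || length(scale) != ncol(x)) {
    stop("center/scale dimensions do not match the feature matrix")
  }
  out <- sweep(sweep(x, 2, center, `-`), 2, scale, `/`)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
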