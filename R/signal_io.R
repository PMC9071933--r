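# Record and annotation I/O: WFDB-style headers/signal files (formats 16 and
# 212) and plain CSV dialects. All sample indices in the R API are 1-based.

#' Construct a single-channel ECG record
#'
#' @param samples Numeric vector of amplitudes in millivolts (physical units,
#'   i.e. after gain correction).
#' @param fs Sampling frequency in Hz. The benchmark regime is 360 Hz.
#' @param resolution_bits ADC resolution in bits, if known (e.g. 11).
#' @param record_id Text label for reports.
#' @return An object of class `"ecg_record"`.
#' @export
#' @examples
#' ecg_record(sin(2 * pi * seq(0, 1, by = 1 / 360)), fs = 360)
ecg_record <- function(samples, fs, resolution_bits = NA_integer_,
                       record_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("an ECG record needs at least 2 samples")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite (no NA/NaN/Inf)")
  }
  fs <- as.numeric(fs)
  if (length(fs) != 1L || is.na(fs) || fs <= 0) stop("fs must be a positive number")
  structure(list(samples = samples, fs = fs,
                 resolution_bits = as.integer(resolution_bits),
                 record_id = as.character(record_id)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record%s: %d samples @ %g Hz (%.1f s)%s\n",
              if (nzchar(x$record_id)) paste0(" '", x$record_id, "'") else "",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.na(x$resolution_bits))
                sprintf(", %d-bit", x$resolution_bits) else ""))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from = 1L, to = min(length(x$samples),
                                                   from + as.integer(10 * x$fs) - 1L), ...) {
  idx <- from:to
  graphics::plot((idx - 1) / x$fs, x$samples[idx], type = "l",
                 xlab = "time (s)", ylab = "amplitude (mV)",
                 main = x$record_id, ...)
  invisible(x)
}

# ---- CSV record dialect: one sample per line, optional "mV" header --------

#' Read an ECG record (WFDB-style or CSV)
#'
#' CSV records hold one millivolt sample per line with an optional single
#' header line `mV`; the sampling frequency is not stored in the file and
#' must be supplied. WFDB-style records are read from the `.hea` header
#' (signal formats 16 and 212); only the first channel is retained and ADC
#' values are converted to millivolts with the header gain and baseline.
#'
#' @param path Path to the CSV file or to the WFDB header (`.hea`); for WFDB
#'   the record name without extension is also accepted.
#' @param fmt `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param fs Sampling frequency in Hz; required for CSV, ignored for WFDB.
#' @param record_id Optional label; defaults to the file stem.
#' @return An [ecg_record()].
#' @export
read_ecg_record <- function(path, fmt = c("auto", "csv", "wfdb"), fs = NULL,
                            record_id = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (fmt == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(fs)) stop("fs must be supplied for CSV records")
    lines <- readLines(path)
    if (length(lines) && trimws(lines[1]) == "mV") lines <- lines[-1]
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric sample '%s' at line %d of %s",
                   trimws(lines[bad]), bad, path))
    }
    if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
    return(ecg_record(vals, fs = fs, record_id = record_id))
  }
  .read_wfdb_record(path, record_id = record_id)
}

#' Write an ECG record as CSV
#'
#' One sample per line in millivolts, preceded by a `mV` header line. The
#' sampling frequency is not stored; keep it alongside.
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, digits = 10) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("mV", format(record$samples, digits = digits, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

# ---- WFDB-style reader ----------------------------------------------------

.read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- strsplit(top[1], "/")[[1]][1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1) stop("malformed WFDB header: ", hea_path)
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain_num <- sub("\\(.*\\)", "", gain_field)
    gain_num <- strsplit(gain_num, "/")[[1]][1]
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)) else 0
    adcres <- if (length(f) >= 4) as.integer(f[4]) else NA_integer_
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], format = as.integer(f[2]),
         gain = as.numeric(gain_num), baseline = baseline,
         adc_resolution = adcres, adc_zero = adczero)
  })
  list(record = rec, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_wfdb_record <- function(path, record_id = NULL) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  hd <- .read_wfdb_header(hea_path)
  s1 <- hd$signals[[1]]
  dat_path <- file.path(dirname(hea_path), s1$file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  # channels stored in the same file are interleaved sample-by-sample
  n_in_file <- sum(vapply(hd$signals, function(s) s$file == s1$file, logical(1)))
  adc <- switch(as.character(s1$format),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v, nrow = n_in_file)[1, ]
    },
    "212" = .decode_fmt212(raw, n_in_file),
    stop("unsupported WFDB signal format: ", s1$format)
  )
  if (!is.na(hd$nsamp) && length(adc) > hd$nsamp) adc <- adc[seq_len(hd$nsamp)]
  gain <- if (is.na(s1$gain) || s1$gain == 0) 200 else s1$gain
  mv <- (adc - s1$baseline) / gain
  if (is.null(record_id)) record_id <- hd$record
  ecg_record(mv, fs = hd$fs, resolution_bits = s1$adc_resolution,
             record_id = record_id)
}

# Format 212: two 12-bit two's-complement samples packed into 3 bytes.
.decode_fmt212 <- function(raw, n_in_file = 1L) {
  v <- as.integer(raw)
  nb <- (length(v) %/% 3L) * 3L
  b1 <- v[seq.int(1L, nb, by = 3L)]
  b2 <- v[seq.int(2L, nb, by = 3L)]
  b3 <- v[seq.int(3L, nb, by = 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  all_samp <- as.vector(rbind(s1, s2))
  matrix(all_samp, nrow = n_in_file)[1, ]
}

# ---- Annotations ----------------------------------------------------------

.beat_classes <- c("N", "LBBB", "RBBB", "P")

#' Construct beat annotations
#'
#' @param index Strictly increasing 1-based sample indices of beats.
#' @param label Beat class per index: `"N"`, `"LBBB"`, `"RBBB"`, `"P"` or
#'   `"OTHER"`. Unknown labels are mapped to `"OTHER"` with a warning.
#' @return An object of class `"beat_annotations"`.
#' @export
beat_annotations <- function(index = integer(), label = character()) {
  index <- as.integer(index)
  label <- as.character(label)
  if (length(label) == 0L && length(index) > 0L) {
    label <- rep("N", length(index))
  }
  if (length(index) != length(label)) stop("index and label lengths differ")
  if (length(index) > 1L && any(diff(index) <= 0L)) {
    stop("annotation indices must be strictly increasing")
  }
  if (any(index < 1L, na.rm = TRUE)) stop("annotation indices must be >= 1")
  unknown <- !(label %in% c(.beat_classes, "OTHER"))
  if (any(unknown)) {
    warning(sprintf("%d annotation label(s) outside {%s} mapped to OTHER (e.g. '%s')",
                    sum(unknown), paste(.beat_classes, collapse = ", "),
                    label[unknown][1]))
    label[unknown] <- "OTHER"
  }
  structure(list(index = index, label = label), class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("Beat annotations: %d beats", length(x$index)))
  if (length(x$index)) {
    tb <- table(x$label)
    cat(" (", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$index)

#' Read beat annotations
#'
#' Reads either the package's two-column annotation CSV (`index,label`,
#' 1-based sample indices) or a binary MIT/WFDB annotation file (detected by
#' a `.atr`/`.ann` extension or by failing to parse as text). MIT beat codes
#' 1, 2, 3 and 12 map to `N`, `LBBB`, `RBBB`, `P`; every other beat code
#' maps to `OTHER`; non-beat annotations are dropped.
#'
#' @param path Input path.
#' @return A [beat_annotations()] object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(atr|ann)$", path, ignore.case = TRUE)) {
    return(.read_mit_annotations(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "label") %in% names(df))) {
    stop("annotation CSV must have columns 'index' and 'label': ", path)
  }
  beat_annotations(df$index, df$label)
}

#' Write beat annotations as CSV
#'
#' Columns `index,label` with 1-based sample indices; round-trips exactly
#' through [read_annotations()].
#'
#' @param ann A [beat_annotations()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "beat_annotations"))
  if (dir.exists(path)) stop("path is a directory: ", path)
  df <- data.frame(index = ann$index, label = ann$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# MIT annotation format: 16-bit little-endian words; type = word >> 10,
# interval = word & 0x3FF (cumulative). Handles SKIP (59) long intervals;
# stops at the 0,0 end marker. Aux/num bytes of codes 60-63 are skipped.
.read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nw <- length(raw) %/% 2L
  words <- readBin(raw, "integer", n = nw, size = 2L, signed = FALSE,
                   endian = "little")
  beat_code_map <- c("1" = "N", "2" = "LBBB", "3" = "RBBB", "12" = "P")
  beat_codes <- c(1:13, 25, 34, 35, 38, 41)  # physiologic beat annotations
  idx <- integer(0); lab <- character(0)
  t <- 0L; i <- 1L
  while (i <= nw) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    interval <- bitwAnd(w, 1023L)
    if (code == 0L && interval == 0L) break
    if (code == 59L) {           # SKIP: next two words hold a 32-bit interval
      if (i + 2L > nw) break
      t <- t + bitwShiftL(words[i + 1L], 16L) + words[i + 2L]
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L, 63L)) {  # NUM/SUB/CHN/AUX: no time advance
      if (code == 63L) i <- i + (interval + interval %% 2L) %/% 2L
      i <- i + 1L
      next
    }
    t <- t + interval
    if (code %in% beat_codes) {
      idx <- c(idx, t + 1L)      # WFDB times are 0-based
      m <- beat_code_map[as.character(code)]
      lab <- c(lab, if (is.na(m)) "OTHER" else m)
    }
    i <- i + 1L
  }
  suppressWarnings(beat_annotations(idx, lab))
}
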