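# Independent oracles used across the suite. The DWT oracle is a plain
# double-loop convolution/decimation cascade, deliberately sharing no code
# with the package's FFT-based filter bank.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_sym_ext <- function(x, p) {
  left <- rev(x)
  right <- rev(x)
  ext <- x
  while (p > 0) {
    take <- min(p, length(x))
    ext <- c(left[seq(length(left) - take + 1, length(left))], ext,
             right[seq_len(take)])
    # alternate mirror orientation for repeated reflections
    left <- rev(left)
    right <- rev(right)
    p <- p - take
  }
  ext
}

oracle_dwt_step <- function(x, lo, hi) {
  fl <- length(lo)
  ext <- oracle_sym_ext(x, fl - 1L)
  la <- (length(x) + fl - 1L) %/% 2L
  a <- numeric(la)
  d <- numeric(la)
  for (k in seq_len(la)) {
    acc_a <- 0
    acc_d <- 0
    for (j in seq_len(fl)) {
      acc_a <- acc_a + ext[fl + 2L * k - j] * lo[j]
      acc_d <- acc_d + ext[fl + 2L * k - j] * hi[j]
    }
    a[k] <- acc_a
    d[k] <- acc_d
  }
  list(a = a, d = d)
}

oracle_db6_filters <- function() {
  lo <- wavecg:::.wavelet_filters$db6
  sgn <- rep_len(c(1, -1), length(lo))
  list(lo = lo, hi = rev(lo) * -sgn)
}

# exhaustive-scan extremum finders (plain loops)
oracle_argmin <- function(v, tie = c("first", "last")) {
  tie <- match.arg(tie)
  best <- 1L
  for (i in seq_along(v)) {
    better <- if (tie == "first") v[i] < v[best] else v[i] <= v[best]
    if (i > 1L && better) best <- i
  }
  best
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

clean_sim <- function(duration_s = 40, seed = 11, ...) {
  generate_ecg(synthesis_config(duration_s = duration_s, seed = seed,
                                noise = noise_preset("clean"), ...))
}
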