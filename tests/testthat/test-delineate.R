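fs360 <- 360

test_that("default windows reproduce the canonical 360 Hz sample counts", {
  p <- delineator_params()
  expect_equal(wavecg:::.ms2samp(p$q_search_ms, fs360), 30L)
  expect_equal(wavecg:::.ms2samp(p$s_search_ms, fs360), 50L)
  expect_equal(wavecg:::.ms2samp(p$onoff_search_ms, fs360), 20L)
  expect_equal(wavecg:::.ms2samp(p$t_range_ms, fs360), c(30L, 160L))
  expect_equal(wavecg:::.ms2samp(p$t_on_search_ms, fs360), 35L)
  expect_equal(wavecg:::.ms2samp(p$t_off_search_ms, fs360), 50L)
})

test_that("Q and S are symmetric troughs of a symmetric complex", {
  t <- seq(-0.3, 0.3, by = 1 / fs360)
  beat <- 1.0 * exp(-t^2 / (2 * 0.010^2)) -
    0.3 * exp(-(t - 0.06)^2 / (2 * 0.008^2)) -
    0.3 * exp(-(t + 0.06)^2 / (2 * 0.008^2))
  rloc <- which.max(beat)
  qloc <- locate_q(beat, rloc, fs360)
  sloc <- locate_s(beat, rloc, fs360)
  expect_lte(abs((rloc - qloc) - (sloc - rloc)), 1)
})

test_that("a monotone ramp drives Q to the far window edge", {
  x <- seq_len(400) * 0.01
  expect_equal(locate_q(x, 200L, fs360), 200L - 30L)
})

test_that("windowed extremum searches agree with an exhaustive-scan oracle", {
  set.seed(77)
  p <- delineator_params()
  for (i in 1:200) {
    x <- rnorm(400)
    rloc <- sample(100:300, 1)
    idxq <- (rloc - 30):(rloc - 1)
    vq <- x[idxq]
    expect_equal(locate_q(x, rloc, fs360, p), idxq[oracle_argmin(vq, "last")])
    idxs <- (rloc + 1):(rloc + 50)
    expect_equal(locate_s(x, rloc, fs360, p),
                 idxs[oracle_argmin(x[idxs], "first")])
    tl <- locate_t(x, rloc, fs360, p)
    idxt <- (rloc + 30):min(rloc + 160, length(x))
    expect_equal(tl, idxt[oracle_argmin(-x[idxt], "first")])
  }
})

test_that("QRS bounds take the flattest slope and break ties away from
           the complex", {
  # exactly flat isoelectric segment entering the window: zero-slope ties
  # resolve away from the complex
  x <- c(rep(0.5, 75), 0.5 - (1:40) * 0.01)
  qloc <- 85L
  b <- locate_qrs_bounds(x, qloc, NA_integer_, fs360)
  expect_equal(b[["qrs_on"]], qloc - 20L)
  # strictly convex dip: matches a brute-force scan
  set.seed(8)
  y <- cumsum(rnorm(300))
  qloc <- 150L
  sloc <- 160L
  b2 <- locate_qrs_bounds(y, qloc, sloc, fs360)
  dif <- abs(diff(y))
  idx_on <- (qloc - 20):(qloc - 1)
  expect_equal(b2[["qrs_on"]], idx_on[oracle_argmin(dif[idx_on], "first")])
  idx_off <- (sloc + 1):(sloc + 20)
  expect_equal(b2[["qrs_off"]], idx_off[oracle_argmin(dif[idx_off], "last")])
})

test_that("T peak takes the earliest maximum and its bounds the far minima
           on flat baselines", {
  x <- numeric(600)
  x[c(330, 340)] <- 1         # two equal maxima inside the T range of rloc=250
  expect_equal(locate_t(x, 250L, fs360), 330L)
  # symmetric hump on a flat baseline: minima resolve to the far window
  # edges (the windows themselves are asymmetric, 35 vs 50 samples)
  t <- seq(-0.5, 0.5, by = 1 / fs360)
  hump <- exp(-t^2 / (2 * 0.05^2))
  tl <- which.max(hump)
  tb <- locate_t_bounds(hump, tl, fs360)
  expect_equal(tb[["t_on"]], tl - 35L)
  expect_equal(tb[["t_off"]], tl + 50L)
  # with equal windows the symmetric hump gives equidistant bounds
  peq <- delineator_params(t_on_search_ms = 50 * 1000 / 360)
  tbeq <- locate_t_bounds(hump, tl, fs360, peq)
  expect_lte(abs((tl - tbeq[["t_on"]]) - (tbeq[["t_off"]] - tl)), 1)
})

test_that("beats near the record edges carry absent fields, others keep the
           ordering invariant", {
  sim <- clean_sim(duration_s = 20, seed = 19)
  den <- denoise_ecg(sim$record)
  fid <- suppressMessages(delineate_record(den, c(5L, sim$truth$rloc), fs360))
  expect_equal(nrow(fid), nrow(sim$truth) + 1)
  expect_true(is.na(fid$qloc[1]))
  expect_true(is.na(fid$qrs_on[1]))
  ok <- stats::complete.cases(fid)
  f <- fid[ok, ]
  expect_true(all(f$qrs_on <= f$qloc & f$qloc < f$rloc &
                    f$rloc < f$sloc & f$sloc <= f$qrs_off))
  expect_true(all(f$tloc > f$sloc & f$t_on < f$tloc & f$tloc < f$t_off))
  expect_equal(nrow(suppressMessages(delineate_record(den, integer(0), fs360))), 0)
})

test_that("clean fixture landmarks are recovered within tolerance", {
  sim <- clean_sim(duration_s = 40, seed = 11)
  det <- detect_r_peaks(sim$record)
  fid <- suppressMessages(delineate_record(det))
  cc <- match_beats(det, sim$truth$rloc, fs360, 50)
  pairs <- attr(cc, "pairs")
  expect_equal(nrow(pairs), nrow(sim$truth))
  tr <- sim$truth[pairs[, "ref"], ]
  fd <- fid[pairs[, "det"], ]
  expect_true(all(abs(fd$rloc - tr$rloc) <= 1))
  expect_true(all(abs(fd$qloc - tr$qloc) <= 2))
  expect_true(all(abs(fd$sloc - tr$sloc) <= 2))
  expect_true(all(abs(fd$tloc - tr$tloc) <= 2))
  dur_err <- abs((fd$qrs_off - fd$qrs_on) - (tr$qrs_off - tr$qrs_on)) / fs360 * 1000
  expect_true(all(dur_err <= 15))
  expect_true(all(abs(fd$t_on - tr$t_on) / fs360 * 1000 <= 30))
  expect_true(all(abs(fd$t_off - tr$t_off) / fs360 * 1000 <= 30))
})
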