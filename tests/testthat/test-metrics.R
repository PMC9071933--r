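test_that("identical beat lists match perfectly; matching is one-to-one", {
  r <- c(100L, 400L, 700L)
  cc <- match_beats(r, r, 360, 50)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(3L, 0L, 0L))
  # one detection between two close references: one TP, one FN
  cc2 <- match_beats(250L, c(248L, 256L), 360, 50)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(1L, 0L, 1L))
  expect_equal(unname(attr(cc2, "pairs")[, "ref"]), 1L)  # nearer wins
})

test_that("jitter within half the tolerance never breaks matching", {
  set.seed(55)
  for (trial in 1:20) {
    n <- sample(10:60, 1)
    ref <- sort(sample(1000:50000, n))
    ref <- ref[c(TRUE, diff(ref) > 200)]
    jit <- ref + sample(-9:9, length(ref), replace = TRUE)  # <= 25 ms at 360
    cc <- match_beats(sort(jit), ref, 360, 50)
    expect_equal(cc$tp, length(ref))
    expect_equal(cc$fp + cc$fn, 0L)
  }
})

test_that("count identities hold on random detection/reference pairs", {
  set.seed(66)
  for (trial in 1:20) {
    ref <- sort(sample(1:20000, sample(5:40, 1)))
    det <- sort(sample(1:20000, sample(5:40, 1)))
    cc <- match_beats(det, ref, 360, 50)
    expect_lte(cc$tp, min(length(det), length(ref)))
    expect_equal(cc$fp, length(det) - cc$tp)
    expect_equal(cc$fn, length(ref) - cc$tp)
    # shifting both lists leaves the counts unchanged
    cc2 <- match_beats(det + 1000L, ref + 1000L, 360, 50)
    expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(cc$tp, cc$fp, cc$fn))
  }
})

test_that("ratio metrics reproduce the benchmark-table rows that are
           internally consistent", {
  # 2273 beats, no errors
  c100 <- confusion_counts(tp = 2273, fp = 0, fn = 0)
  expect_equal(sensitivity(c100), 100)
  expect_equal(positive_predictivity(c100), 100)
  expect_equal(detection_error_rate(c100), 0)
  expect_equal(accuracy(c100), 100)
  # 1852 TP, clean -> zero DER
  expect_equal(detection_error_rate(confusion_counts(tp = 1852)), 0)
  # 2476 TP, no misses -> perfect sensitivity
  expect_equal(sensitivity(confusion_counts(tp = 2476, fn = 0)), 100)
  # one miss in 1759: DER 0.0568...%, printed 0.05 under truncation
  c113 <- confusion_counts(tp = 1759, fp = 0, fn = 1)
  expect_equal(detection_error_rate(c113), 100 * 1 / 1759, tolerance = 1e-12)
  expect_equal(trunc(detection_error_rate(c113) * 100) / 100, 0.05)
})

test_that("derived ratio values evaluate exactly", {
  c1 <- confusion_counts(tp = 1755, fp = 18, fn = 4)
  expect_equal(positive_predictivity(c1), 100 * 1755 / 1773, tolerance = 1e-12)
  expect_equal(detection_error_rate(c1), 100 * 22 / 1755, tolerance = 1e-12)
  expect_equal(sensitivity(confusion_counts(tp = 0, fn = 5)), 0)
  expect_equal(positive_predictivity(confusion_counts(tp = 0, fp = 3)), 0)
  expect_equal(accuracy(confusion_counts(tp = 1, fp = 1, fn = 1, tn = 1)), 50)
  # undefined denominators come back absent
  empty <- confusion_counts()
  expect_true(is.na(suppressMessages(sensitivity(empty))))
  expect_true(is.na(suppressMessages(detection_error_rate(empty))))
})

test_that("both specificity variants evaluate their stated formulas", {
  cc <- confusion_counts(tp = 10, fp = 10, tn = 90)
  expect_message(v1 <- specificity(cc), "TN/\\(TP\\+FP\\)")
  expect_equal(v1, 450)
  expect_equal(specificity(cc, "standard"), 90)
  cc2 <- confusion_counts(tp = 0, fp = 10, tn = 90)
  expect_equal(suppressMessages(specificity(cc2)), 900)
  expect_equal(specificity(cc2, "standard"), 90)
  cc3 <- confusion_counts(tp = 5, fp = 2, tn = 0)
  expect_equal(suppressMessages(specificity(cc3)), 0)
  expect_equal(specificity(cc3, "standard"), 0)
})

test_that("DER responds monotonically to error counts at fixed TP", {
  base <- detection_error_rate(confusion_counts(tp = 1000, fp = 10, fn = 10))
  expect_lt(detection_error_rate(confusion_counts(tp = 1000, fp = 5, fn = 10)),
            base)
  expect_lt(detection_error_rate(confusion_counts(tp = 1000, fp = 10, fn = 5)),
            base)
})

test_that("detection reports carry the table layout and match a brute-force
           recount", {
  rep1 <- detection_report("r100", 1:2273 * 300L, 1:2273 * 300L, 360)
  expect_equal(rep1$tb, 2273)
  expect_equal(rep1$db, 2273)
  expect_equal(c(rep1$tp, rep1$fp, rep1$fn), c(2273L, 0L, 0L))
  expect_equal(c(rep1$se, rep1$pp, rep1$der), c(100, 100, 0))
  # empty detection
  rep0 <- detection_report("none", c(100L, 500L), integer(0), 360)
  expect_equal(rep0$tp, 0)
  expect_equal(rep0$fn, 2)
  expect_equal(rep0$se, 0)
  expect_true(is.na(suppressMessages(rep0$pp)))
  # noisy fixture vs independent tally
  sim <- generate_ecg(synthesis_config(duration_s = 60, seed = 23,
                                       noise = noise_preset("noisy")))
  det <- detect_r_peaks(sim$record)
  rp <- detection_report(sim$record$record_id, sim$truth$rloc, det, 360)
  tol <- 0.05 * 360
  tp_brute <- sum(vapply(det$rlocs, function(p)
    any(abs(sim$truth$rloc - p) <= tol), logical(1)))
  expect_equal(rp$tp, tp_brute)
  expect_equal(rp$se, 100 * rp$tp / (rp$tp + rp$fn))
})

test_that("the two-decimal formatter distinguishes rounding and truncation", {
  rp <- data.frame(record_id = "x", tb = 1, db = 1, tp = 1759, fp = 0, fn = 1,
                   se = 99.943, pp = 100, der = 100 / 1759)
  class(rp) <- c("detection_report", "data.frame")
  expect_equal(format_detection_report(rp, "truncate")$der, "0.05")
  expect_equal(format_detection_report(rp, "round")$der, "0.06")
  expect_equal(format_detection_report(rp, "round")$se, "99.94")
})
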