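# Fidelity metrics and interval comparison.

test_that("snr hand checks and caps", {
  expect_equal(snr(c(1, 1, 1, 1), c(1, 1, 1, 3)), 0)
  expect_equal(snr(1:5, 1:5), 200)                 # zero-noise cap
  expect_equal(snr(c(1, -1, 1, -1), rep(0, 4)), 0) # error equals signal
  expect_error(snr(1:3, 1:4), "length mismatch")
})

test_that("median-noise snr is robust to spikes", {
  expect_equal(snrMed(c(1, 1, 1, 1), c(1, 1, 1, 3)), 200)  # median err 0
  # constant offset: all errors equal, snr_med == snr
  x <- sin(seq(0, 10, by = 0.01))
  expect_equal(snrMed(x, x + 0.2), snr(x, x + 0.2))
  # single-spike corruption inflates the mean but not the median
  xh <- x; xh[300] <- xh[300] + 5
  expect_gt(snrMed(x, xh), snr(x, xh))
})

test_that("mse and rms scale quadratically and linearly", {
  expect_equal(mseMetric(1:4, 1:4)$mse, 0)
  m <- mseMetric(c(0.1, -0.1), c(0, 0))
  expect_equal(m$mse, 0.01)
  expect_equal(m$rms, 0.1)
  m2 <- mseMetric(2 * c(0.1, -0.1), c(0, 0))
  expect_equal(m2$mse, 0.04)
})

test_that("percentile summaries match order statistics", {
  set.seed(9)
  u <- runif(1000)
  s <- percentileSummary(u)
  expect_lt(abs(s$lo_val - 0.025), 0.01)
  expect_lt(abs(s$hi_val - 0.975), 0.01)
  k <- percentileSummary(rep(3.5, 10))
  expect_equal(k$lo_val, 3.5); expect_equal(k$hi_val, 3.5)
  expect_equal(k$mean, 3.5); expect_equal(k$sd, 0)
  # one huge outlier: trimmed mean tracks the mean of the rest
  v <- c(rnorm(200), 1e6)
  s2 <- percentileSummary(v)
  expect_lt(abs(s2$mean - mean(v[-201])), 0.2)
  expect_error(percentileSummary(1), "at least 2")
})

test_that("r-peak detection and rr errors behave on synthetic rhythms", {
  ecg <- synthesizeECG(1, fs = 250, duration = 10, heart_rate_bpm = 60,
                       seed = 12)
  pk <- detectRPeaks(ecgSamples(ecg)[1L, ], 250)
  expect_equal(length(pk), 10L, tolerance = 1)
  rr_ms <- diff(pk) / 250 * 1000
  expect_lte(abs(stats::median(rr_ms) - 1000), 20)
  expect_error(detectRPeaks(rep(0, 100), 250), "no peaks")
  # identical trains: zero error; uniform delay: intervals unaffected
  expect_equal(rrError(pk, pk, 250)$mean_abs_ms, 0)
  expect_equal(rrError(pk, pk + 12L, 250)$mean_abs_ms, 0)
})

test_that("interval comparison uses the pluggable delineator", {
  fs <- 250
  ecg <- synthesizeECG(1, fs = fs, duration = 10, seed = 13)
  x <- ecgSamples(ecg)[1L, ]
  delin <- function(sig, f) {
    r <- detectRPeaks(sig, f)
    list(r = r, qrs_on = r - round(0.04 * f), qrs_off = r + round(0.04 * f),
         t_off = r + round(0.3 * f))
  }
  same <- intervalComparison(x, x, delin, fs = fs)
  expect_equal(same$qrs_ms, 0)
  expect_equal(same$qt_ms, 0)
  expect_equal(same$rr_ms, 0)
  # uniform 40 ms shift leaves all intervals unchanged
  shifted <- c(rep(0, round(0.04 * fs)), x)[seq_along(x)]
  sh <- intervalComparison(x, shifted, delin, fs = fs)
  expect_equal(sh$qt_ms, 0, tolerance = 1e-9)
  expect_equal(sh$rr_ms, 0, tolerance = 1e-9)
  # a widened-QRS delineation on the estimate shows up as the QRS error
  delin_wide <- function(sig, f) {
    d <- delin(sig, f); d$qrs_off <- d$qrs_off + round(0.008 * f); d
  }
  wide <- local({
    dr <- delin(x, fs); de <- delin_wide(x, fs)
    mean(abs((de$qrs_off - de$qrs_on) - (dr$qrs_off - dr$qrs_on))) / fs * 1000
  })
  expect_equal(wide, 8, tolerance = 1)
  # delineator failure skips the record with a warning
  expect_warning(res <- intervalComparison(x, x, function(sig, f)
    stop("boom"), fs = fs), "skipped")
  expect_null(res)
})

test_that("cohort summaries mirror the reporting schema", {
  set.seed(4)
  df <- data.frame(snr_db = rnorm(50, 12, 3), mse = abs(rnorm(50, 0.1)))
  tab <- cohortSummary(df)
  expect_identical(tab$metric, c("snr_db", "mse"))
  expect_true(all(tab$pct_lo <= tab$pct_hi))
  expect_true(all(tab$mean >= tab$pct_lo & tab$mean <= tab$pct_hi))
})
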