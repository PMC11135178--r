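# Synthetic ECG generation, physiological noise, WFDB round trips.

test_that("synthesized ECG has the expected beat count and determinism", {
  ecg <- synthesizeECG(12, fs = 250, duration = 10, heart_rate_bpm = 60,
                       seed = 1)
  x <- ecgSamples(ecg)
  expect_equal(dim(x), c(12L, 2500L))
  expect_true(all(abs(x) <= 5))
  # brute-force local-maximum scan, per lead
  for (l in seq_len(12)) {
    v <- x[l, ]
    pk <- which(diff(sign(diff(v))) == -2) + 1L
    pk <- pk[v[pk] > 0.5 * max(v)]
    expect_true(abs(length(pk) - 10L) <= 1L,
                label = sprintf("lead %d R-peak count %d", l, length(pk)))
  }
  expect_identical(ecgSamples(synthesizeECG(12, 250, 10, 60, seed = 1)), x)
  expect_false(identical(ecgSamples(synthesizeECG(12, 250, 10, 60,
                                                  seed = 2)), x))
})

test_that("degenerate generator inputs are rejected", {
  expect_error(synthesizeECG(duration = 0), "duration")
  expect_error(synthesizeECG(fs = -1), "fs")
  expect_error(synthesizeECG(heart_rate_bpm = 10), "heart_rate_bpm")
})

test_that("RR variability at fixed heart rate stays tight", {
  ecg <- synthesizeECG(1, fs = 500, duration = 30, heart_rate_bpm = 70,
                       seed = 4)
  pk <- detectRPeaks(ecgSamples(ecg)[1L, ], 500)
  rr <- diff(pk) / 500
  expect_lt(stats::sd(rr) / mean(rr), 0.2)
  expect_equal(mean(rr), 60 / 70, tolerance = 0.05)
})

test_that("noise mixing hits the target SNR across levels", {
  ecg <- synthesizeECG(3, fs = 250, duration = 10, seed = 2)
  x <- ecgSamples(ecg)
  for (target in c(-6, 0, 6, 12, 24)) {
    noisy <- addPhysiologicalNoise(ecg, noiseSpec(snr_db = target, seed = 3))
    n <- ecgSamples(noisy) - x
    realized <- 10 * log10(sum(x^2) / sum(n^2))
    expect_lt(abs(realized - target), 0.5, label = paste("snr", target))
  }
  # original object untouched
  expect_identical(ecgSamples(ecg), x)
})

test_that("noise is identity at infinite SNR and additive in structure", {
  ecg <- synthesizeECG(2, fs = 250, duration = 5, seed = 7)
  expect_identical(ecgSamples(addPhysiologicalNoise(ecg,
                     noiseSpec(snr_db = Inf))), ecgSamples(ecg))
  # the realization depends only on the seed: noise extracted from the
  # record and from its doubled copy are perfectly correlated
  sp <- noiseSpec(snr_db = 6, seed = 9)
  n1 <- ecgSamples(addPhysiologicalNoise(ecg, sp)) - ecgSamples(ecg)
  ecg2 <- ECGTimeSeries(2 * ecgSamples(ecg), samplingRate(ecg))
  n2 <- ecgSamples(addPhysiologicalNoise(ecg2, sp)) - ecgSamples(ecg2)
  expect_equal(stats::cor(as.numeric(n1), as.numeric(n2)), 1,
               tolerance = 1e-9)
  expect_equal(n2 / n1, matrix(2, nrow(n1), ncol(n1)), tolerance = 1e-9)
})

test_that("powerline-only noise concentrates at the mains frequency", {
  ecg <- synthesizeECG(1, fs = 250, duration = 10, seed = 5)
  sp <- noiseSpec(snr_db = 0, components = "powerline", mains_freq = 50,
                  seed = 6)
  n <- ecgSamples(addPhysiologicalNoise(ecg, sp)) - ecgSamples(ecg)
  pg <- stats::spec.pgram(as.numeric(n), plot = FALSE, taper = 0)
  f_peak <- pg$freq[which.max(pg$spec)] * 250
  expect_equal(f_peak, 50, tolerance = 1)
})

test_that("WFDB round trip preserves samples, rate and header fields", {
  ecg <- synthesizeECG(12, fs = 250, duration = 4, seed = 8)
  ecg@header <- list(name = "Jane Doe", date = "2001-02-03", id = "R0042")
  path <- file.path(tempdir(), "rt01")
  writeWFDB(ecg, path, gain = 1000)
  back <- readWFDB(path)
  expect_equal(samplingRate(back), 250)
  expect_identical(leadNames(back), leadNames(ecg))
  expect_lt(max(abs(ecgSamples(back) - ecgSamples(ecg))), 1 / 1000 + 1e-12)
  expect_identical(ecgHeader(back)$name, "Jane Doe")
  expect_identical(ecgHeader(back)$date, "2001-02-03")
})

test_that("WFDB reader flags missing files and malformed headers", {
  path <- file.path(tempdir(), "rt02")
  writeWFDB(synthesizeECG(2, 100, 2, seed = 1), path)
  file.remove(paste0(path, ".dat"))
  expect_error(readWFDB(path), "signal file not found")
  writeLines(c("bad"), paste0(path, ".hea"))
  expect_error(readWFDB(path), "malformed WFDB header line")
  bad2 <- file.path(tempdir(), "rt03")
  writeLines(c("rt03 1 250 100", "rt03.dat 8 200/mV"), paste0(bad2, ".hea"))
  expect_error(readWFDB(bad2), "format 16")
})
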