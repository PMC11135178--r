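# Resolution math, grid rendering, calibration pulse, trace ground truth.

test_that("resolution parameters follow the DPI formulas", {
  for (D in c(72, 200, 300)) {
    rp <- resolutionParams(D)
    expect_equal(rp$dv, 2.54 / D)
    expect_equal(rp$dt, 1.016 / D)
    expect_equal(rp$fs_img, D / 1.016)
    expect_equal(rp$dt * rp$fs_img, 1)
  }
  expect_equal(resolutionParams(200)$dv, 0.0127)
  expect_equal(resolutionParams(200)$dt, 0.00508)
  expect_equal(resolutionParams(200)$fs_img, 196.8504, tolerance = 1e-6)
  expect_equal(resolutionParams(1.016)$fs_img, 1)
  expect_error(resolutionParams(0), "positive")
})

test_that("grid canvas has the standard page dimensions and pitch", {
  spec <- renderSpec(dpi = 200)
  img <- renderGrid(spec)
  expect_equal(dim(imagePixels(img)), c(1700L, 2200L, 3L))
  # autocorrelation of the column-mean intensity peaks at the fine pitch
  prof <- colMeans(ecgpaper:::toGray(img))
  ac <- as.numeric(stats::acf(prof - mean(prof), lag.max = 30,
                              plot = FALSE)$acf)[-1L]
  loc <- which(diff(sign(diff(ac))) == -2) + 1L
  loc <- loc[ac[loc] > 0.2]  # significant maxima only
  expect_equal(loc[1L], round(200 / 25.4))
  # mean period of the vertical lines equals D/25.4 within 0.5 px
  gray <- ecgpaper:::toGray(img)
  cm <- colMeans(gray)
  line_cols <- which(cm < max(cm) - 10)
  expect_lt(abs(mean(diff(line_cols)) - 200 / 25.4), 0.5)
})

test_that("grid can be disabled and tiny paper is rejected", {
  spec <- renderSpec(dpi = 200, paper_size = c(2, 2), show_grid = FALSE)
  img <- renderGrid(spec)
  expect_equal(length(unique(as.numeric(imagePixels(img)))), 1L)
  expect_error(renderGrid(renderSpec(dpi = 100, paper_size = c(0.04, 0.04))),
               "too small")
})

test_that("calibration pulse has 1 mV x 0.2 s pixel geometry", {
  spec <- renderSpec(dpi = 200)
  p <- renderCalibrationPulse(spec, x0 = 100, baseline_row = 200)
  expect_equal(p$height_px, round(10 * 200 / 25.4))  # 10 mm
  expect_equal(p$width_px, round(5 * 200 / 25.4))    # 5 mm
  # gain halves the height in px (still 1 mV); speed doubles the width
  p2 <- renderCalibrationPulse(renderSpec(dpi = 200, gain = 5), 100, 200)
  expect_equal(p2$height_px, round(5 * 200 / 25.4))
  expect_equal(p2$height_px / p$height_px, 0.5, tolerance = 0.02)
  p3 <- renderCalibrationPulse(renderSpec(dpi = 200, paper_speed = 50),
                               100, 200)
  expect_equal(p3$width_px, round(10 * 200 / 25.4))
  expect_equal(p3$width_px / p$width_px, 2, tolerance = 0.02)
})

test_that("rendered ground truth obeys the amplitude mapping", {
  # zero signal: every polyline row equals its baseline
  z <- ECGTimeSeries(matrix(0, 12, 2500), fs = 250)
  spec <- renderSpec(dpi = 150)
  rend <- renderECG(z, spec)
  expect_equal(length(rend$truth), 13L)  # 3x4 segments + 1 strip
  for (s in gtSegments(rend$truth))
    expect_true(all(s$rows == s$baseline_row))
  # 1 mV constant: polyline sits gain*D/25.4 px above baseline
  one <- ECGTimeSeries(matrix(1, 12, 2500), fs = 250)
  rend1 <- renderECG(one, spec)
  off <- round(spec$px_per_mv)
  for (s in gtSegments(rend1$truth))
    expect_true(all(s$rows == s$baseline_row - off))
  # px-per-second identity at standard speed
  expect_equal(spec$px_per_s, 1 / resolutionParams(150)$dt)
})

test_that("renderECG validates leads and duration", {
  short <- synthesizeECG(12, 250, 5, seed = 1)
  expect_error(renderECG(short, renderSpec(dpi = 150)), "too short")
  few <- synthesizeECG(8, 250, 10, seed = 1)
  expect_error(renderECG(few, renderSpec(dpi = 150)), "lead")
})

test_that("clean grid-off render is recovered exactly by extraction", {
  # round-trip identity oracle: distortionless, grid off, smooth trace
  pg <- smoothTracePage(dpi = 150, amp_mv = 0.6, freq_hz = 1.2,
                        show_grid = FALSE)
  tr <- extractTrace(binarizeStrip(ecgpaper:::toGray(pg$image)))
  got <- traceRows(tr)[pg$cols]
  expect_identical(as.integer(got), as.integer(pg$rows))
})

test_that("asynchronous layouts stagger row time offsets", {
  ecg <- synthesizeECG(12, 250, 10, seed = 2)
  spec <- renderSpec(dpi = 150, synchronous_segments = FALSE)
  rend <- renderECG(ecg, spec)
  segs <- gtSegments(rend$truth)
  t0_first_col <- vapply(segs[c(1, 5, 9)], `[[`, 0, "t0")
  expect_equal(t0_first_col, c(0, 2.5, 5))
})
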