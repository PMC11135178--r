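# Strip detection, binarization, CCA, trace extraction, unit conversion.

test_that("strip detection counts the layout bands", {
  ecg <- synthesizeECG(12, 250, 10, seed = 3)
  rend <- renderECG(ecg, renderSpec(dpi = 150))
  clean <- removeGrid(rend$image, method = "classical")
  rois <- detectStrips(clean)
  expect_length(rois, 4L)  # 3 segment rows + 1 rhythm strip
  # each ground-truth baseline falls inside exactly one ROI
  for (s in gtSegments(rend$truth)) {
    hits <- vapply(rois, function(r)
      s$baseline_row >= r[1L] && s$baseline_row <= r[2L], TRUE)
    expect_equal(sum(hits), 1L)
  }
  expect_error(detectStrips(PaperImage(array(255, dim = c(80, 80, 3)))),
               "uniform profile")
})

test_that("single-strip images give a single ROI around the ink", {
  pg <- smoothTracePage(dpi = 150, show_grid = FALSE)
  rois <- detectStrips(pg$image)
  expect_length(rois, 1L)
  expect_true(rois[[1L]][1L] <= min(pg$rows) &&
                rois[[1L]][2L] >= max(pg$rows))
})

test_that("binarization separates dark traces from background", {
  white <- matrix(255, 30, 50)
  expect_false(any(binarizeStrip(white)))
  line <- white; line[15, ] <- 0
  m <- binarizeStrip(line)
  expect_true(all(m[15, ]))
  expect_lte(sum(m), 2 * 50)
  inv <- binarizeStrip(255 - line, invert = TRUE)
  expect_identical(inv, m)
})

test_that("component labeling equals the flood-fill oracle", {
  for (s in 1:50) {
    set.seed(s)
    mask <- matrix(runif(400) < 0.35, 20, 20)
    got <- ecgpaper:::label_components_4(mask)
    expect_identical(got, floodFillLabel(mask), label = paste("seed", s))
  }
})

test_that("component filtering and Hausdorff fusion behave as specified", {
  # two trace fragments 1 px apart fuse into one component
  mask <- matrix(FALSE, 20, 40)
  mask[10, 2:15] <- TRUE
  mask[10, 17:35] <- TRUE   # gap of one column at x = 16
  cs <- analyzeComponents(mask, min_h = 1, min_w = 3, min_area = 4,
                          fuse_dist = 2)
  expect_equal(nrow(cs$components), 1L)
  expect_equal(sort(unique(cs$labels[cs$labels > 0L])), 1)
  # an isolated speck below min_area is removed
  mask2 <- mask; mask2[3, 3] <- TRUE
  cs2 <- analyzeComponents(mask2, min_h = 1, min_w = 3, min_area = 4,
                           fuse_dist = 0)
  expect_false(cs2$labels[3, 3] > 0)
  # far-apart fragments stay separate
  cs3 <- analyzeComponents(mask, min_h = 1, min_w = 3, min_area = 4,
                           fuse_dist = 0.5)
  expect_equal(nrow(cs3$components), 2L)
  # empty masks are allowed
  cs4 <- analyzeComponents(matrix(FALSE, 5, 5))
  expect_equal(nrow(cs4$components), 0L)
})

test_that("trace extraction returns one row per column", {
  # horizontal line
  m <- matrix(FALSE, 50, 60); m[40, ] <- TRUE
  tr <- extractTrace(m)
  expect_equal(traceRows(tr), rep(40, 60))
  # rendered sine recovered within 1 px everywhere
  pg <- smoothTracePage(dpi = 150, show_grid = FALSE)
  tr2 <- extractTrace(binarizeStrip(ecgpaper:::toGray(pg$image)))
  expect_lte(max(abs(traceRows(tr2)[pg$cols] - pg$rows)), 1)
  # two strokes: the stroke continuous with its neighbors wins
  m3 <- matrix(FALSE, 50, 9)
  m3[30, ] <- TRUE          # continuous stroke at row 30
  m3[10, 5] <- TRUE         # isolated blob in the middle column
  tr3 <- extractTrace(m3)
  expect_equal(traceRows(tr3)[5], 30)
  expect_error(extractTrace(matrix(FALSE, 4, 4)), "no foreground")
  # missing columns are interpolated and flagged
  m4 <- matrix(FALSE, 20, 11)
  m4[5, 1:4] <- TRUE; m4[9, 8:11] <- TRUE
  tr4 <- extractTrace(m4)
  expect_false(all(tr4@observed))
  expect_equal(traceRows(tr4)[6], 7, tolerance = 1)
})

test_that("grid period estimation matches the DPI formula", {
  for (D in c(200, 300)) {
    spec <- renderSpec(dpi = D, paper_size = c(4, 2.5))
    img <- renderGrid(spec)
    est <- estimateGridPeriod(img)
    expect_lt(abs(est - 5 * D / 25.4) / (5 * D / 25.4), 0.02,
              label = paste("DPI", D))
  }
  expect_error(estimateGridPeriod(PaperImage(array(255, dim = c(60, 60, 3)))),
               "no periodicity")
})

test_that("unit conversion applies the 0.5 mV scaling factor", {
  y <- rep(100, 50)
  tr <- toPhysicalUnits(y, baseline_row = 100, coarse_grid_px = 39.37)
  expect_true(all(traceSignal(tr) == 0))
  # a deviation of one coarse pitch is exactly 0.5 mV
  tr2 <- toPhysicalUnits(c(100, 100 - 39.37), 100, coarse_grid_px = 39.37)
  expect_equal(traceSignal(tr2)[2L], 0.5)
  # two-route sampling frequency consistency at 200 DPI
  tr3 <- toPhysicalUnits(y, 100, coarse_grid_px = 5 * 200 / 25.4)
  expect_lt(abs(traceFs(tr3) - 200 / 1.016) / (200 / 1.016), 0.001)
  # linearity: scaling deviations by c scales mV by c
  dev <- c(0, -10, 25)
  s1 <- traceSignal(toPhysicalUnits(100 - dev, 100, coarse_grid_px = 40))
  s3 <- traceSignal(toPhysicalUnits(100 - 3 * dev, 100,
                                    coarse_grid_px = 40))
  expect_equal(s3, 3 * s1)
  expect_error(toPhysicalUnits(y, 100), "DPI or a grid")
})

test_that("resampling and alignment recover known lags and amplitudes", {
  t_ref <- seq(0, 4, by = 1 / 250)
  ref <- sin(2 * pi * 3 * t_ref)
  same <- resampleAndAlign(ref, 250, ref, 250)
  expect_equal(same$lag, 0L)
  # delayed estimate: lag recovered exactly
  est_del <- c(rep(0, 25), ref)[seq_along(ref)]
  al <- resampleAndAlign(est_del, 250, ref, 250)
  expect_equal(al$lag, 25L)
  # 10 Hz sine resampled 196.85 -> 250 Hz keeps its amplitude within 1%
  t_img <- seq(0, 2, by = 1.016 / 200)
  sig <- sin(2 * pi * 10 * t_img)
  rs <- resampleAndAlign(sig, 200 / 1.016, sin(2 * pi * 10 *
                           seq(0, 2, by = 1 / 250)), 250)
  expect_lt(max(abs(rs$est - rs$ref)), 0.01)
  expect_warning(resampleAndAlign(rep(0, 100), 100, rep(0, 100), 100),
                 "zero-variance")
})
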