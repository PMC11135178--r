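# Creases, quilting, projective transforms, imaging noise, color temp.

test_that("gaussian kernel geometry follows sigma and offset", {
  k <- gaussianKernel(2, 9)
  expect_equal(sum(k), 1)
  expect_equal(k, t(k))
  expect_equal(k, k[9:1, 9:1])          # symmetric under 180 rotation
  expect_equal(k, t(k)[, 9:1][9:1, ])   # and under 90 rotation
  # near-uniform when sigma dwarfs the support
  ku <- gaussianKernel(50, 5)
  expect_lt(max(ku) / min(ku), 1.05)
  # offset displaces the argmax by one pixel in x
  ko <- gaussianKernel(1.5, 9, offset = c(1, 0))
  am <- which(ko == max(ko), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(5, 6))
  expect_error(gaussianKernel(2, 8), "odd")
  expect_error(gaussianKernel(2, 9, offset = c(5, 0)), "offset")
})

test_that("creases darken blurred lines at quantile positions", {
  img <- PaperImage(array(255, dim = c(101, 101, 3)))
  same <- applyCreases(img, creaseSpec(n_creases = 0))
  expect_identical(imagePixels(same), imagePixels(img))
  # one vertical crease dips exactly at the center column
  one <- applyCreases(img, creaseSpec(n_creases = 1, angle_deg = 90,
                                      sigma = 2, kernel_size = 9,
                                      intensity = 0.5))
  colprof <- colMeans(ecgpaper:::toGray(one))
  expect_equal(which.min(colprof), 51L)
  expect_lt(min(colprof), 250)
  expect_equal(colprof[1L], 255)  # far from the line: untouched
  # an offset kernel makes the dip asymmetric
  off <- applyCreases(img, creaseSpec(n_creases = 1, angle_deg = 90,
                                      sigma = 2, kernel_size = 9,
                                      kernel_offset = c(2, 0),
                                      intensity = 0.5))
  po <- 255 - colMeans(ecgpaper:::toGray(off))
  ctr <- which.max(po)
  left <- sum(po[seq_len(ctr - 1L)]); right <- sum(po[-seq_len(ctr)])
  expect_gt(abs(left - right) / (left + right), 0.05)
})

test_that("minimum-error boundary cut matches hand and brute-force costs", {
  # all-zero surface: leftmost path, zero cost
  z <- minErrorBoundaryCut(matrix(0, 4, 3))
  expect_equal(z$cost, 0)
  expect_equal(z$path, rep(1L, 4L))
  # zero valley in the middle column
  e <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0, 1), 3, byrow = TRUE)
  m <- minErrorBoundaryCut(e)
  expect_equal(m$path, rep(2L, 3L))
  expect_equal(m$cost, 0)
  expect_error(minErrorBoundaryCut(matrix(numeric(0), 0, 0)), "empty")
  # exhaustive oracle on random integer surfaces
  for (s in 1:100) {
    set.seed(s)
    N <- sample(2:6, 1); M <- sample(2:5, 1)
    e <- matrix(sample(0:9, N * M, replace = TRUE), N, M)
    expect_equal(minErrorBoundaryCut(e)$cost, bruteForceCutCost(e),
                 label = paste("seed", s))
  }
})

test_that("quilting reduces seam error below the straight midline cut", {
  tex <- wrinkleSeedTexture(c(96, 96), seed = 3)
  # out size equal to the patch: a single unmodified patch of the seed
  sp1 <- quiltSpec(tex, patch = 48, out_size = c(48, 48), seed = 2)
  q1 <- quiltTexture(sp1)
  found <- FALSE
  for (r in 1:49) for (cc in 1:49)
    if (!found && all(q1 == tex[r:(r + 47), cc:(cc + 47)])) found <- TRUE
  expect_true(found)
  # constant seed texture gives a constant output
  spc <- quiltSpec(matrix(7, 60, 60), patch = 30, out_size = c(80, 80),
                   seed = 1)
  expect_true(all(quiltTexture(spc) == 7))
  # chosen seam cost is no worse than the midline seam for the same pair
  set.seed(4)
  a <- matrix(runif(48 * 8), 48, 8); b <- matrix(runif(48 * 8), 48, 8)
  e <- (a - b)^2
  cut <- minErrorBoundaryCut(e)
  expect_lte(cut$cost, sum(e[, 4]))
  expect_error(quiltSpec(tex, patch = 200), "seed texture")
})

test_that("wrinkle blending is multiplicative and edge-case exact", {
  img <- PaperImage(array(rep(c(100, 150, 200), each = 40 * 60),
                          dim = c(40, 60, 3)))
  tex <- wrinkleSeedTexture(c(40, 60), seed = 1)
  expect_identical(imagePixels(applyWrinkles(img, tex, 0)),
                   imagePixels(img))
  expect_identical(imagePixels(applyWrinkles(img, matrix(9, 40, 60), 0.7)),
                   imagePixels(img))
  full <- applyWrinkles(PaperImage(array(128, dim = c(40, 60, 3))), tex, 1)
  expect_gt(stats::cor(as.numeric(imagePixels(full)[, , 1L]),
                       as.numeric(tex)), 0.999)
  expect_error(applyWrinkles(img, tex, 1.2), "blend_alpha")
})

test_that("projective transforms map image and truth consistently", {
  pg <- smoothTracePage(dpi = 100, show_grid = FALSE)
  gt <- GroundTruth(list(list(lead = "II", t0 = 0, t1 = 1, cols = pg$cols,
                              rows = pg$rows, baseline_row = pg$baseline,
                              px_per_mv = 10, px_per_s = 10,
                              kind = "strip")))
  ident <- projectiveTransform(pg$image, diag(3), ground_truth = gt)
  expect_equal(imagePixels(ident$image), imagePixels(pg$image))
  expect_equal(gtSegments(ident$truth)[[1L]]$rows, pg$rows)
  # pure translation shifts polylines by exactly (c, f)
  tr <- projectiveTransform(pg$image,
                            rbind(c(1, 0, 12), c(0, 1, -7), c(0, 0, 1)),
                            ground_truth = gt)
  expect_equal(gtSegments(tr$truth)[[1L]]$cols, pg$cols + 12)
  expect_equal(gtSegments(tr$truth)[[1L]]$rows, pg$rows - 7)
  # known homography: corners match the manual homogeneous product
  m <- rbind(c(1.01, 0.02, 5), c(-0.015, 0.99, 3), c(5e-4, 1e-4, 1))
  res <- projectiveTransform(pg$image, m, ground_truth = gt)
  pt <- c(pg$cols[1L], pg$rows[1L])
  manual <- m %*% c(pt, 1)
  expect_equal(gtSegments(res$truth)[[1L]]$cols[1L],
               manual[1L] / manual[3L], tolerance = 1e-6)
  expect_equal(gtSegments(res$truth)[[1L]]$rows[1L],
               manual[2L] / manual[3L], tolerance = 1e-6)
  expect_error(projectiveSpec(matrix(0, 3, 3)), "singular")
})

test_that("rasterized transformed truth lands on the transformed ink", {
  pg <- smoothTracePage(dpi = 100, show_grid = FALSE)
  gt <- GroundTruth(list(list(lead = "II", t0 = 0, t1 = 1, cols = pg$cols,
                              rows = pg$rows, baseline_row = pg$baseline,
                              px_per_mv = 10, px_per_s = 10,
                              kind = "strip")))
  m <- rbind(c(1, 0.03, 8), c(-0.02, 1, 6), c(0, 0, 1))  # mild affine
  res <- projectiveTransform(pg$image, m, ground_truth = gt)
  gray <- ecgpaper:::toGray(res$image)
  s <- gtSegments(res$truth)[[1L]]
  keep <- s$cols >= 2 & s$cols <= ncol(gray) - 1 &
    s$rows >= 2 & s$rows <= nrow(gray) - 1
  dark_near <- vapply(which(keep), function(i) {
    rr <- round(s$rows[i]); cc <- round(s$cols[i])
    min(gray[(rr - 1):(rr + 1), (cc - 1):(cc + 1)]) < 128
  }, TRUE)
  expect_gt(mean(dark_near), 0.99)
})

test_that("imaging noise moments match their models", {
  img <- PaperImage(array(128, dim = c(600, 600, 3)))
  expect_identical(imagePixels(addGaussianNoise(img, 0)),
                   imagePixels(img))
  expect_identical(imagePixels(addPoissonNoise(img, 0)), imagePixels(img))
  expect_identical(imagePixels(addSaltPepperNoise(img, 0)),
                   imagePixels(img))
  g <- addGaussianNoise(img, 10, seed = 1)
  expect_equal(stats::sd(imagePixels(g) - 128), 10, tolerance = 0.02)
  p <- addPoissonNoise(img, 5, seed = 2)
  d <- imagePixels(p) - 128
  expect_true(all(d >= 0))
  expect_equal(mean(d), 5, tolerance = 0.05)
  expect_true(all(imagePixels(p) <= 255, imagePixels(p) >= 0))
  # p = 1: every pixel saturates; zero fraction is p/2 within 3 sigma
  sp <- addSaltPepperNoise(img, 1, seed = 3)
  v <- imagePixels(sp)[, , 1L]
  expect_true(all(v %in% c(0, 255)))
  n <- length(v)
  expect_lt(abs(mean(v == 0) - 0.5), 3 * sqrt(0.25 / n))
  # channels are hit jointly
  expect_identical(imagePixels(sp)[, , 1L] == 0,
                   imagePixels(sp)[, , 2L] == 0)
})

test_that("color temperature tinges orange below and blue above 6600 K", {
  img <- PaperImage(array(180, dim = c(50, 50, 3)))
  near <- applyColorTemperature(img, 6600)
  expect_lt(max(abs(imagePixels(near) - 180)), 2)
  warm <- imagePixels(applyColorTemperature(img, 1000))
  cool <- imagePixels(applyColorTemperature(img, 40000))
  expect_gt(mean(warm[, , 1L]), mean(warm[, , 3L]))
  expect_gt(mean(cool[, , 3L]), mean(cool[, , 1L]))
  # mean(R) - mean(B) decreases monotonically in K
  ks <- c(1000, 2500, 5000, 6600, 12000, 25000, 40000)
  rb <- vapply(ks, function(K) {
    px <- imagePixels(applyColorTemperature(img, K))
    mean(px[, , 1L]) - mean(px[, , 3L])
  }, 0)
  expect_true(all(diff(rb) < 0))
  expect_error(applyColorTemperature(img, 500), "K must")
})

test_that("distortion stacks are seeded and logged in provenance", {
  pg <- smoothTracePage(dpi = 100)
  cfg <- distortionProfile("scanner")
  a <- applyDistortionStack(pg$image, cfg, seed = 5)
  b <- applyDistortionStack(pg$image, cfg, seed = 5)
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  ops <- vapply(provenance(a$image), `[[`, "", "op")
  expect_true(all(c("applyCreases", "applyWrinkles",
                    "applyColorTemperature", "addGaussianNoise") %in% ops))
})
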