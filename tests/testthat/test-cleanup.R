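# Inpainting, text masks, patch split/stitch, grid removal.

test_that("inpainting restores constants and linear ramps", {
  img <- PaperImage(array(120, dim = c(40, 40, 3)))
  mask <- matrix(FALSE, 40, 40)
  expect_identical(imagePixels(inpaintImage(img, mask)),
                   imagePixels(img))
  mask[10:20, 12:22] <- TRUE
  out <- inpaintImage(img, mask)
  expect_equal(imagePixels(out), imagePixels(img))
  # linear ramp with a 5x5 hole: first-order scheme is near-exact
  ramp <- array(rep(outer(seq(0, 150, length.out = 40),
                          seq(0, 80, length.out = 40), `+`), 3),
                dim = c(40, 40, 3))
  hole <- matrix(FALSE, 40, 40); hole[18:22, 18:22] <- TRUE
  filled <- imagePixels(inpaintImage(PaperImage(ramp), hole))[, , 1L]
  expect_lt(max(abs(filled[hole] - ramp[, , 1L][hole])), 2)
  # untouched outside the mask
  expect_identical(filled[!hole], ramp[, , 1L][!hole])
  expect_error(inpaintImage(img, matrix(TRUE, 40, 40)), "entire image")
})

test_that("inpainting is idempotent on its own output", {
  set.seed(2)
  px <- array(rep(matrix(runif(1600, 50, 200), 40), 3), dim = c(40, 40, 3))
  mask <- matrix(FALSE, 40, 40); mask[15:25, 8:30] <- TRUE
  once <- imagePixels(inpaintImage(PaperImage(px), mask))
  twice <- imagePixels(inpaintImage(PaperImage(once), mask))
  expect_equal(twice, once)
})

test_that("text masks combine overlays and detector boxes", {
  img <- PaperImage(array(255, dim = c(60, 90, 3)))
  expect_error(makeTextMask(img), "overlays or a detector")
  empty <- makeTextMask(img, overlays = list())
  expect_false(any(empty))
  m <- matrix(FALSE, 60, 90); m[10, 10] <- TRUE
  raw <- makeTextMask(img, overlays = list(m), dilation = 0)
  expect_equal(sum(raw), 1L)
  dil <- makeTextMask(img, overlays = list(m), dilation = 2)
  expect_equal(sum(dil), 25L)
  det <- function(image) rbind(c(5, 5, 14, 9), c(10, 8, 19, 12))
  boxed <- makeTextMask(img, detector = det, dilation = 0)
  expect_equal(sum(boxed), 10 * 5 + 10 * 5 - 5 * 2)  # union minus overlap
})

test_that("patchify covers the image and stitches back exactly", {
  expect_equal(ecgpaper:::patchOrigins(60), c(1L, 26L, 31L))
  set.seed(3)
  ch <- matrix(runif(70 * 95, 0, 255), 70, 95)
  ps <- patchify(ch)
  expect_s3_class(ps, "PatchSet")
  expect_true(all(ps$patches >= 0 & ps$patches <= 1))
  back <- stitchPatches(ps)
  expect_equal(back, ch, tolerance = 1e-9)
  expect_error(patchify(matrix(0, 20, 20)), "smaller than the patch")
  # stitching weights are normalized: constant patches stay constant
  ps2 <- ps; ps2$patches[] <- 0.5
  expect_equal(stitchPatches(ps2), matrix(0.5 * 255, 70, 95))
  # modifying one interior patch only changes pixels under that patch
  ps3 <- ps
  k <- which(ps$origins[, 1L] == 26 & ps$origins[, 2L] == 26)[1L]
  ps3$patches[, , k] <- ps3$patches[, , k] + 0.1
  delta <- abs(stitchPatches(ps3) - back) > 1e-12
  expect_true(all(which(delta, arr.ind = TRUE)[, 1L] %in% 26:55))
  expect_true(all(which(delta, arr.ind = TRUE)[, 2L] %in% 26:55))
})

test_that("denoiser training drives the loss down and honors shapes", {
  pairs <- makeGridPatchPairs(220, seed = 21)
  spec <- denoiserSpec(depth = 3, filters = 4, kernel = 3, epochs = 3,
                       batch_size = 32, lr = 5e-3, seed = 1)
  bad <- pairs; bad$clean <- bad$clean[, , 1:10]
  expect_error(trainDenoiser(bad, spec), "identical shape")
  model <- trainDenoiser(pairs, spec)
  expect_lt(utils::tail(model$history$train, 1), model$history$train[1L])
  # zero-residual limit: identical pairs train to a near-zero residual
  idpairs <- list(noisy = pairs$clean, clean = pairs$clean)
  mid <- trainDenoiser(idpairs, spec)
  out <- predictResidual(mid, pairs$clean[, , 1:20])
  expect_lt(mean(abs(out)), 0.01)
})

test_that("denoiser models serialize losslessly", {
  pairs <- makeGridPatchPairs(120, seed = 31)
  spec <- denoiserSpec(depth = 3, filters = 4, kernel = 3, epochs = 1,
                       batch_size = 32, seed = 2)
  model <- trainDenoiser(pairs, spec)
  path <- file.path(tempdir(), "denoiser.json")
  saveDenoiser(model, path)
  back <- loadDenoiser(path)
  p1 <- predictResidual(model, pairs$noisy[, , 1:8])
  p2 <- predictResidual(back, pairs$noisy[, , 1:8])
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("classical grid removal clears grid ink but keeps the trace", {
  pg <- smoothTracePage(dpi = 150)
  px <- imagePixels(pg$image)
  grid_before <- mean(px[, , 1L] - pmax(px[, , 2L], px[, , 3L]) > 25)
  expect_gt(grid_before, 0.01)
  clean <- removeGrid(pg$image, method = "classical")
  cx <- imagePixels(clean)
  grid_after <- mean(cx[, , 1L] - pmax(cx[, , 2L], cx[, , 3L]) > 25)
  expect_lt(grid_after, 0.001)
  # trace pixels survive below the binarization threshold
  gray <- ecgpaper:::toGray(clean)
  dark <- gray[cbind(pg$rows, pg$cols)] < 128
  expect_gte(mean(dark), 0.99)
  expect_error(removeGrid(pg$image, method = "dncnn"), "model")
})
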