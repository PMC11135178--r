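# Printed/handwritten overlays and their ink masks.

test_that("one lead label is printed per rendered segment", {
  ecg <- synthesizeECG(12, 250, 10, seed = 1)
  rend <- renderECG(ecg, renderSpec(dpi = 150))
  out <- overlayLeadNames(rend$image, rend$truth)
  expect_length(out$masks, 13L)
  expect_true(all(vapply(out$masks, any, TRUE)))
  # empty ground truth leaves the image unchanged
  un <- overlayLeadNames(rend$image, GroundTruth())
  expect_identical(imagePixels(un$image), imagePixels(rend$image))
})

test_that("overlays only darken pixels inside their mask", {
  ecg <- synthesizeECG(12, 250, 10, seed = 1)
  rend <- renderECG(ecg, renderSpec(dpi = 150))
  before <- imagePixels(rend$image)
  out <- overlayLeadNames(rend$image, rend$truth)
  after <- imagePixels(out$image)
  union_mask <- Reduce(`|`, out$masks)
  changed <- apply(abs(after - before) > 0, c(1, 2), any)
  expect_true(all(changed[!union_mask] == FALSE))
})

test_that("labels can be forced off the trace", {
  ecg <- synthesizeECG(12, 250, 10, seed = 1)
  rend <- renderECG(ecg, renderSpec(dpi = 150))
  out <- overlayLeadNames(rend$image, rend$truth,
                          allow_trace_overlap = FALSE)
  H <- dim(imagePixels(rend$image))[1L]
  trace_idx <- unlist(lapply(gtSegments(rend$truth), function(s)
    (s$cols - 1L) * H + s$rows))
  for (m in out$masks)
    expect_length(intersect(which(m), trace_idx), 0L)
})

test_that("metadata rendering honors headers and templates", {
  img <- PaperImage(array(255, dim = c(120, 400, 3)))
  one <- overlayMetadata(img, header = list(date = "2001-02-03"))
  expect_length(one$masks, 1L)
  expect_gt(sum(one$masks[[1L]]), 0)
  tmp <- overlayMetadata(img, header = list(name = "A", date = "B"),
                         template = "{name} {date}")
  expect_gt(sum(tmp$masks[[1L]]), 0)
  expect_error(overlayMetadata(img, header = list(name = "A"),
                               template = "{name} {dob}"), "dob")
  none <- overlayMetadata(img, header = list())
  expect_identical(imagePixels(none$image), imagePixels(img))
})

test_that("keyword sampling is seeded and validated", {
  lex <- c("alpha", "beta", "gamma", "delta")
  expect_identical(sampleKeywords(lex, 0, seed = 1), character(0))
  expect_setequal(sampleKeywords(lex, 4, seed = 2), lex)
  expect_identical(sampleKeywords(lex, 3, seed = 5),
                   sampleKeywords(lex, 3, seed = 5))
  expect_error(sampleKeywords(character(0), 1), "empty lexicon")
  # the bundled lexicon loads
  expect_gt(length(sampleKeywords(n = 5, seed = 1)), 0)
})

test_that("handwritten overlays are deterministic and style-dependent", {
  img <- PaperImage(array(255, dim = c(200, 600, 3)))
  a <- renderHandwritten(img, "atrial fibrillation", style_id = 2,
                         anchor = c(40, 120), seed = 3)
  b <- renderHandwritten(img, "atrial fibrillation", style_id = 2,
                         anchor = c(40, 120), seed = 3)
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  c_ <- renderHandwritten(img, "atrial fibrillation", style_id = 5,
                          anchor = c(40, 120), seed = 3)
  expect_false(identical(a$mask, c_$mask))
  # no-ops and errors
  noop <- renderHandwritten(img, "", style_id = 0)
  expect_identical(imagePixels(noop$image), imagePixels(img))
  expect_error(renderHandwritten(img, "x", style_id = 9), "style_id")
  expect_error(renderHandwritten(img, "x", style_id = 1,
                                 anchor = c(1e5, 10)), "anchor")
  # random placement is reproducible per seed and in bounds
  r1 <- renderHandwritten(img, "qt", style_id = 1, seed = 11)
  r2 <- renderHandwritten(img, "qt", style_id = 1, seed = 11)
  expect_identical(r1$mask, r2$mask)
  expect_gt(sum(r1$mask), 0)
})
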