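# Printed and handwritten-style text overlays with ground-truth ink masks.

# Seven handwriting style presets: parametric warps over the package stroke
# font (slant, per-character rotation jitter, baseline sinusoid, stroke
# thickness, ink color). Styles 0..6.
HANDWRITING_STYLES <- list(
  list(slant = 0.15, jitter_deg = 4, baseline_amp = 0.04, baseline_freq = 0.8,
       thickness = 2, color = c(20, 20, 90)),
  list(slant = 0.30, jitter_deg = 7, baseline_amp = 0.08, baseline_freq = 1.2,
       thickness = 2, color = c(10, 10, 40)),
  list(slant = -0.12, jitter_deg = 5, baseline_amp = 0.05, baseline_freq = 0.6,
       thickness = 3, color = c(25, 25, 120)),
  list(slant = 0.05, jitter_deg = 10, baseline_amp = 0.10, baseline_freq = 1.6,
       thickness = 2, color = c(0, 0, 0)),
  list(slant = 0.40, jitter_deg = 3, baseline_amp = 0.03, baseline_freq = 0.5,
       thickness = 1, color = c(30, 30, 140)),
  list(slant = 0.22, jitter_deg = 8, baseline_amp = 0.12, baseline_freq = 2.0,
       thickness = 3, color = c(15, 15, 60)),
  list(slant = -0.05, jitter_deg = 6, baseline_amp = 0.06, baseline_freq = 1.0,
       thickness = 2, color = c(5, 5, 30)))

applyInk <- function(image, mask, color) {
  out <- paintMask(image, mask, color)
  rewrap(image, asPixelArray(out))
}

#' Overlay printed lead-name labels
#'
#' Prints one label per ground-truth trace segment near its start, in the
#' style of clinical printouts. With `allow_trace_overlap = FALSE` the label
#' is nudged vertically until its ink mask is disjoint from every
#' ground-truth polyline pixel.
#'
#' @param image [PaperImage-class] or pixel array.
#' @param ground_truth [GroundTruth-class] from [renderECG()].
#' @param font_size cap height in px (default 3 mm at the image DPI, 24 px
#'   when the DPI is unknown).
#' @param allow_trace_overlap may label ink touch the trace pixels?
#' @param color RGB ink color.
#' @return list with `image` (provenance updated) and `masks` (one logical
#'   H x W mask per label).
#' @export
overlayLeadNames <- function(image, ground_truth, font_size = NULL,
                             allow_trace_overlap = TRUE, color = c(0, 0, 0)) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  segs <- gtSegments(ground_truth)
  segs <- Filter(function(s) s$kind %in% c("segment", "strip"), segs)
  if (!length(segs))
    return(list(image = rewrap(image, px), masks = list()))
  if (is.null(font_size)) {
    dpi <- if (methods::is(image, "PaperImage")) imageDPI(image) else NA_real_
    font_size <- if (is.finite(dpi)) round(mmToPx(3, dpi)) else 24
  }
  trace_idx <- unlist(lapply(segs, function(s) {
    keep <- s$rows >= 1 & s$rows <= H & s$cols >= 1 & s$cols <= W
    (s$cols[keep] - 1L) * H + s$rows[keep]
  }))
  masks <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    anchor <- c(s$cols[1L] + 2, s$baseline_row - round(0.8 * font_size))
    mask <- textMask(H, W, s$lead, anchor, font_size)
    if (!allow_trace_overlap) {
      for (shift in c(0, -1, 1, -2, 2, -3, 3) * font_size) {
        mask_try <- textMask(H, W, s$lead, anchor + c(0, shift), font_size)
        if (!any(which(mask_try) %in% trace_idx)) { mask <- mask_try; break }
        mask <- mask_try
      }
    }
    masks[[i]] <- mask
    px <- asPixelArray(applyInk(px, mask, color))
  }
  out <- rewrap(image, px, "overlayLeadNames",
                list(n_labels = length(segs),
                     allow_trace_overlap = allow_trace_overlap))
  list(image = out, masks = masks)
}

#' Overlay printed metadata text
#'
#' Renders header fields (date, patient record numbers, ...) as a printed
#' text block. Either pass a named header list (each non-empty field becomes
#' a `field: value` line) or a template string with `{field}` placeholders
#' resolved from the header.
#'
#' @param image image or [PaperImage-class].
#' @param header named list of field strings (e.g. from [ecgHeader()]).
#' @param template optional template with `{field}` placeholders; referencing
#'   a field absent from `header` is an error naming the field.
#' @param anchor `(col, row)` of the text block's top-left; default top-left
#'   corner region.
#' @param font_size cap height in px.
#' @param color RGB ink color.
#' @return list with `image` and `masks` (one mask per rendered line;
#'   empty input leaves the image unchanged).
#' @export
overlayMetadata <- function(image, header = list(), template = NULL,
                            anchor = NULL, font_size = 20,
                            color = c(0, 0, 0)) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  lines <- character(0)
  if (!is.null(template) && nzchar(template)) {
    fields <- regmatches(template,
                         gregexpr("\\{([^}]+)\\}", template))[[1L]]
    fields <- gsub("[{}]", "", fields)
    unknown <- setdiff(fields, names(header))
    if (length(unknown))
      stop("template references unknown field: ",
           paste(unknown, collapse = ", "))
    out_line <- template
    for (f in fields)
      out_line <- gsub(paste0("\\{", f, "\\}"), as.character(header[[f]]),
                       out_line)
    lines <- strsplit(out_line, "\n")[[1L]]
  } else {
    keep <- vapply(header, function(v) nzchar(as.character(v)[1L]), TRUE)
    header <- header[keep]
    if (length(header))
      lines <- sprintf("%s: %s", names(header),
                       vapply(header, as.character, ""))
  }
  if (!length(lines))
    return(list(image = rewrap(image, px), masks = list()))
  if (is.null(anchor)) anchor <- c(round(0.02 * W) + 1, round(font_size * 1.6))
  masks <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    a <- c(anchor[1L], anchor[2L] + (i - 1L) * round(1.6 * font_size))
    masks[[i]] <- textMask(H, W, lines[i], a, font_size)
    px <- asPixelArray(applyInk(px, masks[[i]], color))
  }
  out <- rewrap(image, px, "overlayMetadata", list(n_lines = length(lines)))
  list(image = out, masks = masks)
}

#' Sample keywords from a lexicon
#'
#' Draws `n` phrases from a keyword lexicon (ECG/cardiovascular terms by
#' default), without replacement while possible; deterministic per seed.
#'
#' @param lexicon character vector of phrases, or path to a UTF-8 text file
#'   with one phrase per line; NULL uses the bundled ECG lexicon.
#' @param n number of phrases (>= 0).
#' @param seed integer seed.
#' @return character vector of length `n`.
#' @export
sampleKeywords <- function(lexicon = NULL, n = 1, seed = 1) {
  if (is.null(lexicon))
    lexicon <- system.file("extdata", "ecg_keywords.txt", package = "ecgpaper")
  if (is.character(lexicon) && length(lexicon) == 1L && file.exists(lexicon))
    lexicon <- readLines(lexicon, warn = FALSE, encoding = "UTF-8")
  lexicon <- lexicon[nzchar(trimws(lexicon))]
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(character(0))
  if (!length(lexicon)) stop("empty lexicon")
  withSeed(seed, {
    if (n <= length(lexicon)) sample(lexicon, n)
    else c(sample(lexicon, length(lexicon)),
           sample(lexicon, n - length(lexicon), replace = TRUE))
  })
}

#' Overlay handwritten-style text
#'
#' Renders text from the package stroke font and perturbs it per one of
#' seven handwriting style presets (slant, per-character rotation jitter,
#' baseline sinusoid, stroke thickness, blue/black ink). With `anchor =
#' NULL` an in-bounds position is drawn uniformly from the seed.
#'
#' @param image image or [PaperImage-class].
#' @param text string to write; empty text is a no-op.
#' @param style_id handwriting style, 0..6.
#' @param anchor `(col, row)` of the left baseline end, or NULL for random
#'   placement.
#' @param seed integer seed (jitter and random placement).
#' @param font_size cap height in px.
#' @return list with `image` and `mask`.
#' @export
renderHandwritten <- function(image, text, style_id = 0, anchor = NULL,
                              seed = 1, font_size = 28) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  if (!is.numeric(style_id) || length(style_id) != 1L ||
      !(style_id %in% 0:6))
    stop("style_id must lie in 0..6")
  if (!nzchar(text))
    return(list(image = rewrap(image, px), mask = matrix(FALSE, H, W)))
  style <- HANDWRITING_STYLES[[style_id + 1L]]
  text_w <- ceiling(0.85 * font_size * nchar(text)) + font_size
  mask <- withSeed(seed, {
    if (is.null(anchor)) {
      anchor <- c(stats::runif(1, 1, max(1, W - text_w)),
                  stats::runif(1, 1.5 * font_size, H - 0.5 * font_size))
    } else if (anchor[1L] < 1 || anchor[1L] > W ||
               anchor[2L] < 1 || anchor[2L] > H) {
      stop("anchor outside image bounds")
    }
    textMask(H, W, text, anchor, font_size, style = style,
             seed = NULL)  # RNG already seeded in this scope
  })
  px <- asPixelArray(applyInk(px, mask, style$color))
  out <- rewrap(image, px, "renderHandwritten",
                list(text = text, style_id = style_id, seed = seed))
  list(image = out, mask = mask)
}
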