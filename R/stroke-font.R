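# Minimal vector stroke font used for printed and handwritten-style
# overlays. Each glyph is a list of polylines in a unit box (x in 0..0.6,
# y in 0..1, y up). Lowercase renders as small caps. A stroke font keeps
# text rendering deterministic across platforms and makes the parametric
# handwriting warps (slant, jitter, baseline sine) straightforward.

STROKE_GLYPHS <- local({
  g <- list(
    "A" = list(c(0, 0, 0.3, 1, 0.6, 0), c(0.12, 0.35, 0.48, 0.35)),
    "B" = list(c(0, 0, 0, 1, 0.45, 1, 0.55, 0.85, 0.55, 0.65, 0.45, 0.5, 0, 0.5),
               c(0.45, 0.5, 0.6, 0.35, 0.6, 0.15, 0.45, 0, 0, 0)),
    "C" = list(c(0.6, 0.85, 0.45, 1, 0.15, 1, 0, 0.85, 0, 0.15, 0.15, 0,
                 0.45, 0, 0.6, 0.15)),
    "D" = list(c(0, 0, 0, 1, 0.4, 1, 0.6, 0.8, 0.6, 0.2, 0.4, 0, 0, 0)),
    "E" = list(c(0.6, 1, 0, 1, 0, 0, 0.6, 0), c(0, 0.5, 0.45, 0.5)),
    "F" = list(c(0.6, 1, 0, 1, 0, 0), c(0, 0.5, 0.45, 0.5)),
    "G" = list(c(0.6, 0.85, 0.45, 1, 0.15, 1, 0, 0.85, 0, 0.15, 0.15, 0,
                 0.45, 0, 0.6, 0.15, 0.6, 0.4, 0.35, 0.4)),
    "H" = list(c(0, 0, 0, 1), c(0.6, 0, 0.6, 1), c(0, 0.5, 0.6, 0.5)),
    "I" = list(c(0.1, 0, 0.5, 0), c(0.3, 0, 0.3, 1), c(0.1, 1, 0.5, 1)),
    "J" = list(c(0.6, 1, 0.6, 0.15, 0.45, 0, 0.15, 0, 0, 0.15)),
    "K" = list(c(0, 0, 0, 1), c(0.6, 1, 0, 0.45), c(0.2, 0.6, 0.6, 0)),
    "L" = list(c(0, 1, 0, 0, 0.6, 0)),
    "M" = list(c(0, 0, 0, 1, 0.3, 0.5, 0.6, 1, 0.6, 0)),
    "N" = list(c(0, 0, 0, 1, 0.6, 0, 0.6, 1)),
    "O" = list(c(0.15, 0, 0, 0.15, 0, 0.85, 0.15, 1, 0.45, 1, 0.6, 0.85,
                 0.6, 0.15, 0.45, 0, 0.15, 0)),
    "P" = list(c(0, 0, 0, 1, 0.45, 1, 0.6, 0.85, 0.6, 0.6, 0.45, 0.45,
                 0, 0.45)),
    "Q" = list(c(0.15, 0, 0, 0.15, 0, 0.85, 0.15, 1, 0.45, 1, 0.6, 0.85,
                 0.6, 0.15, 0.45, 0, 0.15, 0), c(0.35, 0.25, 0.65, -0.05)),
    "R" = list(c(0, 0, 0, 1, 0.45, 1, 0.6, 0.85, 0.6, 0.6, 0.45, 0.45,
                 0, 0.45), c(0.3, 0.45, 0.6, 0)),
    "S" = list(c(0.6, 0.85, 0.45, 1, 0.15, 1, 0, 0.85, 0, 0.65, 0.15, 0.5,
                 0.45, 0.5, 0.6, 0.35, 0.6, 0.15, 0.45, 0, 0.15, 0, 0, 0.15)),
    "T" = list(c(0, 1, 0.6, 1), c(0.3, 1, 0.3, 0)),
    "U" = list(c(0, 1, 0, 0.15, 0.15, 0, 0.45, 0, 0.6, 0.15, 0.6, 1)),
    "V" = list(c(0, 1, 0.3, 0, 0.6, 1)),
    "W" = list(c(0, 1, 0.15, 0, 0.3, 0.5, 0.45, 0, 0.6, 1)),
    "X" = list(c(0, 0, 0.6, 1), c(0, 1, 0.6, 0)),
    "Y" = list(c(0, 1, 0.3, 0.5, 0.6, 1), c(0.3, 0.5, 0.3, 0)),
    "Z" = list(c(0, 1, 0.6, 1, 0, 0, 0.6, 0)),
    "0" = list(c(0.15, 0, 0, 0.15, 0, 0.85, 0.15, 1, 0.45, 1, 0.6, 0.85,
                 0.6, 0.15, 0.45, 0, 0.15, 0), c(0.12, 0.2, 0.48, 0.8)),
    "1" = list(c(0.15, 0.8, 0.35, 1, 0.35, 0), c(0.15, 0, 0.55, 0)),
    "2" = list(c(0, 0.85, 0.15, 1, 0.45, 1, 0.6, 0.85, 0.6, 0.65, 0, 0,
                 0.6, 0)),
    "3" = list(c(0.05, 1, 0.55, 1, 0.3, 0.62, 0.5, 0.55, 0.6, 0.35,
                 0.6, 0.2, 0.45, 0, 0.15, 0, 0, 0.15)),
    "4" = list(c(0.45, 0, 0.45, 1, 0, 0.3, 0.6, 0.3)),
    "5" = list(c(0.6, 1, 0, 1, 0, 0.55, 0.4, 0.6, 0.6, 0.45, 0.6, 0.2,
                 0.45, 0, 0.1, 0, 0, 0.1)),
    "6" = list(c(0.55, 0.9, 0.4, 1, 0.15, 1, 0, 0.8, 0, 0.15, 0.15, 0,
                 0.45, 0, 0.6, 0.15, 0.6, 0.35, 0.45, 0.5, 0.05, 0.5)),
    "7" = list(c(0, 1, 0.6, 1, 0.2, 0)),
    "8" = list(c(0.3, 0.5, 0.12, 0.6, 0.05, 0.75, 0.12, 0.93, 0.3, 1,
                 0.48, 0.93, 0.55, 0.75, 0.48, 0.6, 0.3, 0.5, 0.1, 0.4,
                 0.02, 0.22, 0.1, 0.05, 0.3, 0, 0.5, 0.05, 0.58, 0.22,
                 0.5, 0.4, 0.3, 0.5)),
    "9" = list(c(0.05, 0.1, 0.2, 0, 0.45, 0, 0.6, 0.2, 0.6, 0.85, 0.45, 1,
                 0.15, 1, 0, 0.85, 0, 0.65, 0.15, 0.5, 0.55, 0.5)),
    "-" = list(c(0.1, 0.45, 0.5, 0.45)),
    "." = list(c(0.27, 0.02, 0.33, 0.02, 0.33, 0.08, 0.27, 0.08, 0.27, 0.02)),
    "," = list(c(0.32, 0.08, 0.24, -0.12)),
    ":" = list(c(0.27, 0.25, 0.33, 0.25, 0.33, 0.31, 0.27, 0.31, 0.27, 0.25),
               c(0.27, 0.65, 0.33, 0.65, 0.33, 0.71, 0.27, 0.71, 0.27, 0.65)),
    "/" = list(c(0.05, 0, 0.55, 1)),
    "(" = list(c(0.45, 1.05, 0.3, 0.7, 0.3, 0.3, 0.45, -0.05)),
    ")" = list(c(0.15, 1.05, 0.3, 0.7, 0.3, 0.3, 0.15, -0.05)),
    "'" = list(c(0.3, 1, 0.26, 0.82)),
    "%" = list(c(0.05, 0, 0.55, 1),
               c(0.05, 0.75, 0.15, 0.85, 0.05, 0.95, -0.02, 0.85, 0.05, 0.75),
               c(0.5, 0.05, 0.6, 0.15, 0.5, 0.25, 0.43, 0.15, 0.5, 0.05)),
    " " = list()
  )
  g
})

# Per-character stroke segments for a text string rendered at `size` px
# cap height, anchored at `anchor = (col, row)` (left end of the baseline).
# Returns a data.frame of segments in pixel coordinates (row axis down).
# style: list(slant, jitter_deg, baseline_amp, baseline_freq, thickness)
textSegments <- function(text, anchor, size, style = NULL, seed = NULL) {
  chars <- strsplit(text, "")[[1L]]
  segs <- NULL
  advance <- 0.85 * size
  withSeed(seed, {
    x_pen <- anchor[1L]
    for (k in seq_along(chars)) {
      ch <- chars[k]
      scale <- size
      if (ch %in% letters) { ch <- toupper(ch); scale <- 0.72 * size }
      gl <- STROKE_GLYPHS[[ch]]
      if (is.null(gl)) gl <- STROKE_GLYPHS[["-"]]  # unknown glyph placeholder
      rot <- if (!is.null(style) && style$jitter_deg > 0)
        stats::runif(1, -style$jitter_deg, style$jitter_deg) * pi / 180 else 0
      dy_base <- if (!is.null(style) && style$baseline_amp > 0)
        style$baseline_amp * size *
          sin(style$baseline_freq * (x_pen - anchor[1L]) / size) else 0
      slant <- if (!is.null(style)) style$slant else 0
      for (poly in gl) {
        xs <- poly[seq(1, length(poly), 2)]
        ys <- poly[seq(2, length(poly), 2)]
        # slant then per-char rotation about the glyph center
        xs2 <- xs + slant * ys
        cx <- 0.3 + slant * 0.5; cy <- 0.5
        xr <- cx + (xs2 - cx) * cos(rot) - (ys - cy) * sin(rot)
        yr <- cy + (xs2 - cx) * sin(rot) + (ys - cy) * cos(rot)
        px <- x_pen + xr * scale
        py <- anchor[2L] - yr * scale + dy_base
        if (length(px) > 1L)
          segs <- rbind(segs, cbind(px[-length(px)], py[-length(py)],
                                    px[-1L], py[-1L]))
      }
      x_pen <- x_pen + advance * (if (chars[k] %in% letters) 0.78 else 1)
    }
  })
  if (is.null(segs)) segs <- matrix(numeric(0), ncol = 4L)
  colnames(segs) <- c("x0", "y0", "x1", "y1")
  segs
}

# Rasterize text into a logical H x W mask.
textMask <- function(H, W, text, anchor, size, style = NULL, seed = NULL) {
  segs <- textSegments(text, anchor, size, style, seed)
  if (!nrow(segs)) return(matrix(FALSE, H, W))
  th <- if (!is.null(style)) style$thickness else 1
  rasterSegments(H, W, segs[, "x0"], segs[, "y0"], segs[, "x1"], segs[, "y1"],
                 thickness = th)
}
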