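# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' All user-facing randomness in the package flows through a single integer
#' seed per call; the caller's RNG state is restored afterwards.
#'
#' @param seed integer seed or NULL (use current RNG state).
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# millimetres to (real-valued) pixels at D dots per inch
mmToPx <- function(mm, dpi) mm * dpi / 25.4

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}

# Accept a PaperImage or a raw array/matrix; return numeric array H x W x 3.
asPixelArray <- function(image) {
  if (methods::is(image, "PaperImage")) image <- imagePixels(image)
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a PaperImage or an H x W x 3 array")
  storage.mode(image) <- "double"
  image
}

# Luminance conversion with the usual Rec.601 weights.
toGray <- function(image) {
  px <- asPixelArray(image)
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# Return an updated PaperImage when the input was one, else the raw array.
rewrap <- function(image, pixels, op = NULL, params = list()) {
  if (methods::is(image, "PaperImage")) {
    image@pixels <- pixels
    if (!is.null(op)) image@provenance <- c(image@provenance,
                                            list(list(op = op, params = params)))
    image
  } else pixels
}

# Bilinear sampling of a single-channel matrix at fractional (row, col)
# positions; out-of-range positions return `fill`.
bilinearSample <- function(mat, rows, cols, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= H - 1 & c0 <= W - 1
  # edge band: clamp positions that are within half a pixel of the border
  edge <- !ok & rows >= 0.5 & cols >= 0.5 & rows <= H + 0.5 & cols <= W + 0.5
  out <- rep(fill, length(rows))
  if (any(ok)) {
    i0 <- (c0[ok] - 1L) * H + r0[ok]
    v00 <- mat[i0]; v10 <- mat[i0 + 1L]
    v01 <- mat[i0 + H]; v11 <- mat[i0 + H + 1L]
    out[ok] <- v00 * (1 - fr[ok]) * (1 - fc[ok]) + v10 * fr[ok] * (1 - fc[ok]) +
      v01 * (1 - fr[ok]) * fc[ok] + v11 * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    rr <- clamp(round(rows[edge]), 1, H); cc <- clamp(round(cols[edge]), 1, W)
    out[edge] <- mat[cbind(rr, cc)]
  }
  out
}

# Block-mean downsample of a matrix by an integer factor (for coarse searches).
blockMean <- function(mat, f) {
  if (f <= 1L) return(mat)
  H <- (nrow(mat) %/% f) * f; W <- (ncol(mat) %/% f) * f
  m <- mat[seq_len(H), seq_len(W), drop = FALSE]
  dim(m) <- c(f, H %/% f, W)
  m <- colMeans(m)
  dim(m) <- c(H %/% f, f, W %/% f)
  m <- aperm(m, c(2L, 1L, 3L))
  dim(m) <- c(f, (H %/% f) * (W %/% f))
  m <- colMeans(m)
  matrix(m, H %/% f, W %/% f)
}

# Separable moving-average of a vector with replicated edges.
movingAverage <- function(x, L) {
  if (L %% 2L != 1L) stop("filter order must be odd")
  m <- (L - 1L) / 2L
  xp <- c(rep(x[1L], m), x, rep(x[length(x)], m))
  as.numeric(stats::filter(xp, rep(1 / L, L), sides = 2L))[(m + 1L):(m + length(x))]
}

#' Draw a polyline onto an image
#'
#' Sets the pixels of a column-indexed polyline (one row per column, as in
#' trace ground truth) to a given color, filling vertical gaps between
#' consecutive columns so the drawn curve is 8-connected. Used by the
#' renderer and by fixtures that paint known traces onto a page.
#'
#' @param image PaperImage or H x W x 3 array.
#' @param cols,rows integer pixel coordinates (1-based; equal length).
#' @param color length-3 RGB in 0..255.
#' @param fill_gaps fill vertical jumps between consecutive columns.
#' @param gap_color color for gap-fill pixels (defaults to `color`).
#' @return image of the same class as the input.
#' @export
drawPolyline <- function(image, cols, rows, color = c(0, 0, 0),
                         fill_gaps = TRUE, gap_color = NULL) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  cols <- as.integer(round(cols)); rows <- as.integer(round(rows))
  keep <- cols >= 1L & cols <= W & rows >= 1L & rows <= H
  cols <- cols[keep]; rows <- rows[keep]
  if (is.null(gap_color)) gap_color <- color
  if (fill_gaps && length(cols) > 1L) {
    # vertical jumps are filled in the trailing column, through the next
    # column's row, so the drawn curve is 4-connected (required by the
    # 4-connectivity component analysis downstream)
    gc_ <- integer(0); gr_ <- integer(0)
    dy <- diff(rows); dx <- diff(cols)
    for (i in which(abs(dy) >= 1L & dx == 1L)) {
      span <- if (dy[i] > 0) (rows[i] + 1L):rows[i + 1L]
              else (rows[i] - 1L):rows[i + 1L]
      gr_ <- c(gr_, span); gc_ <- c(gc_, rep(cols[i], length(span)))
    }
    if (length(gc_)) {
      for (ch in 1:3) px[cbind(gr_, gc_, ch)] <- gap_color[ch]
    }
  }
  for (ch in 1:3) px[cbind(rows, cols, ch)] <- color[ch]
  rewrap(image, px, "drawPolyline", list(n = length(cols)))
}

# Rasterize straight segments (x0,y0)-(x1,y1) with a thickness; returns a
# logical H x W mask. Used by the stroke-font renderer and crease lines.
rasterSegments <- function(H, W, x0, y0, x1, y1, thickness = 1) {
  mask <- matrix(FALSE, H, W)
  half <- max(0, (thickness - 1) / 2)
  for (i in seq_along(x0)) {
    len <- sqrt((x1[i] - x0[i])^2 + (y1[i] - y0[i])^2)
    n <- max(2L, ceiling(len * 2) + 1L)
    xs <- seq(x0[i], x1[i], length.out = n)
    ys <- seq(y0[i], y1[i], length.out = n)
    for (dx in seq(-half, half, by = if (half > 0) 0.5 else 1)) {
      for (dy in seq(-half, half, by = if (half > 0) 0.5 else 1)) {
        cc <- round(xs + dx); rr <- round(ys + dy)
        ok <- cc >= 1 & cc <= W & rr >= 1 & rr <= H
        mask[cbind(rr[ok], cc[ok])] <- TRUE
      }
    }
  }
  mask
}

# Paint a logical mask onto an image in a given color.
paintMask <- function(image, mask, color) {
  px <- asPixelArray(image)
  idx <- which(mask)
  if (length(idx)) {
    H <- dim(px)[1L]; W <- dim(px)[2L]
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[idx] <- color[ch]
      px[, , ch] <- plane
    }
  }
  rewrap(image, px)
}

#' Read/write a PaperImage as PNG
#'
#' Thin wrappers over the png package keeping the 0..255 convention and the
#' DPI tag of [PaperImage-class].
#'
#' @param image PaperImage.
#' @param path file path.
#' @return `writeImagePNG` returns the path invisibly; `readImagePNG`
#'   returns a PaperImage (DPI from the PNG metadata when present).
#' @export
writeImagePNG <- function(image, path) {
  px <- asPixelArray(image) / 255
  dpi <- if (methods::is(image, "PaperImage")) image@dpi else NA_real_
  if (is.finite(dpi)) png::writePNG(px, path, dpi = dpi)
  else png::writePNG(px, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  px <- png::readPNG(path, info = TRUE)
  info <- attr(px, "info")
  dpi <- if (!is.null(info$dpi)) mean(info$dpi) else NA_real_
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE] * 255
  PaperImage(px, dpi = dpi)
}
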