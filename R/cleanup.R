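# Text removal (fast-marching style inpainting) and grid removal
# (residual denoiser or classical color suppression).

#' Inpaint masked pixels by first-order extrapolation
#'
#' Fast-marching-style scheme: masked pixels are filled in increasing
#' order of their distance to the known region; each pixel is estimated
#' from its already-known 8-neighbors by the distance-weighted first-order
#' approximation `I_q(p) = I(q) + grad I(q) . (p - q)` (gradients by
#' central differences over known pixels). Unmasked pixels are untouched;
#' the scheme is exact on linear intensity ramps up to discretization.
#'
#' @param image image or [PaperImage-class].
#' @param mask logical H x W matrix; TRUE marks pixels to fill.
#' @return image of the same class as the input.
#' @export
inpaintImage <- function(image, mask) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  mask <- matrix(as.logical(mask), H, W)
  if (!any(mask)) return(rewrap(image, px))
  if (all(mask)) stop("mask covers the entire image")
  dist <- as.matrix(EBImage::distmap(mask * 1))
  known <- !mask
  targets <- which(mask)
  targets <- targets[order(dist[targets])]
  ch1 <- px[, , 1L]; ch2 <- px[, , 2L]; ch3 <- px[, , 3L]
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (p in targets) {
    r <- ((p - 1L) %% H) + 1L
    c <- ((p - 1L) %/% H) + 1L
    sw <- 0; acc <- c(0, 0, 0)
    for (k in seq_len(nrow(nb))) {
      qr <- r + nb$dr[k]; qc <- c + nb$dc[k]
      if (qr < 1L || qr > H || qc < 1L || qc > W || !known[qr, qc]) next
      w <- 1 / (nb$dr[k]^2 + nb$dc[k]^2)
      # gradients at q over known pixels: central differences where both
      # neighbors are known, one-sided otherwise (still exact on linear
      # ramps), zero when no neighbor is known
      gx1 <- gx2 <- gx3 <- gy1 <- gy2 <- gy3 <- 0
      left_ok <- qc > 1L && known[qr, qc - 1L]
      right_ok <- qc < W && known[qr, qc + 1L]
      if (left_ok && right_ok) {
        gx1 <- (ch1[qr, qc + 1L] - ch1[qr, qc - 1L]) / 2
        gx2 <- (ch2[qr, qc + 1L] - ch2[qr, qc - 1L]) / 2
        gx3 <- (ch3[qr, qc + 1L] - ch3[qr, qc - 1L]) / 2
      } else if (right_ok) {
        gx1 <- ch1[qr, qc + 1L] - ch1[qr, qc]
        gx2 <- ch2[qr, qc + 1L] - ch2[qr, qc]
        gx3 <- ch3[qr, qc + 1L] - ch3[qr, qc]
      } else if (left_ok) {
        gx1 <- ch1[qr, qc] - ch1[qr, qc - 1L]
        gx2 <- ch2[qr, qc] - ch2[qr, qc - 1L]
        gx3 <- ch3[qr, qc] - ch3[qr, qc - 1L]
      }
      up_ok <- qr > 1L && known[qr - 1L, qc]
      dn_ok <- qr < H && known[qr + 1L, qc]
      if (up_ok && dn_ok) {
        gy1 <- (ch1[qr + 1L, qc] - ch1[qr - 1L, qc]) / 2
        gy2 <- (ch2[qr + 1L, qc] - ch2[qr - 1L, qc]) / 2
        gy3 <- (ch3[qr + 1L, qc] - ch3[qr - 1L, qc]) / 2
      } else if (dn_ok) {
        gy1 <- ch1[qr + 1L, qc] - ch1[qr, qc]
        gy2 <- ch2[qr + 1L, qc] - ch2[qr, qc]
        gy3 <- ch3[qr + 1L, qc] - ch3[qr, qc]
      } else if (up_ok) {
        gy1 <- ch1[qr, qc] - ch1[qr - 1L, qc]
        gy2 <- ch2[qr, qc] - ch2[qr - 1L, qc]
        gy3 <- ch3[qr, qc] - ch3[qr - 1L, qc]
      }
      dcq <- c - qc; drq <- r - qr
      acc <- acc + w * c(ch1[qr, qc] + gx1 * dcq + gy1 * drq,
                         ch2[qr, qc] + gx2 * dcq + gy2 * drq,
                         ch3[qr, qc] + gx3 * dcq + gy3 * drq)
      sw <- sw + w
    }
    if (sw > 0) {
      v <- clamp(acc / sw, 0, 255)
      ch1[r, c] <- v[1L]; ch2[r, c] <- v[2L]; ch3[r, c] <- v[3L]
      known[r, c] <- TRUE
    }
  }
  px[, , 1L] <- ch1; px[, , 2L] <- ch2; px[, , 3L] <- ch3
  rewrap(image, px, "inpaintImage", list(n_masked = length(targets)))
}

# square dilation of a logical mask by radius d (shift-OR)
dilateMask <- function(mask, d) {
  if (d <= 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0 && dc == 0) next
    rs <- max(1L, 1L + dr):min(H, H + dr)
    rt <- max(1L, 1L - dr):min(H, H - dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    ct <- max(1L, 1L - dc):min(W, W - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

#' Build a text mask for inpainting
#'
#' In synthetic mode the union of the overlay ink masks (dilated by a small
#' radius) is the ground-truth text mask; alternatively a pluggable
#' detector returning bounding boxes `(x1, y1, x2, y2)` can be supplied.
#'
#' @param image image or [PaperImage-class] (sets the mask size).
#' @param overlays list of logical H x W ink masks (may be empty).
#' @param detector function(image) returning an `n x 4` box matrix.
#' @param dilation dilation radius in px (default 2).
#' @return logical H x W mask.
#' @export
makeTextMask <- function(image, overlays = NULL, detector = NULL,
                         dilation = 2) {
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  if (is.null(overlays) && is.null(detector))
    stop("either overlays or a detector must be supplied")
  mask <- matrix(FALSE, H, W)
  if (!is.null(overlays))
    for (m in overlays) mask <- mask | matrix(as.logical(m), H, W)
  if (!is.null(detector)) {
    boxes <- detector(image)
    if (length(boxes)) {
      boxes <- matrix(round(boxes), ncol = 4L)
      for (i in seq_len(nrow(boxes))) {
        x1 <- clamp(boxes[i, 1L], 1, W); y1 <- clamp(boxes[i, 2L], 1, H)
        x2 <- clamp(boxes[i, 3L], 1, W); y2 <- clamp(boxes[i, 4L], 1, H)
        mask[y1:y2, x1:x2] <- TRUE
      }
    }
  }
  dilateMask(mask, dilation)
}

PATCH_SIZE <- 30L
PATCH_OVERLAP <- 5L

# tile origins with stride (patch - overlap); final tile re-anchored flush
# with the image edge so coverage is complete
patchOrigins <- function(total, patch = PATCH_SIZE,
                         overlap = PATCH_OVERLAP) {
  stride <- patch - overlap
  s <- seq(1L, max(1L, total - patch + 1L), by = stride)
  if (s[length(s)] + patch - 1L < total) s <- c(s, total - patch + 1L)
  s
}

#' Split a channel into overlapping patches / stitch them back
#'
#' `patchify` cuts a single-channel image into 30 x 30 tiles with 5 px
#' overlap (edge tiles flush with the border), scaled to `[0, 1]`.
#' `stitchPatches` reassembles a patch set with exponential
#' distance-weighted blending: the weight of a pixel within a patch is
#' `exp(-d / tau)` with `d` the Euclidean distance to the patch center
#' (`tau = 5`, the overlap width), normalized across covering patches, so
#' unmodified patches stitch back to the original exactly.
#'
#' @param channel numeric matrix (intensities 0..255 or 0..1).
#' @param patchset list from `patchify`.
#' @param tau weighting decay in px.
#' @return `patchify`: list of class `"PatchSet"` with `patches`
#'   (`30 x 30 x K` array in `[0, 1]`), `origins` (K x 2, row/col),
#'   `image_shape` and `scale`; `stitchPatches`: the reassembled matrix on
#'   the original intensity scale.
#' @export
patchify <- function(channel) {
  channel <- as.matrix(channel)
  H <- nrow(channel); W <- ncol(channel)
  if (H < PATCH_SIZE || W < PATCH_SIZE)
    stop("image smaller than the patch size")
  scale <- if (max(channel) > 1.5) 255 else 1
  rs <- patchOrigins(H); cs <- patchOrigins(W)
  K <- length(rs) * length(cs)
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, K))
  origins <- matrix(0L, K, 2L)
  k <- 0L
  for (r in rs) for (cc in cs) {
    k <- k + 1L
    patches[, , k] <- channel[r:(r + PATCH_SIZE - 1L),
                              cc:(cc + PATCH_SIZE - 1L)] / scale
    origins[k, ] <- c(r, cc)
  }
  structure(list(patches = patches, origins = origins,
                 image_shape = c(H, W), scale = scale),
            class = "PatchSet")
}

#' @rdname patchify
#' @export
stitchPatches <- function(patchset, tau = 5) {
  stopifnot(inherits(patchset, "PatchSet"))
  H <- patchset$image_shape[1L]; W <- patchset$image_shape[2L]
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  ctr <- (PATCH_SIZE + 1) / 2
  dg <- sqrt(outer((seq_len(PATCH_SIZE) - ctr)^2,
                   (seq_len(PATCH_SIZE) - ctr)^2, `+`))
  wpatch <- exp(-dg / tau)
  for (k in seq_len(dim(patchset$patches)[3L])) {
    r <- patchset$origins[k, 1L]; cc <- patchset$origins[k, 2L]
    ri <- r:(r + PATCH_SIZE - 1L); ci <- cc:(cc + PATCH_SIZE - 1L)
    acc[ri, ci] <- acc[ri, ci] + wpatch * patchset$patches[, , k]
    wsum[ri, ci] <- wsum[ri, ci] + wpatch
  }
  acc / wsum * patchset$scale
}

# classical grid suppression: pixels whose color matches the (reddish)
# grid are replaced by the background estimate
gridColorMask <- function(px, redness_min = 25, value_min = 90) {
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  (r - pmax(g, b) > redness_min) & (r > value_min)
}

#' Remove the background grid
#'
#' Residual-denoiser route: each RGB channel is patchified (30 x 30, 5 px
#' overlap, scaled to 0..1), the trained model predicts the grid residual
#' per patch, the residual is subtracted and patches are stitched with
#' exponential distance weighting. Classical route: pixels whose color
#' matches the configured grid hue are suppressed and replaced by the
#' background (optionally smoothed by inpainting).
#'
#' @param image image or [PaperImage-class].
#' @param model trained `"ECGDenoiser"` (for `method = "dncnn"`).
#' @param method `"dncnn"` or `"classical"`.
#' @param redness_min classical route: minimum red excess (R - max(G, B))
#'   identifying grid ink.
#' @param background RGB used to fill suppressed grid pixels.
#' @param inpaint_edges classical route: inpaint suppressed pixels adjacent
#'   to dark trace ink instead of flat-filling them.
#' @return image of the same class as the input.
#' @export
removeGrid <- function(image, model = NULL,
                       method = c("dncnn", "classical"),
                       redness_min = 25, background = c(255, 255, 255),
                       inpaint_edges = FALSE) {
  method <- match.arg(method)
  px <- asPixelArray(image)
  if (method == "dncnn") {
    if (is.null(model)) stop("no model supplied for the denoiser route")
    for (ch in 1:3) {
      ps <- patchify(px[, , ch])
      res <- predictResidual(model, ps$patches)
      ps$patches <- clamp(ps$patches - res, 0, 1)
      px[, , ch] <- clamp(stitchPatches(ps), 0, 255)
    }
  } else {
    if (is.null(redness_min)) stop("no grid color configured")
    mask <- gridColorMask(px, redness_min = redness_min)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- background[ch]
      px[, , ch] <- plane
    }
    if (inpaint_edges && any(mask)) {
      gray <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
      near_dark <- dilateMask(gray < 128, 1L) & mask
      if (any(near_dark)) px <- asPixelArray(inpaintImage(px, near_dark))
    }
  }
  rewrap(image, px, "removeGrid", list(method = method))
}
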