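# Physical and imaging degradations: creases, quilted wrinkle textures,
# affine/projective viewpoint changes, pixel noise, color temperature.

#' (Possibly off-center) normalized Gaussian kernel
#'
#' Evaluates `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)` at
#' integer offsets relative to the kernel center displaced by `offset`,
#' then normalizes to sum 1. Displacing the center yields the asymmetric
#' blur used to mimic light reflecting off a paper fold at an angle.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param L_k odd kernel side length (>= 3).
#' @param offset `(dx, dy)` displacement of the kernel center in pixels;
#'   each component must be smaller than `L_k/2` in magnitude.
#' @return `L_k x L_k` matrix summing to 1.
#' @export
gaussianKernel <- function(sigma, L_k, offset = c(0, 0)) {
  stopifnotScalar(sigma, "sigma", positive = TRUE)
  if (L_k %% 2 != 1 || L_k < 3) stop("L_k must be odd and >= 3")
  if (any(abs(offset) >= L_k / 2)) stop("offset components must be < L_k/2")
  ctr <- (L_k + 1) / 2
  x <- matrix(rep(seq_len(L_k) - ctr - offset[1L], each = L_k), L_k)
  y <- matrix(rep(seq_len(L_k) - ctr - offset[2L], times = L_k), L_k)
  k <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  k / sum(k)
}

#' Crease specification
#'
#' @param n_creases number of fold lines.
#' @param angle_deg inclination of the lines (90 = vertical).
#' @param sigma Gaussian blur std in px.
#' @param kernel_size odd blur kernel side (>= 3).
#' @param kernel_offset `(dx, dy)` kernel center displacement.
#' @param intensity line darkness in `[0, 1]`.
#' @param seed integer seed.
#' @return validated list of class `"CreaseSpec"`.
#' @export
creaseSpec <- function(n_creases = 2, angle_deg = 80, sigma = 2,
                       kernel_size = 9, kernel_offset = c(0, 0),
                       intensity = 0.35, seed = 1) {
  if (kernel_size %% 2 != 1 || kernel_size < 3)
    stop("kernel_size must be odd and >= 3")
  stopifnotScalar(sigma, "sigma", positive = TRUE)
  if (any(abs(kernel_offset) >= kernel_size / 2))
    stop("kernel_offset components must be < kernel_size/2")
  if (intensity < 0 || intensity > 1) stop("intensity must lie in [0, 1]")
  structure(list(n_creases = as.integer(n_creases), angle_deg = angle_deg,
                 sigma = sigma, kernel_size = kernel_size,
                 kernel_offset = kernel_offset, intensity = intensity,
                 seed = seed),
            class = "CreaseSpec")
}

#' Apply crease (paper fold) artifacts
#'
#' Draws `n_creases` parallel lines at the given inclination, spaced at the
#' quantile translations of the line family across the image extent,
#' darkens them by `intensity`, and blurs the darkening layer with the
#' (possibly off-center) Gaussian kernel. Pixels outside the blurred line
#' neighborhoods are untouched.
#'
#' @param image image or [PaperImage-class].
#' @param spec [creaseSpec()] result; `n_creases = 0` is the identity.
#' @return image of the same class as the input.
#' @export
applyCreases <- function(image, spec) {
  stopifnot(inherits(spec, "CreaseSpec"))
  px <- asPixelArray(image)
  if (spec$n_creases == 0L) return(rewrap(image, px))
  H <- dim(px)[1L]; W <- dim(px)[2L]
  th <- spec$angle_deg * pi / 180
  dvec <- c(cos(th), sin(th))     # line direction (x, y)
  nvec <- c(-sin(th), cos(th))    # unit normal
  corners <- cbind(x = c(1, W, 1, W), y = c(1, 1, H, H))
  proj <- corners %*% nvec
  qs <- (seq_len(spec$n_creases)) / (spec$n_creases + 1)
  offsets <- min(proj) + qs * (max(proj) - min(proj))
  center <- c((1 + W) / 2, (1 + H) / 2)
  c0 <- sum(center * nvec)
  ext <- sqrt(H^2 + W^2)
  layer <- matrix(0, H, W)
  for (o in offsets) {
    p0 <- center + (o - c0) * nvec
    a <- p0 - ext * dvec; b <- p0 + ext * dvec
    m <- rasterSegments(H, W, a[1L], a[2L], b[1L], b[2L], thickness = 1)
    layer[m] <- spec$intensity
  }
  k <- gaussianKernel(spec$sigma, spec$kernel_size, spec$kernel_offset)
  layer_b <- EBImage::filter2(layer, k, boundary = "replicate")
  layer_b <- clamp(layer_b, 0, 1)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - layer_b)
  rewrap(image, px, "applyCreases",
         list(n = spec$n_creases, angle = spec$angle_deg,
              intensity = spec$intensity))
}

#' Minimum-error boundary cut
#'
#' Dynamic-programming seam through a non-negative error surface: the
#' cumulative cost is `E[i, j] = e[i, j] + min(E[i-1, j-1], E[i-1, j],
#' E[i-1, j+1])` with out-of-range predecessors treated as `+Inf`;
#' backtracking from the last row yields the 8-connected minimal path.
#' Ties pick the leftmost minimal predecessor, making the path
#' deterministic.
#'
#' @param e numeric matrix `N x M`, `e >= 0`.
#' @return list with `path` (one column index per row, 1-based) and `cost`
#'   (summed `e` along the path, the global minimum over all such paths).
#' @export
minErrorBoundaryCut <- function(e) {
  e <- as.matrix(e)
  if (!length(e)) stop("empty error surface")
  if (any(e < 0)) stop("error surface must be non-negative")
  N <- nrow(e); M <- ncol(e)
  E <- matrix(Inf, N, M)
  E[1L, ] <- e[1L, ]
  if (N > 1L) for (i in 2:N) {
    prev <- E[i - 1L, ]
    left <- c(Inf, prev[-M]); right <- c(prev[-1L], Inf)
    E[i, ] <- e[i, ] + pmin(left, prev, right)
  }
  j <- which.min(E[N, ])
  path <- integer(N)
  path[N] <- j
  if (N > 1L) for (i in (N - 1L):1L) {
    cand <- (path[i + 1L] - 1L):(path[i + 1L] + 1L)
    cand <- cand[cand >= 1L & cand <= M]
    path[i] <- cand[which.min(E[i, cand])]
  }
  list(path = path, cost = sum(e[cbind(seq_len(N), path)]))
}

#' Quilting specification
#'
#' @param seed_texture grayscale matrix (wrinkle seed image).
#' @param patch patch side in px.
#' @param overlap overlap in px, `0 < overlap < patch` (default `patch/6`).
#' @param out_size `(H, W)` of the synthesized texture.
#' @param blend_alpha wrinkle opacity used later by [applyWrinkles()].
#' @param seed integer seed.
#' @return validated list of class `"QuiltSpec"`.
#' @export
quiltSpec <- function(seed_texture, patch = 48, overlap = NULL,
                      out_size = c(256, 256), blend_alpha = 0.5, seed = 1) {
  seed_texture <- as.matrix(seed_texture)
  if (is.null(overlap)) overlap <- max(1L, round(patch / 6))
  if (overlap <= 0 || overlap >= patch)
    stop("overlap must satisfy 0 < overlap < patch")
  if (any(dim(seed_texture) < patch))
    stop("patch larger than seed texture")
  structure(list(seed_texture = seed_texture, patch = as.integer(patch),
                 overlap = as.integer(overlap),
                 out_size = as.integer(out_size),
                 blend_alpha = blend_alpha, seed = seed),
            class = "QuiltSpec")
}

#' Synthesize a wrinkle texture by image quilting
#'
#' Places randomly drawn seed-texture patches in raster-scan order with the
#' configured overlap; each seam follows the [minErrorBoundaryCut()] of the
#' squared-difference error surface between the overlapping regions
#' (vertical and horizontal cuts combined on L-shaped corner overlaps).
#' Deterministic per seed.
#'
#' @param spec [quiltSpec()] result.
#' @return numeric matrix of size `out_size`.
#' @export
quiltTexture <- function(spec) {
  stopifnot(inherits(spec, "QuiltSpec"))
  tex <- spec$seed_texture
  p <- spec$patch; ov <- spec$overlap
  H <- spec$out_size[1L]; W <- spec$out_size[2L]
  stride <- p - ov
  starts <- function(total) {
    s <- seq(1L, max(1L, total - p + 1L), by = stride)
    if (s[length(s)] + p - 1L < total) s <- c(s, total - p + 1L)
    s
  }
  rs_all <- starts(H); cs_all <- starts(W)
  out <- matrix(0, H, W)
  withSeed(spec$seed, {
    for (rs in rs_all) for (cs in cs_all) {
      pr <- sample.int(nrow(tex) - p + 1L, 1L)
      pc <- sample.int(ncol(tex) - p + 1L, 1L)
      patch <- tex[pr:(pr + p - 1L), pc:(pc + p - 1L)]
      re <- rs + p - 1L; ce <- cs + p - 1L
      keep_new <- matrix(TRUE, p, p)
      if (cs > 1L) {  # vertical seam against what is already placed
        e <- (out[rs:re, cs:(cs + ov - 1L)] - patch[, seq_len(ov)])^2
        cut <- minErrorBoundaryCut(e)$path
        for (i in seq_len(p))
          if (cut[i] > 1L) keep_new[i, seq_len(cut[i] - 1L)] <- FALSE
      }
      if (rs > 1L) {  # horizontal seam
        e <- (out[rs:(rs + ov - 1L), cs:ce] - patch[seq_len(ov), ])^2
        cut <- minErrorBoundaryCut(t(e))$path
        for (j in seq_len(p))
          if (cut[j] > 1L) keep_new[seq_len(cut[j] - 1L), j] <- FALSE
      }
      block <- out[rs:re, cs:ce]
      block[keep_new] <- patch[keep_new]
      out[rs:re, cs:ce] <- block
    }
  })
  out
}

#' Synthetic wrinkle seed texture
#'
#' Procedurally generated stand-in for a scanned plain-wrinkle photograph:
#' a smoothed random luminance field with directional streaks, mean ~128.
#' Synthetic by construction; used as the default quilting seed.
#'
#' @param size `(H, W)` of the texture.
#' @param seed integer seed.
#' @param streak_angle_deg dominant wrinkle direction.
#' @return numeric matrix in [0, 255].
#' @export
wrinkleSeedTexture <- function(size = c(160, 160), seed = 7,
                               streak_angle_deg = 25) {
  withSeed(seed, {
    H <- size[1L]; W <- size[2L]
    base <- matrix(stats::rnorm(H * W), H, W)
    k <- gaussianKernel(4, 17)
    sm <- EBImage::filter2(base, k, boundary = "circular")
    th <- streak_angle_deg * pi / 180
    # anisotropic second pass: elongated kernel along the streak direction
    L <- 21; ctr <- (L + 1) / 2
    xx <- matrix(rep(seq_len(L) - ctr, each = L), L)
    yy <- matrix(rep(seq_len(L) - ctr, times = L), L)
    u <- xx * cos(th) + yy * sin(th); v <- -xx * sin(th) + yy * cos(th)
    ak <- exp(-(u^2 / (2 * 7^2) + v^2 / (2 * 1.5^2)))
    ak <- ak / sum(ak)
    streaks <- EBImage::filter2(base, ak, boundary = "circular")
    f <- sm + 1.5 * streaks
    f <- (f - mean(f)) / stats::sd(f)
    clamp(128 + 35 * f, 0, 255)
  })
}

#' Blend a wrinkle texture into an image
#'
#' Multiplicative luminance blend:
#' `out = image * (1 - alpha + alpha * texture / mean(texture))`, clipped to
#' `[0, 255]`. The texture is bilinearly resized to the image size when the
#' dimensions differ. A constant texture is an identity for any alpha.
#'
#' @param image image or [PaperImage-class].
#' @param texture grayscale matrix (e.g. from [quiltTexture()]).
#' @param blend_alpha opacity in `[0, 1]`.
#' @return image of the same class as the input.
#' @export
applyWrinkles <- function(image, texture, blend_alpha = 0.5) {
  if (blend_alpha < 0 || blend_alpha > 1)
    stop("blend_alpha must lie in [0, 1]")
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  texture <- as.matrix(texture)
  if (!all(dim(texture) == c(H, W))) {
    rr <- (seq_len(H) - 0.5) / H * nrow(texture) + 0.5
    cc <- (seq_len(W) - 0.5) / W * ncol(texture) + 0.5
    texture <- matrix(
      bilinearSample(texture, rep(rr, times = W), rep(cc, each = H),
                     fill = mean(texture)), H, W)
  }
  gainm <- 1 - blend_alpha + blend_alpha * texture / mean(texture)
  for (ch in 1:3) px[, , ch] <- clamp(px[, , ch] * gainm, 0, 255)
  rewrap(image, px, "applyWrinkles", list(alpha = blend_alpha))
}

#' Projective transform specification
#'
#' @param matrix invertible 3x3 real matrix `(a b c; d e f; g h i)` acting
#'   on homogeneous pixel coordinates `(x, y, 1)` (x = column, y = row);
#'   normalized so `i = 1` when `i != 0`. The affine case has `g = h = 0`.
#' @return validated list of class `"ProjectiveSpec"`.
#' @export
projectiveSpec <- function(matrix) {
  m <- matrix
  if (!is.matrix(m)) m <- base::matrix(as.numeric(m), 3L, 3L, byrow = TRUE)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(3L, 3L))) stop("transform matrix must be 3x3")
  if (abs(det(m)) < 1e-12) stop("singular transform matrix")
  if (m[3L, 3L] != 0) m <- m / m[3L, 3L]
  structure(list(matrix = m, affine = all(m[3L, 1:2] == 0)),
            class = "ProjectiveSpec")
}

applyHomography <- function(m, x, y) {
  w <- m[3L, 1L] * x + m[3L, 2L] * y + m[3L, 3L]
  list(x = (m[1L, 1L] * x + m[1L, 2L] * y + m[1L, 3L]) / w,
       y = (m[2L, 1L] * x + m[2L, 2L] * y + m[2L, 3L]) / w)
}

#' Apply a projective (or affine) transform to image and ground truth
#'
#' Pixels are inverse-warped with bilinear sampling (out-of-source pixels
#' filled with a background color); ground-truth polylines are mapped by the
#' forward matrix with homogeneous division. The affine special case
#' preserves parallel lines.
#'
#' @param image image or [PaperImage-class].
#' @param spec [projectiveSpec()] or a 3x3 matrix.
#' @param ground_truth optional [GroundTruth-class] to transform alongside.
#' @param fill background RGB for unmapped pixels.
#' @return list with `image` and (when supplied) `truth` whose polyline
#'   coordinates are real-valued after the mapping.
#' @export
projectiveTransform <- function(image, spec, ground_truth = NULL,
                                fill = c(255, 255, 255)) {
  if (is.matrix(spec)) spec <- projectiveSpec(spec)
  stopifnot(inherits(spec, "ProjectiveSpec"))
  px <- asPixelArray(image)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  minv <- solve(spec$matrix)
  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), times = W)
  src <- applyHomography(minv, xs, ys)
  out <- array(0, dim = dim(px))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinearSample(px[, , ch], src$y, src$x,
                                         fill = fill[ch]), H, W)
  img_out <- rewrap(image, out, "projectiveTransform",
                    list(matrix = spec$matrix))
  truth_out <- NULL
  if (!is.null(ground_truth)) {
    segs <- lapply(gtSegments(ground_truth), function(s) {
      fwd <- applyHomography(spec$matrix, s$cols, s$rows)
      base <- applyHomography(spec$matrix, s$cols[1L], s$baseline_row)
      s$cols <- fwd$x; s$rows <- fwd$y
      s$baseline_row <- base$y
      s
    })
    truth_out <- GroundTruth(segs)
  }
  if (is.null(ground_truth)) list(image = img_out)
  else list(image = img_out, truth = truth_out)
}

#' Imaging noise
#'
#' Per-pixel noise models of scanned/photographed documents: additive
#' Gaussian sensor noise, additive Poisson shot noise (both clipped to
#' `[0, 255]`), and salt-and-pepper sensor malfunctions that set a pixel
#' (all three channels jointly) to 0 or 255 with probability `p/2` each.
#'
#' @param image image or [PaperImage-class].
#' @param eta Gaussian std in intensity units (>= 0).
#' @param lambda Poisson rate (>= 0).
#' @param p salt-and-pepper density in `[0, 1]`.
#' @param seed integer seed.
#' @return image of the same class as the input.
#' @export
addGaussianNoise <- function(image, eta, seed = 1) {
  if (eta < 0) stop("eta must be non-negative")
  px <- asPixelArray(image)
  if (eta == 0) return(rewrap(image, px))
  withSeed(seed, {
    px <- clamp(px + array(stats::rnorm(length(px), 0, eta), dim = dim(px)),
                0, 255)
  })
  rewrap(image, px, "addGaussianNoise", list(eta = eta, seed = seed))
}

#' @rdname addGaussianNoise
#' @export
addPoissonNoise <- function(image, lambda, seed = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  px <- asPixelArray(image)
  if (lambda == 0) return(rewrap(image, px))
  withSeed(seed, {
    px <- clamp(px + array(stats::rpois(length(px), lambda), dim = dim(px)),
                0, 255)
  })
  rewrap(image, px, "addPoissonNoise", list(lambda = lambda, seed = seed))
}

#' @rdname addGaussianNoise
#' @export
addSaltPepperNoise <- function(image, p, seed = 1) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  px <- asPixelArray(image)
  if (p == 0) return(rewrap(image, px))
  H <- dim(px)[1L]; W <- dim(px)[2L]
  withSeed(seed, {
    u <- matrix(stats::runif(H * W), H, W)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[u < p / 2] <- 0
      plane[u >= p / 2 & u < p] <- 255
      px[, , ch] <- plane
    }
  })
  rewrap(image, px, "addSaltPepperNoise", list(p = p, seed = seed))
}

# Blackbody color approximation (piecewise log fits over K/100).
kelvinToRGB <- function(K) {
  t <- K / 100
  r <- if (t <= 66) 255 else 329.698727446 * (t - 60)^-0.1332047592
  g <- if (t <= 66) 99.4708025861 * log(t) - 161.1195681661
       else 288.1221695283 * (t - 60)^-0.0755148492
  b <- if (t >= 66) 255
       else if (t <= 19) 0
       else 138.5177312231 * log(t - 10) - 305.0447927307
  clamp(c(r, g, b), 0, 255)
}

#' Shift the color temperature of an image
#'
#' Scales the RGB channels by a blackbody-approximation white point,
#' normalized so 6600 K is the identity; lower temperatures push an orange
#' tinge, higher ones a blue tinge, mimicking aged or re-photographed
#' thermal paper.
#'
#' @param image image or [PaperImage-class].
#' @param K color temperature in Kelvin, 1000..40000.
#' @return image of the same class as the input.
#' @export
applyColorTemperature <- function(image, K) {
  if (K < 1000 || K > 40000) stop("K must lie in [1000, 40000]")
  px <- asPixelArray(image)
  wp <- kelvinToRGB(K) / kelvinToRGB(6600)
  for (ch in 1:3) px[, , ch] <- clamp(px[, , ch] * wp[ch], 0, 255)
  rewrap(image, px, "applyColorTemperature", list(K = K))
}

#' Distortion profile presets
#'
#' Named parameter bundles for the full degradation stack, applied in the
#' order creases, wrinkles, perspective, color temperature, Gaussian,
#' Poisson, salt-and-pepper.
#'
#' @param name `"clean"`, `"scanner"` or `"photo"`.
#' @return list of stage parameter lists (NULL stages are skipped).
#' @export
distortionProfile <- function(name = c("clean", "scanner", "photo")) {
  name <- match.arg(name)
  switch(name,
    clean = list(),
    scanner = list(
      creases = list(n_creases = 2, angle_deg = 85, sigma = 2,
                     kernel_size = 9, intensity = 0.25),
      wrinkles = list(blend_alpha = 0.25),
      color_temp = list(K = 5200),
      gaussian = list(eta = 4)),
    photo = list(
      creases = list(n_creases = 3, angle_deg = 70, sigma = 3,
                     kernel_size = 11, kernel_offset = c(1, 0),
                     intensity = 0.35),
      wrinkles = list(blend_alpha = 0.4),
      projective = list(matrix = rbind(c(1, 0.01, 4), c(-0.008, 1, 2),
                                       c(2e-5, 1e-5, 1))),
      color_temp = list(K = 4000),
      gaussian = list(eta = 6),
      poisson = list(lambda = 3),
      salt_pepper = list(p = 0.002)))
}

#' Apply a full distortion stack
#'
#' Convenience wrapper applying the configured stages in the canonical
#' order (creases, wrinkles, perspective, color temperature, Gaussian,
#' Poisson, salt-and-pepper); provenance records the realized order.
#'
#' @param image image or [PaperImage-class].
#' @param config list as returned by [distortionProfile()] (stage names:
#'   `creases`, `wrinkles`, `projective`, `color_temp`, `gaussian`,
#'   `poisson`, `salt_pepper`).
#' @param ground_truth optional [GroundTruth-class], transformed by the
#'   geometric stages.
#' @param seed integer seed shared by the stochastic stages.
#' @return list with `image` and `truth`.
#' @export
applyDistortionStack <- function(image, config, ground_truth = NULL,
                                 seed = 1) {
  truth <- ground_truth
  if (!is.null(config$creases)) {
    cs <- do.call(creaseSpec, c(config$creases, list(seed = seed)))
    image <- applyCreases(image, cs)
  }
  if (!is.null(config$wrinkles)) {
    w <- config$wrinkles
    tex <- if (!is.null(w$texture)) w$texture else {
      qs <- quiltSpec(wrinkleSeedTexture(seed = seed), patch = 48,
                      out_size = c(192, 192), seed = seed)
      quiltTexture(qs)
    }
    image <- applyWrinkles(image, tex, w$blend_alpha)
  }
  if (!is.null(config$projective)) {
    res <- projectiveTransform(image, projectiveSpec(config$projective$matrix),
                               ground_truth = truth)
    image <- res$image
    if (!is.null(truth)) truth <- res$truth
  }
  if (!is.null(config$color_temp))
    image <- applyColorTemperature(image, config$color_temp$K)
  if (!is.null(config$gaussian))
    image <- addGaussianNoise(image, config$gaussian$eta, seed = seed + 1)
  if (!is.null(config$poisson))
    image <- addPoissonNoise(image, config$poisson$lambda, seed = seed + 2)
  if (!is.null(config$salt_pepper))
    image <- addSaltPepperNoise(image, config$salt_pepper$p, seed = seed + 3)
  list(image = image, truth = truth)
}
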