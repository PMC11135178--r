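# Strip segmentation, trace extraction and conversion to physical units.

#' Detect lead strips from the row-intensity profile
#'
#' Computes the row-mean intensity profile `I(x)`, smooths it with a
#' non-causal moving average of order `L` (edge values replicated), finds
#' the significant minima (below the midpoint between global extremes,
#' merged when closer than `min_gap_px`), and splits the page at the local
#' maxima between consecutive minima. Dark trace rows produce the minima,
#' white separation regions the maxima.
#'
#' @param image grid/text-removed image (dark foreground) or
#'   [PaperImage-class].
#' @param L moving-average filter order (odd, default 11).
#' @param min_gap_px minimum distance between distinct strips (default
#'   5 mm at the image DPI, else 40 px).
#' @param min_depth minima must lie below
#'   `min + min_depth * (max - min)` of the smoothed profile.
#' @return list of `c(start, end)` row intervals, one per strip, with the
#'   smoothed profile attached as attribute `"profile"`.
#' @export
detectStrips <- function(image, L = 11, min_gap_px = NULL, min_depth = 0.5) {
  gray <- toGray(image)
  if (is.null(min_gap_px)) {
    dpi <- if (methods::is(image, "PaperImage")) imageDPI(image) else NA_real_
    min_gap_px <- if (is.finite(dpi)) round(mmToPx(5, dpi)) else 40
  }
  prof <- rowMeans(gray)
  sm <- movingAverage(prof, L)
  rng <- range(sm)
  if (diff(rng) < 1e-9) stop("no strips found: uniform profile")
  thr <- rng[1L] + min_depth * diff(rng)
  n <- length(sm)
  is_min <- c(FALSE, sm[2:(n - 1)] <= sm[1:(n - 2)] &
                sm[2:(n - 1)] <= sm[3:n], FALSE) & sm < thr
  cand <- which(is_min)
  if (!length(cand)) stop("no strips found")
  # merge minima closer than min_gap_px, keeping the deepest of each run
  groups <- cumsum(c(1, diff(cand) > min_gap_px))
  minima <- vapply(split(cand, groups),
                   function(ix) ix[which.min(sm[ix])], 0)
  minima <- sort(unname(minima))
  bounds <- integer(0)
  if (length(minima) > 1L)
    for (i in seq_len(length(minima) - 1L)) {
      seg <- (minima[i] + 1L):(minima[i + 1L] - 1L)
      bounds <- c(bounds, seg[which.max(sm[seg])])
    }
  edges <- c(1L, bounds, n)
  rois <- lapply(seq_along(minima),
                 function(i) c(edges[i], edges[i + 1L]))
  attr(rois, "profile") <- sm
  rois
}

#' Binarize a strip image
#'
#' Foreground = pixels darker than their 3 x 3 neighborhood mean minus an
#' offset, or darker than an absolute dark threshold (captures thick
#' strokes whose centers equal the local mean). `invert = TRUE` handles
#' light-foreground input.
#'
#' @param strip_image image, matrix or [PaperImage-class].
#' @param offset local-threshold offset in intensity units.
#' @param dark_abs absolute darkness threshold.
#' @param invert invert the contrast before thresholding.
#' @return logical H x W foreground mask.
#' @export
binarizeStrip <- function(strip_image, offset = 10, dark_abs = 100,
                          invert = FALSE) {
  gray <- if (is.matrix(strip_image)) strip_image else toGray(strip_image)
  if (invert) gray <- 255 - gray
  local_mean <- EBImage::filter2(gray, matrix(1 / 9, 3L, 3L),
                                 boundary = "replicate")
  (gray < local_mean - offset) | (gray < dark_abs)
}

# outer boundary pixels (4-neighbor touching background) of a label matrix
outerBoundary <- function(lab, id) {
  m <- lab == id
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  dn <- rbind(m[-1L, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -W, drop = FALSE])
  rt <- cbind(m[, -1L, drop = FALSE], FALSE)
  which(m & !(up & dn & lf & rt), arr.ind = TRUE)
}

# minimum separation between two outer-boundary point sets: the distance
# the fusion threshold is applied to. (The symmetric max-min Hausdorff
# distance of two long adjacent trace fragments is of the order of their
# length, so thresholding it would never fuse a broken trace; the
# separation of the outer pixels is the quantity that makes nearby
# fragments mergeable.)
boundarySeparation <- function(A, B) {
  out <- Inf
  step <- 2000L
  for (s in seq(1L, nrow(A), by = step)) {
    ix <- s:min(s + step - 1L, nrow(A))
    d2 <- outer(A[ix, 1L], B[, 1L], `-`)^2 +
      outer(A[ix, 2L], B[, 2L], `-`)^2
    out <- min(out, min(d2))
  }
  sqrt(out)
}

#' Connected-component analysis with size filtering and Hausdorff fusion
#'
#' 4-connected labeling of a binary mask; components failing the size
#' thresholds are discarded (area below `min_area`, above `max_area`, or
#' both height and width below their minima), then pairs of surviving
#' components whose outer-boundary pixel sets come within `fuse_dist` of
#' each other are merged (union-find over all close pairs, i.e. to a
#' fixpoint), re-joining traces broken by grid removal.
#'
#' @param mask logical matrix.
#' @param min_h,min_w minimum bounding-box height/width in px.
#' @param min_area,max_area area bounds in px.
#' @param fuse_dist Hausdorff fusion distance in px (0 disables fusion).
#' @return list of class `"ComponentSet"` with `labels` (integer matrix,
#'   0 = background), `components` (data.frame: id, area, h, w) and
#'   `boundaries` (outer-boundary pixel matrices per component).
#' @export
analyzeComponents <- function(mask, min_h = 3, min_w = 3, min_area = 10,
                              max_area = Inf, fuse_dist = 10) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  lab <- label_components_4(mask)
  K <- max(lab)
  if (K == 0L)
    return(structure(list(labels = lab,
                          components = data.frame(id = integer(0),
                                                  area = integer(0),
                                                  h = integer(0),
                                                  w = integer(0)),
                          boundaries = list()),
                     class = "ComponentSet"))
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  area <- tabulate(ids, K)
  hh <- tapply(idx[, 1L], ids, function(v) diff(range(v)) + 1L)
  ww <- tapply(idx[, 2L], ids, function(v) diff(range(v)) + 1L)
  keep <- which(area >= min_area & area <= max_area &
                  !(hh < min_h & ww < min_w))
  lab[!(lab %in% keep)] <- 0L
  # merge via union-find over Hausdorff-close pairs
  if (length(keep) > 1L && fuse_dist > 0) {
    bnd <- lapply(keep, function(id) outerBoundary(lab, id))
    names(bnd) <- keep
    parent <- stats::setNames(keep, keep)
    findRoot <- function(x) { while (parent[[as.character(x)]] != x)
      x <- parent[[as.character(x)]]; x }
    bbox <- lapply(keep, function(id) {
      b <- bnd[[as.character(id)]]
      c(min(b[, 1L]), max(b[, 1L]), min(b[, 2L]), max(b[, 2L]))
    })
    names(bbox) <- keep
    for (i in seq_along(keep)) for (j in seq_len(i - 1L)) {
      a <- keep[i]; b <- keep[j]
      ba <- bbox[[as.character(a)]]; bb <- bbox[[as.character(b)]]
      gap_r <- max(0, max(ba[1L], bb[1L]) - min(ba[2L], bb[2L]))
      gap_c <- max(0, max(ba[3L], bb[3L]) - min(ba[4L], bb[4L]))
      if (sqrt(gap_r^2 + gap_c^2) > fuse_dist) next
      d <- boundarySeparation(bnd[[as.character(a)]],
                              bnd[[as.character(b)]])
      if (d <= fuse_dist) {
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
      }
    }
    roots <- vapply(keep, findRoot, 0)
    remap <- stats::setNames(roots, keep)
    pos <- lab > 0L
    lab[pos] <- remap[as.character(lab[pos])]
    keep <- sort(unique(roots))
  }
  final_ids <- sort(unique(lab[lab > 0L]))
  comp <- data.frame(id = final_ids,
                     area = vapply(final_ids,
                                   function(id) sum(lab == id), 0L))
  comp$h <- vapply(final_ids, function(id) {
    r <- which(lab == id, arr.ind = TRUE)[, 1L]
    diff(range(r)) + 1L }, 0L)
  comp$w <- vapply(final_ids, function(id) {
    c <- which(lab == id, arr.ind = TRUE)[, 2L]
    diff(range(c)) + 1L }, 0L)
  boundaries <- lapply(final_ids, function(id) outerBoundary(lab, id))
  structure(list(labels = lab, components = comp, boundaries = boundaries),
            class = "ComponentSet")
}

#' Extract the trace as one row per column
#'
#' Renders the component mask as dark-foreground grayscale, blurs it with
#' a 1 x 3 horizontal mean filter to pull in neighborhood (time-axis)
#' context, and takes per column the darkest below-threshold pixel.
#' Ties go to the row closest to the previous column's choice (the trace
#' is continuous), then to the smallest row index. Columns with no
#' foreground are marked missing and linearly interpolated from their
#' neighbors.
#'
#' @param component_mask logical foreground mask, label matrix (> 0 =
#'   foreground), or dark-foreground grayscale matrix.
#' @param fg_threshold grayscale threshold below which a pixel counts as
#'   foreground candidate.
#' @return [ExtractedTrace-class] with `yHat` per column and the
#'   observed/interpolated flags (signal conversion is done by
#'   [toPhysicalUnits()]).
#' @export
extractTrace <- function(component_mask, fg_threshold = 128) {
  m <- as.matrix(component_mask)
  # logical masks and small-integer label matrices render as foreground 0 /
  # background 255; anything else is taken as dark-foreground grayscale
  gray <- if (is.logical(m) || (all(m == round(m)) && max(m) < 100 &&
                                min(m) >= 0 && max(m) >= 1))
    ifelse(m > 0, 0, 255) else m
  H <- nrow(gray); W <- ncol(gray)
  B <- (cbind(gray[, 1L], gray[, -W, drop = FALSE]) + gray +
          cbind(gray[, -1L, drop = FALSE], gray[, W])) / 3
  fg <- gray < fg_threshold
  y <- rep(NA_real_, W)
  prev <- NA_real_
  for (x in seq_len(W)) {
    cand <- which(fg[, x])
    if (!length(cand)) next
    b <- B[cand, x]
    tied <- cand[b <= min(b) + 1e-9]
    y[x] <- if (length(tied) > 1L && !is.na(prev))
      tied[which.min(abs(tied - prev))]  # continuity, then smallest row
    else tied[1L]
    prev <- y[x]
  }
  observed <- !is.na(y)
  if (!any(observed)) stop("no foreground in any column")
  if (any(!observed)) {
    obs_x <- which(observed)
    y <- stats::approx(obs_x, y[obs_x], xout = seq_len(W), rule = 2)$y
  }
  ExtractedTrace(yHat = y, observed = observed)
}

# subpixel autocorrelation peak via parabolic interpolation
acfPeakRefine <- function(ac, lag) {
  if (lag < 2L || lag > length(ac) - 1L) return(lag)
  a <- ac[lag - 1L]; b <- ac[lag]; cc <- ac[lag + 1L]
  den <- a - 2 * b + cc
  if (abs(den) < 1e-12) return(lag)
  lag + 0.5 * (a - cc) / den
}

profilePeriod <- function(prof, min_lag = 3L) {
  x <- prof - mean(prof)
  if (stats::sd(x) < 1e-9) return(NA_real_)
  n <- length(x)
  maxlag <- min(n - 2L, 600L)
  ac <- as.numeric(stats::acf(x, lag.max = maxlag, plot = FALSE,
                              demean = TRUE)$acf)[-1L]
  # first significant local maximum
  loc <- which(diff(sign(diff(ac))) == -2) + 1L
  loc <- loc[loc >= min_lag & ac[loc] > 0.15]
  if (!length(loc)) return(NA_real_)
  p1 <- loc[1L]
  p <- acfPeakRefine(ac, p1)
  # climb the harmonics: at each multiple, re-locate the peak near k*p and
  # update the fundamental, so the estimate cannot drift to a neighboring
  # harmonic while gaining subpixel precision at large lags
  k <- 1L
  repeat {
    k_next <- k + 1L
    target <- k_next * p
    if (target > maxlag - 2L) break
    lo <- max(min_lag, floor(target - p / 2))
    hi <- min(maxlag - 1L, ceiling(target + p / 2))
    if (hi <= lo) break
    sub <- lo:hi
    pk <- sub[which.max(ac[sub])]
    if (ac[pk] < 0.05) break
    p <- acfPeakRefine(ac, pk) / k_next
    k <- k_next
  }
  p
}

#' Estimate the grid pitch from an image
#'
#' Autocorrelation of the row- and column-mean intensity profiles yields
#' the fine (1 mm) grid period; the reported coarse pitch is five times
#' that. Subpixel accuracy comes from parabolic interpolation at a high
#' harmonic of the fundamental lag. Run this before grid removal.
#'
#' @param image image retaining the grid.
#' @return coarse grid pitch in px (5 mm equivalent).
#' @export
estimateGridPeriod <- function(image) {
  gray <- toGray(image)
  p_col <- profilePeriod(colMeans(gray))
  p_row <- profilePeriod(rowMeans(gray))
  ps <- c(p_col, p_row)
  ps <- ps[is.finite(ps)]
  if (!length(ps)) stop("no periodicity detected")
  # the two axes must agree; otherwise trust the stronger (column) axis
  fine <- if (length(ps) == 2L && abs(diff(ps)) / mean(ps) < 0.1)
    mean(ps) else ps[1L]
  5 * fine
}

#' Convert an extracted trace to physical units
#'
#' Applies the amplitude scaling factor `0.5 mV / coarse grid px` to the
#' baseline-relative pixel deviations and derives the image-implied
#' sampling frequency from the DPI (`fs = D / 1.016`) when trusted, else
#' from the grid pitch (`fs = coarse_px * paper_speed / 5` samples/s,
#' i.e. `coarse_px / 0.2` at the standard 25 mm/s).
#'
#' @param y_hat row index per column (or [ExtractedTrace-class]).
#' @param baseline_row baseline row; rows above it are positive mV.
#' @param coarse_grid_px coarse grid pitch in px (> 0).
#' @param D optional trusted DPI.
#' @param paper_speed paper speed in mm/s.
#' @return [ExtractedTrace-class] with `signalMv` and `fsImage` filled in.
#' @export
toPhysicalUnits <- function(y_hat, baseline_row, coarse_grid_px = NULL,
                            D = NULL, paper_speed = 25) {
  observed <- NULL
  if (methods::is(y_hat, "ExtractedTrace")) {
    observed <- y_hat@observed
    y_hat <- traceRows(y_hat)
  }
  if (is.null(coarse_grid_px) && is.null(D))
    stop("need either a DPI or a grid-pitch estimate")
  if (is.null(coarse_grid_px)) coarse_grid_px <- 5 * D / 25.4
  if (coarse_grid_px <= 0) stop("coarse_grid_px must be positive")
  signal_mv <- (baseline_row - y_hat) * (0.5 / coarse_grid_px)
  fs <- if (!is.null(D)) D / 1.016 else coarse_grid_px * paper_speed / 5
  ExtractedTrace(yHat = y_hat, signalMv = signal_mv, fsImage = fs,
                 coarseGridPx = coarse_grid_px, baselineRow = baseline_row,
                 observed = if (is.null(observed))
                   rep(TRUE, length(y_hat)) else observed)
}

#' Resample a digitized series and align it to a reference
#'
#' Cubic-spline resampling from the image-implied rate to the reference
#' rate, then integer-lag alignment at the cross-correlation maximum
#' within `+-max_lag_s`; both series are truncated to the common support.
#'
#' @param signal_mv digitized series (mV) at `fs_from`.
#' @param fs_from its sampling frequency, Hz.
#' @param reference reference series at `fs_to`.
#' @param fs_to target sampling frequency, Hz.
#' @param max_lag_s alignment search half-window in seconds.
#' @return list with `est`, `ref` (aligned, equal length) and `lag`
#'   (samples at `fs_to`; positive = estimate was delayed).
#' @export
resampleAndAlign <- function(signal_mv, fs_from, reference, fs_to,
                             max_lag_s = 0.5) {
  if (!length(signal_mv) || !length(reference)) stop("empty series")
  t_old <- (seq_along(signal_mv) - 1L) / fs_from
  t_new <- seq(0, max(t_old), by = 1 / fs_to)
  est <- stats::spline(t_old, signal_mv, xout = t_new)$y
  ref <- reference
  if (stats::sd(est) < 1e-12 || stats::sd(ref) < 1e-12) {
    warning("zero-variance series: alignment skipped, lag 0")
    n <- min(length(est), length(ref))
    return(list(est = est[seq_len(n)], ref = ref[seq_len(n)], lag = 0L))
  }
  max_lag <- round(max_lag_s * fs_to)
  lags <- -max_lag:max_lag
  e0 <- est - mean(est); r0 <- ref - mean(ref)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(r0), length(e0) - l)
      if (n < 2) return(-Inf)
      sum(r0[seq_len(n)] * e0[seq_len(n) + l]) / n
    } else {
      n <- min(length(r0) + l, length(e0))
      if (n < 2) return(-Inf)
      sum(r0[seq_len(n) - l] * e0[seq_len(n)]) / n
    }
  }, 0)
  lag <- lags[which.max(cc)]
  if (lag >= 0) {
    n <- min(length(ref), length(est) - lag)
    list(est = est[seq_len(n) + lag], ref = ref[seq_len(n)], lag = lag)
  } else {
    n <- min(length(ref) + lag, length(est))
    list(est = est[seq_len(n)], ref = ref[seq_len(n) - lag], lag = lag)
  }
}
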