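# Global rotation estimation and compensation via the Radon transform.

#' Sinogram (Radon transform values)
#'
#' @slot values matrix over (rho, theta): one column per angle.
#' @slot rho_axis pixel offsets from the image center.
#' @slot theta_axis angles in degrees, strictly increasing.
#' @export
setClass("Sinogram",
  representation(values = "matrix", rho_axis = "numeric",
                 theta_axis = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@theta_axis, strictly = TRUE))
      return("theta_axis must be strictly increasing")
    if (ncol(object@values) != length(object@theta_axis))
      return("one value column per angle required")
    if (nrow(object@values) != length(object@rho_axis))
      return("one value row per rho required")
    TRUE
  })

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d rho x %d theta (%.3g..%.3g deg)\n",
              nrow(object@values), ncol(object@values),
              min(object@theta_axis), max(object@theta_axis)))
})

# rotation homography about the image center: positive angle rotates the
# content counter-clockwise in display coordinates (y down)
rotationMatrix <- function(angle_deg, H, W) {
  a <- angle_deg * pi / 180
  cx <- (1 + W) / 2; cy <- (1 + H) / 2
  R <- rbind(c(cos(a), sin(a), 0), c(-sin(a), cos(a), 0), c(0, 0, 1))
  Tc <- rbind(c(1, 0, cx), c(0, 1, cy), c(0, 0, 1))
  Tm <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  Tc %*% R %*% Tm
}

#' Rotate an image about its center
#'
#' Bilinear inverse-warp rotation; positive angles rotate the content
#' counter-clockwise (display coordinates). Ground truth, when given, is
#' rotated consistently.
#'
#' @param image image or [PaperImage-class].
#' @param angle_deg rotation angle in degrees.
#' @param ground_truth optional [GroundTruth-class].
#' @param fill background RGB for unmapped pixels.
#' @return list with `image` (and `truth` when ground truth was given).
#' @export
rotateImage <- function(image, angle_deg, ground_truth = NULL,
                        fill = c(255, 255, 255)) {
  px <- asPixelArray(image)
  m <- rotationMatrix(angle_deg, dim(px)[1L], dim(px)[2L])
  projectiveTransform(image, projectiveSpec(m), ground_truth = ground_truth,
                      fill = fill)
}

# project a single-channel matrix (mass image, zero background) onto the
# axis perpendicular to lines at angle theta: rotate (bilinear, zero fill)
# and column-sum; the hot loop lives in src/conv.cpp
radonProject <- function(mat, theta_deg) {
  as.numeric(rotate_colsums(mat, theta_deg))
}

#' Discrete Radon transform
#'
#' Line-integral projections `R(rho, theta)` of a single-channel image: for
#' each angle the image is rotated about its center (bilinear) inside a
#' zero-padded square and summed along columns, so the `theta = 0`
#' projection equals the column sums. Total mass is conserved per angle up
#' to interpolation error.
#'
#' @param image_gray numeric matrix (single channel).
#' @param thetas angles in degrees, strictly increasing, non-empty.
#' @return [Sinogram-class].
#' @export
radonTransform <- function(image_gray, thetas) {
  if (!length(thetas)) stop("empty angle set")
  image_gray <- as.matrix(image_gray)
  H <- nrow(image_gray); W <- ncol(image_gray)
  side <- ceiling(sqrt(H^2 + W^2))
  if (side %% 2L != max(H, W) %% 2L) side <- side + 1L
  pad <- matrix(0, side, side)
  r0 <- floor((side - H) / 2); c0 <- floor((side - W) / 2)
  pad[r0 + seq_len(H), c0 + seq_len(W)] <- image_gray
  vals <- rotate_colsums(pad, as.numeric(thetas))
  methods::new("Sinogram", values = vals,
               rho_axis = seq_len(side) - (side + 1) / 2,
               theta_axis = as.numeric(thetas))
}

# variance-of-projection criterion over a candidate angle grid; each
# projection is normalized by the projection of the page support so the
# rectangular page envelope (which peaks near 45 degrees) cancels and only
# the internal row structure (grid, trace baselines) drives the variance
projectionVariances <- function(mass, angles) {
  H <- nrow(mass); W <- ncol(mass)
  side <- ceiling(sqrt(H^2 + W^2))
  pad <- matrix(0, side, side)
  supp <- pad
  r0 <- floor((side - H) / 2); c0 <- floor((side - W) / 2)
  pad[r0 + seq_len(H), c0 + seq_len(W)] <- mass
  supp[r0 + seq_len(H), c0 + seq_len(W)] <- 1
  pm <- rotate_colsums(pad, angles)
  ps <- rotate_colsums(supp, angles)
  vapply(seq_along(angles), function(i) {
    ok <- ps[, i] > 0.5 * max(ps[, i])
    if (sum(ok) < 3L) return(0)
    stats::var(pm[ok, i] / ps[ok, i])
  }, 0)
}

#' Estimate global page rotation
#'
#' Finds the skew angle of a scanned/photographed ECG page as the angle
#' maximizing the variance over rho of the Radon projection profile (the
#' standard document-skew criterion: grid and trace rows align and produce
#' a strongly peaked projection when the page is level). A coarse search on
#' a block-mean-downsampled page is refined at 0.05 degree resolution.
#'
#' @param image image or [PaperImage-class] with dominant horizontal
#'   structure.
#' @param theta_range `(min, max)` search range in degrees.
#' @param theta_step coarse step in degrees.
#' @return estimated rotation angle in degrees (positive =
#'   counter-clockwise content rotation, i.e. the angle to undo with
#'   [derotate()]).
#' @export
estimateRotation <- function(image, theta_range = c(-45, 45),
                             theta_step = 0.25) {
  gray <- toGray(image)
  mass <- 255 - gray
  if (max(mass) - min(mass) < 1e-9) stop("no dominant orientation")
  f_coarse <- max(1L, ceiling(max(dim(mass)) / 360))
  small <- blockMean(mass, f_coarse)
  coarse_angles <- seq(theta_range[1L], theta_range[2L], by = theta_step)
  v <- projectionVariances(small, coarse_angles)
  if (max(v) <= 0 || !any(is.finite(v))) stop("no dominant orientation")
  best <- coarse_angles[which.max(v)]
  # refinement pass at 0.05 deg on a larger rendition
  f_fine <- max(1L, ceiling(max(dim(mass)) / 1100))
  large <- blockMean(mass, f_fine)
  fine_angles <- seq(best - 2 * theta_step, best + 2 * theta_step, by = 0.05)
  v2 <- projectionVariances(large, fine_angles)
  # radonProject rotates by the candidate angle before summing, so the
  # best candidate is the angle that undoes the page rotation: report its
  # negative as the detected rotation
  -fine_angles[which.max(v2)]
}

#' Undo a global rotation
#'
#' Rotates the image (and optionally its ground truth) by `-angle_deg`
#' about the center with bilinear resampling and background fill,
#' compensating the rotation reported by [estimateRotation()].
#'
#' @param image image or [PaperImage-class].
#' @param angle_deg angle to undo, degrees (finite).
#' @param ground_truth optional [GroundTruth-class].
#' @param fill background RGB.
#' @return list with `image` (and `truth` when ground truth was given).
#' @export
derotate <- function(image, angle_deg, ground_truth = NULL,
                     fill = c(255, 255, 255)) {
  stopifnotScalar(angle_deg, "angle_deg")
  rotateImage(image, -angle_deg, ground_truth = ground_truth, fill = fill)
}
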