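# End-to-end digitization: page -> strips -> traces -> calibrated series,
# plus round-trip evaluation helpers used for validation and reporting.

# most frequent rounded row: flat (baseline) samples dominate a strip
modeRow <- function(y) {
  tb <- table(round(y))
  as.numeric(names(tb)[which.max(tb)])
}

#' Digitize an ECG paper image
#'
#' Full classical pipeline: optional Radon-based rotation compensation,
#' grid-pitch estimation, grid removal (classical color suppression or a
#' trained residual denoiser), strip detection, per-strip binarization,
#' connected-component filtering/fusion, column-wise trace extraction and
#' conversion to millivolts.
#'
#' @param image [PaperImage-class] or pixel array.
#' @param dpi trusted DPI (NULL: derive timing from the grid pitch).
#' @param method grid removal route, `"classical"` or `"dncnn"`.
#' @param model trained `"ECGDenoiser"` for the `"dncnn"` route.
#' @param correct_rotation estimate and undo page rotation first.
#' @param text_masks optional list of ink masks to inpaint before grid
#'   removal.
#' @param paper_speed mm/s used for the time base.
#' @param fuse_dist,min_area component-analysis parameters (px).
#' @return list with `traces` (one [ExtractedTrace-class] per strip),
#'   `rois` (row intervals), `coarse_grid_px`, `rotation_deg`.
#' @export
digitizePage <- function(image, dpi = NULL,
                         method = c("classical", "dncnn"), model = NULL,
                         correct_rotation = FALSE, text_masks = NULL,
                         paper_speed = 25, fuse_dist = 10, min_area = 10) {
  method <- match.arg(method)
  rotation <- 0
  if (correct_rotation) {
    rotation <- estimateRotation(image)
    image <- derotate(image, rotation)$image
  }
  if (!is.null(text_masks) && length(text_masks))
    image <- inpaintImage(image, Reduce(`|`, text_masks))
  coarse_px <- estimateGridPeriod(image)
  clean <- removeGrid(image, model = model, method = method)
  rois <- detectStrips(clean)
  gray <- toGray(clean)
  traces <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    mask <- binarizeStrip(gray[roi[1L]:roi[2L], , drop = FALSE])
    comps <- analyzeComponents(mask, min_area = min_area,
                               fuse_dist = fuse_dist)
    kept <- comps$labels > 0L
    if (!any(kept)) next
    tr <- extractTrace(kept)
    baseline <- modeRow(traceRows(tr))
    traces[[i]] <- toPhysicalUnits(tr, baseline, coarse_grid_px = coarse_px,
                                   D = dpi, paper_speed = paper_speed)
  }
  list(traces = traces, rois = rois, coarse_grid_px = coarse_px,
       rotation_deg = rotation)
}

#' Round-trip fidelity of a rendered record
#'
#' Renders an ECG onto gridded paper, digitizes the page back (classical
#' grid removal by default) and scores the recovered series against the
#' reference: per-record SNR / median-noise SNR / MSE over the
#' concatenated aligned segments (ground-truth time windows identify each
#' segment's columns, as appropriate in synthetic mode), and the
#' RR-interval error from the rhythm strip.
#'
#' @param ecg [ECGTimeSeries-class].
#' @param spec [renderSpec()].
#' @param method,model grid removal route.
#' @param distort_config optional [distortionProfile()]-style list applied
#'   after rendering (geometric stages are skipped in scoring).
#' @param seed seed for the distortion stages.
#' @return list with the per-record metrics, the per-segment data.frame
#'   and the digitization byproducts.
#' @export
evaluateRoundTrip <- function(ecg, spec, method = "classical", model = NULL,
                              distort_config = NULL, seed = 1) {
  rend <- renderECG(ecg, spec)
  image <- rend$image
  truth <- rend$truth
  if (!is.null(distort_config)) {
    ds <- applyDistortionStack(image, distort_config, ground_truth = truth,
                               seed = seed)
    image <- ds$image
    truth <- ds$truth
  }
  coarse_px <- estimateGridPeriod(image)
  clean <- removeGrid(image, model = model, method = method)
  rois <- detectStrips(clean)
  gray <- toGray(clean)
  fs <- samplingRate(ecg)
  strip_y <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    mask <- binarizeStrip(gray[roi[1L]:roi[2L], , drop = FALSE])
    comps <- analyzeComponents(mask)
    kept <- comps$labels > 0L
    if (any(kept)) {
      tr <- tryCatch(extractTrace(kept), error = function(e) NULL)
      if (!is.null(tr))
        strip_y[[i]] <- traceRows(tr) + roi[1L] - 1  # absolute rows
    }
  }
  roiFor <- function(baseline_row) {
    for (i in seq_along(rois))
      if (baseline_row >= rois[[i]][1L] && baseline_row <= rois[[i]][2L])
        return(i)
    NA_integer_
  }
  seg_rows <- list()
  est_all <- numeric(0); ref_all <- numeric(0)
  rr_est <- rr_ref <- NULL
  for (s in gtSegments(truth)) {
    i <- roiFor(s$baseline_row)
    if (is.na(i) || is.null(strip_y[[i]])) next
    y <- strip_y[[i]][s$cols]
    baseline <- modeRow(y)
    est_mv <- (baseline - y) * 0.5 / coarse_px
    fs_img <- coarse_px * spec$paper_speed / 5
    i0 <- round(s$t0 * fs) + 1L
    i1 <- min(round(s$t1 * fs), ncol(ecgSamples(ecg)))
    ref <- ecgSamples(ecg)[match(s$lead, leadNames(ecg)), i0:i1]
    al <- resampleAndAlign(est_mv, fs_img, ref, fs, max_lag_s = 0.1)
    est_all <- c(est_all, al$est); ref_all <- c(ref_all, al$ref)
    seg_rows[[length(seg_rows) + 1L]] <-
      data.frame(lead = s$lead, kind = s$kind, t0 = s$t0,
                 snr_db = snr(al$ref, al$est), lag = al$lag)
    if (s$kind == "strip" && is.null(rr_est)) {
      rr_ref <- tryCatch(detectRPeaks(al$ref, fs), error = function(e) NULL)
      rr_est <- tryCatch(detectRPeaks(al$est, fs), error = function(e) NULL)
    }
  }
  if (!length(est_all)) stop("no segment could be digitized")
  rr <- if (!is.null(rr_est) && !is.null(rr_ref) &&
            length(rr_ref) >= 2L && length(rr_est) >= 2L)
    tryCatch(rrError(rr_ref, rr_est, fs), error = function(e) NULL)
  else NULL
  rec <- evaluateRecord(ref_all, est_all)
  c(rec,
    list(rr_mean_abs_ms = if (is.null(rr)) NA_real_ else rr$mean_abs_ms,
         segments = do.call(rbind, seg_rows),
         coarse_grid_px = coarse_px))
}

#' Calibration-pulse round trip
#'
#' Renders only the standard 1 mV / 0.2 s calibration pulse (with
#' surrounding baseline) on a gridded page at the requested DPI, then runs
#' the full classical digitization chain — grid-pitch estimation, color
#' grid removal, binarization, column-argmin extraction, 0.5 mV/coarse-grid
#' conversion — and measures the recovered plateau amplitude and pulse
#' width.
#'
#' @param dpi page resolution.
#' @return list with `amplitude_mv`, `width_s`, `coarse_grid_px`, `fs_img`,
#'   and the `dv`/`dt` resolution of the page.
#' @export
calibrationPulseRoundTrip <- function(dpi = 200) {
  spec <- renderSpec(dpi = dpi, paper_size = c(4, 3))
  img <- renderGrid(spec)
  H <- dim(imagePixels(img))[1L]; W <- dim(imagePixels(img))[2L]
  baseline <- round(H * 0.6)
  x_start <- round(W * 0.12); x_end <- round(W * 0.88)
  pulse_x <- round(W * 0.3)
  pulse <- renderCalibrationPulse(spec, x0 = pulse_x,
                                  baseline_row = baseline)
  cols <- x_start:x_end
  rows <- rep(baseline, length(cols))
  in_pulse <- cols >= pulse_x & cols < pulse_x + pulse$width_px
  rows[in_pulse] <- baseline - pulse$height_px
  img <- drawPolyline(img, cols, rows, color = spec$trace_color)
  coarse_px <- estimateGridPeriod(img)
  clean <- removeGrid(img, method = "classical")
  mask <- binarizeStrip(toGray(clean))
  comps <- analyzeComponents(mask)
  tr <- extractTrace(comps$labels > 0L)
  base_est <- modeRow(traceRows(tr))
  tr <- toPhysicalUnits(tr, base_est, coarse_grid_px = coarse_px)
  sig <- traceSignal(tr)
  plateau <- stats::median(sig[sig > 0.5 * max(sig)])
  width_cols <- sum(sig > 0.5 * plateau)
  rp <- resolutionParams(dpi)
  list(amplitude_mv = plateau, width_s = width_cols / traceFs(tr),
       coarse_grid_px = coarse_px, fs_img = traceFs(tr),
       dv = rp$dv, dt = rp$dt, n_columns = length(sig))
}
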