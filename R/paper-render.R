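# Rendering of ECG time-series onto standard ECG paper rasters.

#' Image/time-series resolution parameters
#'
#' For a page scanned at `D` dots per inch on standard ECG paper
#' (25 mm/s, 10 mm/mV), one pixel spans `dv = 2.54/D` mV vertically and
#' `dt = 1.016/D` s horizontally, giving an image-implied sampling
#' frequency `fs_img = D/1.016` Hz.
#'
#' @param D scan resolution in dots per inch (> 0).
#' @return list with `dv` (mV/px), `dt` (s/px) and `fs_img` (Hz).
#' @examples
#' resolutionParams(200)  # dv 0.0127 mV, dt 0.00508 s, fs_img 196.85 Hz
#' @export
resolutionParams <- function(D) {
  stopifnotScalar(D, "D", positive = TRUE)
  list(dv = 2.54 / D, dt = 1.016 / D, fs_img = D / 1.016)
}

#' Paper rendering specification
#'
#' Geometry and style of the rendered ECG page. Defaults follow the common
#' clinical format: 25 mm/s, 10 mm/mV, US-letter landscape page, a 3 x 4
#' grid of 2.5 s segments (leads arranged column-major in standard order)
#' plus one full-length lead II rhythm strip, red-pink grid.
#'
#' @param dpi dots per inch `D` (>= 72).
#' @param paper_speed mm per second (default 25).
#' @param gain mm per mV (default 10).
#' @param paper_size `(width_in, height_in)` in inches.
#' @param rows,cols layout of segment slots.
#' @param rhythm_leads lead names plotted as full-duration strips.
#' @param segment_len segment duration in seconds.
#' @param synchronous_segments if FALSE, row r segments are offset by
#'   `(r-1) * segment_len` (older swept machines).
#' @param show_grid,show_calibration render toggles.
#' @param background,fine_color,coarse_color,trace_color RGB triples 0..255.
#' @param trace_thickness_px trace thickness (1 keeps extraction exact).
#' @param margins_in page margins `(left, right, top, bottom)` in inches.
#' @return validated list of class `"RenderSpec"`.
#' @export
renderSpec <- function(dpi = 200, paper_speed = 25, gain = 10,
                       paper_size = c(11, 8.5), rows = 3, cols = 4,
                       rhythm_leads = "II", segment_len = 2.5,
                       synchronous_segments = TRUE,
                       show_grid = TRUE, show_calibration = TRUE,
                       background = c(255, 255, 255),
                       fine_color = c(255, 204, 204),
                       coarse_color = c(244, 138, 138),
                       trace_color = c(0, 0, 0),
                       trace_thickness_px = 1,
                       margins_in = c(0.3, 0.15, 0.55, 0.2)) {
  stopifnotScalar(dpi, "dpi", positive = TRUE)
  if (dpi < 72) stop("dpi must be at least 72")
  stopifnotScalar(paper_speed, "paper_speed", positive = TRUE)
  stopifnotScalar(gain, "gain", positive = TRUE)
  stopifnot(length(paper_size) == 2L, all(paper_size > 0))
  structure(list(dpi = dpi, paper_speed = paper_speed, gain = gain,
                 paper_size = paper_size, rows = as.integer(rows),
                 cols = as.integer(cols), rhythm_leads = rhythm_leads,
                 segment_len = segment_len,
                 synchronous_segments = synchronous_segments,
                 show_grid = show_grid, show_calibration = show_calibration,
                 background = background, fine_color = fine_color,
                 coarse_color = coarse_color, trace_color = trace_color,
                 trace_thickness_px = trace_thickness_px,
                 margins_in = margins_in,
                 fine_pitch_px = dpi / 25.4,
                 coarse_pitch_px = 5 * dpi / 25.4,
                 px_per_mv = gain * dpi / 25.4,
                 px_per_s = paper_speed * dpi / 25.4),
            class = "RenderSpec")
}

#' Render the standard ECG paper grid
#'
#' Draws the fine 1 mm and coarse 5 mm rulings on a uniform background.
#' Line positions accumulate in floating point and are rounded per line, so
#' the mean pitch stays at `D/25.4` px even when it is non-integer.
#'
#' @param spec [renderSpec()] result.
#' @return [PaperImage-class] of `round(height_in * D) x round(width_in * D)`
#'   pixels.
#' @export
renderGrid <- function(spec) {
  stopifnot(inherits(spec, "RenderSpec"))
  W <- round(spec$paper_size[1L] * spec$dpi)
  H <- round(spec$paper_size[2L] * spec$dpi)
  if (min(W, H) < spec$coarse_pitch_px)
    stop("paper too small for one coarse grid cell")
  px <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) px[, , ch] <- spec$background[ch]
  if (spec$show_grid) {
    vx <- 1 + round(seq(0, W - 1, by = spec$fine_pitch_px))
    hy <- 1 + round(seq(0, H - 1, by = spec$fine_pitch_px))
    v_coarse <- seq_along(vx) %% 5L == 1L
    h_coarse <- seq_along(hy) %% 5L == 1L
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[, vx[!v_coarse]] <- spec$fine_color[ch]
      plane[hy[!h_coarse], ] <- spec$fine_color[ch]
      plane[, vx[v_coarse]] <- spec$coarse_color[ch]
      plane[hy[h_coarse], ] <- spec$coarse_color[ch]
      px[, , ch] <- plane
    }
  }
  PaperImage(px, dpi = spec$dpi,
             provenance = list(list(op = "renderGrid",
                                    params = list(dpi = spec$dpi,
                                                  show_grid = spec$show_grid))))
}

#' Calibration pulse polyline
#'
#' The standard reference mark: a rectangular pulse of 1 mV amplitude
#' (`gain` mm high) and 0.2 s width (`0.2 * paper_speed` mm wide), expressed
#' as a pixel polyline (one row per column) flanked by one baseline column
#' on each side so the vertical edges rasterize when drawn.
#'
#' @param spec [renderSpec()] result (with `show_calibration = TRUE`).
#' @param x0 starting column of the pulse (1-based).
#' @param baseline_row baseline row.
#' @return list with `cols`, `rows`, `height_px`, `width_px`.
#' @export
renderCalibrationPulse <- function(spec, x0 = 1, baseline_row = 1) {
  stopifnot(inherits(spec, "RenderSpec"))
  if (!spec$show_calibration) stop("show_calibration is FALSE")
  h <- round(mmToPx(spec$gain, spec$dpi))          # 1 mV
  w <- round(mmToPx(0.2 * spec$paper_speed, spec$dpi))  # 0.2 s
  cols <- (x0 - 1):(x0 + w)
  rows <- c(baseline_row, rep(baseline_row - h, w), baseline_row)
  list(cols = cols, rows = rows, height_px = h, width_px = w)
}

# map layout slot (row r, col c) to lead index, column-major as on standard
# 3x4 printouts (row 1: I aVR V1 V4, row 2: II aVL V2 V5, ...)
layoutLeadIndex <- function(r, c, rows) (c - 1L) * rows + r

#' Render an ECG onto paper
#'
#' Draws every layout segment plus the rhythm strip(s) onto the grid page,
#' together with per-band calibration pulses, and returns the pixel-exact
#' ground truth: for each segment, one row per column with
#' `row = baseline - round(sample_mV * px_per_mv)`.
#'
#' @param ecg [ECGTimeSeries-class] (duration must cover the layout).
#' @param spec [renderSpec()] result.
#' @return list with elements `image` ([PaperImage-class]), `truth`
#'   ([GroundTruth-class], trace segments and strips only) and `pulses`
#'   (list of calibration-pulse polylines).
#' @export
renderECG <- function(ecg, spec) {
  stopifnot(methods::is(ecg, "ECGTimeSeries"), inherits(spec, "RenderSpec"))
  n_slots <- spec$rows * spec$cols
  if (n_slots > length(leadNames(ecg)))
    stop("layout needs lead index ", n_slots, " but record has only ",
         length(leadNames(ecg)), " leads")
  missing_rhythm <- setdiff(spec$rhythm_leads, leadNames(ecg))
  if (length(missing_rhythm))
    stop("lead missing from record: ", paste(missing_rhythm, collapse = ", "))
  duration <- ecgDuration(ecg)
  if (spec$cols * spec$segment_len > duration + 1e-9)
    stop("record too short for layout: needs ",
         spec$cols * spec$segment_len, " s, has ", duration, " s")
  img <- renderGrid(spec)
  px <- imagePixels(img)
  H <- dim(px)[1L]; W <- dim(px)[2L]
  m <- round(spec$margins_in * spec$dpi)  # left right top bottom
  n_bands <- spec$rows + length(spec$rhythm_leads)
  band_h <- (H - m[3L] - m[4L]) / n_bands
  baselines <- round(m[3L] + (seq_len(n_bands) - 0.5) * band_h)
  x0 <- m[1L] + 1L
  pulse_gap <- round(mmToPx(2, spec$dpi))
  x_trace <- x0
  pulses <- list()
  if (spec$show_calibration) {
    pw <- round(mmToPx(0.2 * spec$paper_speed, spec$dpi))
    x_trace <- x0 + pw + pulse_gap + 2L
    for (b in seq_len(n_bands))
      pulses[[b]] <- renderCalibrationPulse(spec, x0 = x0 + 1L,
                                            baseline_row = baselines[b])
  }
  plot_w <- W - m[2L] - x_trace
  seg_w <- spec$segment_len * spec$px_per_s
  if (spec$cols * seg_w > plot_w + 1e-9)
    stop("paper too narrow for ", spec$cols, " segments of ",
         spec$segment_len, " s")
  t_grid <- (seq_len(ncol(ecgSamples(ecg))) - 1L) / samplingRate(ecg)
  segs <- list()
  traceSegment <- function(lead_idx, t0, t1, xstart, baseline) {
    n_col <- floor((t1 - t0) * spec$px_per_s)
    xs <- xstart + seq_len(n_col) - 1L
    tt <- t0 + (xs - xstart) / spec$px_per_s
    tt <- pmin(tt, max(t_grid))
    mv <- stats::approx(t_grid, ecgSamples(ecg)[lead_idx, ], xout = tt,
                        rule = 2)$y
    rows <- baseline - round(mv * spec$px_per_mv)
    list(lead = leadNames(ecg)[lead_idx], t0 = t0, t1 = t1,
         cols = xs, rows = rows, baseline_row = baseline,
         px_per_mv = spec$px_per_mv, px_per_s = spec$px_per_s,
         kind = "segment")
  }
  for (r in seq_len(spec$rows)) {
    for (c in seq_len(spec$cols)) {
      offset <- if (spec$synchronous_segments) 0
                else ((r - 1L) * spec$segment_len) %% duration
      t0 <- ((c - 1L) * spec$segment_len + offset) %% duration
      t1 <- min(t0 + spec$segment_len, duration)
      s <- traceSegment(layoutLeadIndex(r, c, spec$rows), t0, t1,
                        x_trace + round((c - 1L) * seg_w), baselines[r])
      segs[[length(segs) + 1L]] <- s
    }
  }
  for (i in seq_along(spec$rhythm_leads)) {
    lead_idx <- match(spec$rhythm_leads[i], leadNames(ecg))
    s <- traceSegment(lead_idx, 0, duration, x_trace,
                      baselines[spec$rows + i])
    s$kind <- "strip"
    segs[[length(segs) + 1L]] <- s
  }
  for (p in pulses)
    px <- drawPolyline(px, p$cols, p$rows, color = spec$trace_color)
  for (s in segs)
    px <- drawPolyline(px, s$cols, s$rows, color = spec$trace_color)
  img@pixels <- px
  img@provenance <- c(img@provenance,
                      list(list(op = "renderECG",
                                params = list(n_segments = length(segs),
                                              synchronous =
                                                spec$synchronous_segments))))
  list(image = img, truth = GroundTruth(segs), pulses = pulses)
}
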