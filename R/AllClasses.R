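#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ecgpaper, .registration = TRUE
NULL

STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' Multi-lead ECG time-series
#'
#' Container for a per-lead sample matrix in millivolts together with its
#' sampling frequency, ordered lead labels and free-form header metadata
#' (patient name/ID/date strings as found in WFDB headers).
#'
#' @slot samples numeric matrix, n_leads x n_samples, in mV.
#' @slot fs sampling frequency in Hz.
#' @slot leadNames unique lead labels, one per row of `samples`.
#' @slot header named list of free-form metadata strings.
#' @export
setClass("ECGTimeSeries",
  representation(samples = "matrix", fs = "numeric",
                 leadNames = "character", header = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@leadNames) != nrow(object@samples))
      msg <- c(msg, "one lead name per sample row required")
    if (anyDuplicated(object@leadNames))
      msg <- c(msg, "lead names must be unique")
    if (length(msg)) msg else TRUE
  })

#' Construct an ECGTimeSeries
#'
#' @param samples numeric matrix (n_leads x n_samples) in mV.
#' @param fs sampling frequency, Hz.
#' @param leadNames lead labels; defaults to the standard 12-lead order
#'   I, II, III, aVR, aVL, aVF, V1..V6 truncated/recycled to the row count.
#' @param header named list of metadata strings.
#' @return ECGTimeSeries object.
#' @export
ECGTimeSeries <- function(samples, fs, leadNames = NULL, header = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(leadNames)) {
    if (nrow(samples) <= length(STANDARD_LEADS))
      leadNames <- STANDARD_LEADS[seq_len(nrow(samples))]
    else
      leadNames <- c(STANDARD_LEADS,
                     paste0("X", seq_len(nrow(samples) - length(STANDARD_LEADS))))
  }
  methods::new("ECGTimeSeries", samples = samples, fs = fs,
               leadNames = as.character(leadNames), header = header)
}

#' Accessors for ECGTimeSeries
#'
#' @param object ECGTimeSeries.
#' @return `ecgSamples` the mV matrix; `samplingRate` fs in Hz; `leadNames`
#'   the labels; `ecgDuration` the record length in seconds; `ecgHeader`
#'   the metadata list.
#' @export
setGeneric("ecgSamples", function(object) standardGeneric("ecgSamples"))
#' @rdname ecgSamples
#' @export
setMethod("ecgSamples", "ECGTimeSeries", function(object) object@samples)

#' @rdname ecgSamples
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname ecgSamples
#' @export
setMethod("samplingRate", "ECGTimeSeries", function(object) object@fs)

#' @rdname ecgSamples
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))
#' @rdname ecgSamples
#' @export
setMethod("leadNames", "ECGTimeSeries", function(object) object@leadNames)

#' @rdname ecgSamples
#' @export
setGeneric("ecgDuration", function(object) standardGeneric("ecgDuration"))
#' @rdname ecgSamples
#' @export
setMethod("ecgDuration", "ECGTimeSeries",
          function(object) ncol(object@samples) / object@fs)

#' @rdname ecgSamples
#' @export
setGeneric("ecgHeader", function(object) standardGeneric("ecgHeader"))
#' @rdname ecgSamples
#' @export
setMethod("ecgHeader", "ECGTimeSeries", function(object) object@header)

setMethod("show", "ECGTimeSeries", function(object) {
  cat(sprintf("ECGTimeSeries: %d leads x %d samples @ %.6g Hz (%.3g s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs))
  cat("  leads:", paste(object@leadNames, collapse = ", "), "\n")
  if (length(object@header))
    cat("  header fields:", paste(names(object@header), collapse = ", "), "\n")
})

#' Rendered/scanned ECG paper image
#'
#' RGB raster (8 bits per channel, stored as numeric 0..255) with a DPI tag
#' and an append-only provenance log of the operations applied to it.
#'
#' @slot pixels numeric array H x W x 3 in [0, 255].
#' @slot dpi dots per inch as rendered (NA when unknown).
#' @slot provenance list of `list(op =, params =)` entries, append-only.
#' @export
setClass("PaperImage",
  representation(pixels = "array", dpi = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3L] != 3L)
      return("pixels must be an H x W x 3 array")
    rng <- range(object@pixels)
    if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 255)
      return("pixel values must lie in [0, 255]")
    TRUE
  })

#' Construct a PaperImage
#'
#' @param pixels H x W x 3 numeric array in [0, 255] (a matrix is expanded
#'   to gray RGB).
#' @param dpi dots per inch.
#' @param provenance initial provenance log.
#' @return PaperImage object.
#' @export
PaperImage <- function(pixels, dpi = NA_real_, provenance = list()) {
  pixels <- asPixelArray(pixels)
  methods::new("PaperImage", pixels = pixels, dpi = as.numeric(dpi),
               provenance = provenance)
}

#' Accessors for PaperImage
#'
#' @param object PaperImage.
#' @return `imagePixels` the H x W x 3 array; `imageDPI` the DPI tag;
#'   `provenance` the operation log.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname imagePixels
#' @export
setMethod("imagePixels", "PaperImage", function(object) object@pixels)

#' @rdname imagePixels
#' @export
setGeneric("imageDPI", function(object) standardGeneric("imageDPI"))
#' @rdname imagePixels
#' @export
setMethod("imageDPI", "PaperImage", function(object) object@dpi)

#' @rdname imagePixels
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname imagePixels
#' @export
setMethod("provenance", "PaperImage", function(object) object@provenance)

setMethod("show", "PaperImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PaperImage: %d x %d px, %s DPI, %d provenance entries\n",
              d[1L], d[2L],
              if (is.finite(object@dpi)) format(object@dpi) else "unknown",
              length(object@provenance)))
  if (length(object@provenance))
    cat("  ops:", paste(vapply(object@provenance, `[[`, "", "op"),
                        collapse = " -> "), "\n")
})

#' Per-segment rendering ground truth
#'
#' One entry per rendered trace segment: lead name, time window, pixel
#' polyline (one row per column), baseline row and the pixel calibration
#' (px per mV, px per second).
#'
#' @slot segments list; each element has fields `lead`, `t0`, `t1`, `cols`,
#'   `rows`, `baseline_row`, `px_per_mv`, `px_per_s`, `kind`
#'   ("segment", "strip" or "pulse").
#' @export
setClass("GroundTruth", representation(segments = "list"),
  validity = function(object) {
    need <- c("lead", "t0", "t1", "cols", "rows", "baseline_row",
              "px_per_mv", "px_per_s", "kind")
    for (s in object@segments) {
      if (!all(need %in% names(s))) return("segment missing required fields")
      if (length(s$cols) != length(s$rows))
        return("polyline cols/rows length mismatch")
      if (anyDuplicated(s$cols))
        return("exactly one row per column required within a segment")
    }
    TRUE
  })

#' @rdname GroundTruth-class
#' @param segments list of segment entries.
#' @export
GroundTruth <- function(segments = list())
  methods::new("GroundTruth", segments = segments)

#' Accessor for GroundTruth segments
#' @param object GroundTruth.
#' @return list of segment entries.
#' @export
setGeneric("gtSegments", function(object) standardGeneric("gtSegments"))
#' @rdname gtSegments
#' @export
setMethod("gtSegments", "GroundTruth", function(object) object@segments)

setMethod("length", "GroundTruth", function(x) length(x@segments))

setMethod("show", "GroundTruth", function(object) {
  kinds <- vapply(object@segments, `[[`, "", "kind")
  cat(sprintf("GroundTruth: %d segments (%s)\n", length(object@segments),
              paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
})

#' Extracted trace of one strip
#'
#' Column-wise row indices of the recovered trace with the calibrated mV
#' series at the image-implied sampling frequency.
#'
#' @slot yHat row index per column (NA where no ink was found before
#'   interpolation).
#' @slot signalMv calibrated series in mV.
#' @slot fsImage image-implied sampling frequency, Hz.
#' @slot coarseGridPx estimated coarse grid pitch in px.
#' @slot baselineRow baseline row used for conversion.
#' @slot observed logical; FALSE where the column was interpolated.
#' @export
setClass("ExtractedTrace",
  representation(yHat = "numeric", signalMv = "numeric", fsImage = "numeric",
                 coarseGridPx = "numeric", baselineRow = "numeric",
                 observed = "logical"))

#' @rdname ExtractedTrace-class
#' @param yHat,signalMv,fsImage,coarseGridPx,baselineRow,observed slot values.
#' @export
ExtractedTrace <- function(yHat, signalMv = numeric(0), fsImage = NA_real_,
                           coarseGridPx = NA_real_, baselineRow = NA_real_,
                           observed = rep(TRUE, length(yHat))) {
  methods::new("ExtractedTrace", yHat = as.numeric(yHat),
               signalMv = as.numeric(signalMv), fsImage = as.numeric(fsImage),
               coarseGridPx = as.numeric(coarseGridPx),
               baselineRow = as.numeric(baselineRow),
               observed = as.logical(observed))
}

#' Accessors for ExtractedTrace
#' @param object ExtractedTrace.
#' @return `traceRows` the per-column row indices; `traceSignal` the mV
#'   series; `traceFs` the image-implied sampling rate in Hz.
#' @export
setGeneric("traceRows", function(object) standardGeneric("traceRows"))
#' @rdname traceRows
#' @export
setMethod("traceRows", "ExtractedTrace", function(object) object@yHat)
#' @rdname traceRows
#' @export
setGeneric("traceSignal", function(object) standardGeneric("traceSignal"))
#' @rdname traceRows
#' @export
setMethod("traceSignal", "ExtractedTrace", function(object) object@signalMv)
#' @rdname traceRows
#' @export
setGeneric("traceFs", function(object) standardGeneric("traceFs"))
#' @rdname traceRows
#' @export
setMethod("traceFs", "ExtractedTrace", function(object) object@fsImage)

setMethod("show", "ExtractedTrace", function(object) {
  cat(sprintf(
    "ExtractedTrace: %d columns, %.4g Hz image rate, %.4g px coarse grid\n",
    length(object@yHat), object@fsImage, object@coarseGridPx))
  if (length(object@observed))
    cat(sprintf("  interpolated columns: %d\n", sum(!object@observed)))
})
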