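# Ground-truth ECG sources: synthetic generator, physiological noise,
# WFDB (.hea/.dat, format 16) input/output.

# Per-wave beat template parameters. Times/widths in seconds relative to the
# R peak, amplitudes in mV. The morphology is a stylized sum of Gaussian
# kernels (P, Q, R, S, T), the classic dynamical-model family for synthetic
# ECG; per-lead multipliers vary amplitude but keep a dominant positive R so
# every lead carries an identifiable P-QRS-T complex.
BEAT_WAVES <- list(
  pos   = c(P = -0.180, Q = -0.028, R = 0.000, S = 0.030, T = 0.280),
  width = c(P =  0.028, Q =  0.010, R = 0.013, S = 0.013, T = 0.060),
  amp   = c(P =  0.120, Q = -0.140, R = 1.200, S = -0.250, T = 0.350))

#' Synthesize a multi-lead ECG time-series
#'
#' Generates a quasi-periodic 12-lead-style ECG from a sum-of-Gaussian-kernels
#' beat template (P, Q, R, S, T waves) driven by a mildly variable RR
#' process. Deterministic for a fixed seed; amplitudes stay well inside
#' +-5 mV. This stands in for clinical time-series archives as the
#' ground-truth source of the rendering pipeline.
#'
#' @param n_leads number of leads (default 12, standard labels).
#' @param fs sampling frequency in Hz.
#' @param duration record length in seconds.
#' @param heart_rate_bpm mean heart rate, 20..300.
#' @param seed integer seed; all randomness in the call flows from it.
#' @param rr_cv coefficient of variation of the RR process (default 0.03).
#' @return [ECGTimeSeries-class] with `n_leads x round(duration * fs)`
#'   samples in mV.
#' @examples
#' ecg <- synthesizeECG(12, fs = 250, duration = 10, heart_rate_bpm = 60,
#'                      seed = 1)
#' dim(ecgSamples(ecg))
#' @export
synthesizeECG <- function(n_leads = 12, fs = 250, duration = 10,
                          heart_rate_bpm = 60, seed = 1, rr_cv = 0.03) {
  stopifnotScalar(fs, "fs", positive = TRUE)
  stopifnotScalar(duration, "duration", positive = TRUE)
  stopifnotScalar(heart_rate_bpm, "heart_rate_bpm")
  if (heart_rate_bpm < 20 || heart_rate_bpm > 300)
    stop("heart_rate_bpm must lie in [20, 300]")
  n <- round(duration * fs)
  withSeed(seed, {
    rr_mean <- 60 / heart_rate_bpm
    n_beats <- ceiling(duration / rr_mean) + 3L
    rr <- rr_mean * (1 + rr_cv * stats::rnorm(n_beats))
    rr <- pmax(rr, 0.25 * rr_mean)
    r_times <- 0.4 * rr_mean + cumsum(c(0, rr[-n_beats]))
    t <- (seq_len(n) - 1L) / fs
    # per-lead amplitude multipliers: dominant R between ~0.7 and ~1.4 of
    # the template, secondary waves jittered independently
    lead_gain <- stats::runif(n_leads, 0.7, 1.4)
    wave_jit <- matrix(stats::runif(n_leads * 5L, 0.8, 1.2), n_leads, 5L)
    samples <- matrix(0, n_leads, n)
    for (b in seq_len(n_beats)) {
      tr <- r_times[b]
      if (tr - 0.4 > duration) break
      # T position stretches mildly with the local RR interval
      stretch <- c(1, 1, 1, 1, (rr[b] / rr_mean)^0.5)
      for (w in 1:5) {
        mu <- tr + BEAT_WAVES$pos[w] * stretch[w]
        sdv <- BEAT_WAVES$width[w]
        idx <- which(t > mu - 5 * sdv & t < mu + 5 * sdv)
        if (!length(idx)) next
        bump <- exp(-(t[idx] - mu)^2 / (2 * sdv^2))
        samples[, idx] <- samples[, idx] +
          (BEAT_WAVES$amp[w] * lead_gain * wave_jit[, w]) %o% bump
      }
    }
    ECGTimeSeries(samples, fs = fs,
                  leadNames = if (n_leads <= 12) STANDARD_LEADS[seq_len(n_leads)]
                              else NULL,
                  header = list(name = "synthetic", seed = as.character(seed),
                                heart_rate_bpm = as.character(heart_rate_bpm)))
  })
}

#' Physiological noise specification
#'
#' @param snr_db target signal-to-noise ratio in dB (whole record, all leads
#'   pooled); `Inf` means no noise.
#' @param components subset of `"baseline_wander"`, `"powerline"`,
#'   `"muscle"`, `"white"`.
#' @param mains_freq powerline frequency in Hz.
#' @param seed integer seed.
#' @return validated list of class `"NoiseSpec"`.
#' @export
noiseSpec <- function(snr_db = 6,
                      components = c("baseline_wander", "powerline",
                                     "muscle", "white"),
                      mains_freq = 50, seed = 1) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("snr_db must be a single number (possibly Inf)")
  known <- c("baseline_wander", "powerline", "muscle", "white")
  components <- match.arg(components, known, several.ok = TRUE)
  stopifnotScalar(mains_freq, "mains_freq", positive = TRUE)
  structure(list(snr_db = snr_db, components = components,
                 mains_freq = mains_freq, seed = seed),
            class = "NoiseSpec")
}

# One unit-power noise realization per component, n samples per lead.
noiseComponent <- function(kind, n_leads, n, fs, mains_freq) {
  t <- (seq_len(n) - 1L) / fs
  m <- switch(kind,
    baseline_wander = {
      freqs <- stats::runif(4L, 0.05, 0.45)
      out <- matrix(0, n_leads, n)
      for (l in seq_len(n_leads)) {
        amp <- stats::runif(4L, 0.3, 1)
        ph <- stats::runif(4L, 0, 2 * pi)
        out[l, ] <- colSums(amp * sin(outer(2 * pi * freqs, t) + ph))
      }
      out
    },
    powerline = {
      ph <- stats::runif(n_leads, 0, 2 * pi)
      amp <- stats::runif(n_leads, 0.5, 1)
      amp * sin(outer(rep(2 * pi * mains_freq, n_leads), t) + ph)
    },
    muscle = {
      # band-limited white noise: first difference of white noise emphasizes
      # the EMG-like high band, then light smoothing
      out <- matrix(stats::rnorm(n_leads * n), n_leads, n)
      t(apply(out, 1L, function(x) {
        d <- c(0, diff(x))
        movingAverage(d, 3L)
      }))
    },
    white = matrix(stats::rnorm(n_leads * n), n_leads, n),
    stop("unknown noise component: ", kind))
  p <- mean(m^2)
  if (p > 0) m / sqrt(p) else m
}

#' Contaminate an ECG with physiological noise at a target SNR
#'
#' Adds a mixture of baseline wander, powerline interference, muscle noise
#' and white device noise, scaled so the realized
#' `10*log10(sum(x^2)/sum(n^2))` over the whole record (all leads pooled)
#' equals `spec$snr_db`. The input object is not modified; the noise
#' realization depends only on the seed and record geometry, the input
#' signal enters only through the global power scaling.
#'
#' @param ecg [ECGTimeSeries-class].
#' @param spec [noiseSpec()] result.
#' @return new ECGTimeSeries; identical copy when `snr_db` is infinite or
#'   no components are selected.
#' @export
addPhysiologicalNoise <- function(ecg, spec) {
  stopifnot(methods::is(ecg, "ECGTimeSeries"), inherits(spec, "NoiseSpec"))
  x <- ecgSamples(ecg)
  if (is.infinite(spec$snr_db) && spec$snr_db > 0) return(ecg)
  if (!length(spec$components))
    stop("components must be non-empty when noise is applied")
  withSeed(spec$seed, {
    noise <- matrix(0, nrow(x), ncol(x))
    for (k in spec$components)
      noise <- noise + noiseComponent(k, nrow(x), ncol(x), samplingRate(ecg),
                                      spec$mains_freq)
    p_sig <- mean(x^2)
    p_noise <- mean(noise^2)
    scale <- if (p_noise > 0) sqrt(p_sig / (p_noise * 10^(spec$snr_db / 10)))
             else 0
    out <- x + scale * noise
    methods::initialize(ecg, samples = out)
  })
}

# ---- WFDB (format 16) -------------------------------------------------

#' Write an ECG record in WFDB format 16
#'
#' Writes `<record>.hea` (text header) and `<record>.dat` (16-bit
#' little-endian, sample-interleaved across signals). Amplitudes are
#' quantized at `gain` ADC units per mV; free-form header metadata is stored
#' verbatim as `# field: value` comment lines.
#'
#' @param ecg [ECGTimeSeries-class].
#' @param path record path without extension (e.g. `"dir/rec01"`).
#' @param gain ADC units per mV (default 1000, i.e. 1 uV quantization).
#' @return the header path, invisibly.
#' @export
writeWFDB <- function(ecg, path, gain = 1000) {
  stopifnot(methods::is(ecg, "ECGTimeSeries"))
  x <- ecgSamples(ecg)
  nsig <- nrow(x); nsamp <- ncol(x)
  record <- basename(path)
  adc <- round(x * gain)
  adc <- clamp(adc, -32768, 32767)
  checksums <- apply(adc, 1L, function(v) {
    s <- sum(v) %% 65536
    if (s >= 32768) s - 65536 else s
  })
  hea <- c(sprintf("%s %d %.10g %d", record, nsig, samplingRate(ecg), nsamp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
                   record, gain, adc[, 1L], checksums, leadNames(ecg)))
  hdr <- ecgHeader(ecg)
  if (length(hdr))
    hea <- c(hea, sprintf("# %s: %s", names(hdr),
                          vapply(hdr, as.character, "")))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(paste0(path, ".hea"))
}

#' Read a WFDB format-16 ECG record
#'
#' @param path record path with or without the `.hea` extension.
#' @return [ECGTimeSeries-class]; comment lines of the form
#'   `# field: value` populate the header metadata list.
#' @export
readWFDB <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header file not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(first) < 4L)
    stop("malformed WFDB header line: '", lines[1L], "'")
  nsig <- suppressWarnings(as.integer(first[2L]))
  fs <- suppressWarnings(as.numeric(first[3L]))
  nsamp <- suppressWarnings(as.integer(first[4L]))
  if (any(is.na(c(nsig, fs, nsamp))))
    stop("malformed WFDB header line: '", lines[1L], "'")
  sig_lines <- lines[-1L]
  comments <- sig_lines[startsWith(trimws(sig_lines), "#")]
  sig_lines <- sig_lines[!startsWith(trimws(sig_lines), "#")]
  if (length(sig_lines) < nsig)
    stop("WFDB header declares ", nsig, " signals but lists ",
         length(sig_lines))
  gains <- numeric(nsig); baselines <- numeric(nsig)
  lead_names <- character(nsig); dat_file <- NULL
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(sig_lines[i]), "\\s+")[[1L]]
    if (length(tok) < 3L || tok[2L] != "16")
      stop("malformed WFDB signal line (format 16 expected): '",
           sig_lines[i], "'")
    dat_file <- tok[1L]
    gspec <- tok[3L]
    g <- suppressWarnings(as.numeric(sub("\\(.*$", "", sub("/.*$", "", gspec))))
    b <- if (grepl("\\(", gspec))
      suppressWarnings(as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gspec)))
    else 0
    if (is.na(g) || g == 0)
      stop("malformed WFDB gain field: '", sig_lines[i], "'")
    gains[i] <- g; baselines[i] <- b
    lead_names[i] <- if (length(tok) >= 9L) paste(tok[9:length(tok)],
                                                  collapse = " ")
                     else paste0("S", i)
  }
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = nsig * nsamp, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(adc) < nsig * nsamp)
    stop("signal file shorter than header declares")
  adc <- matrix(adc, nrow = nsig)   # sample-interleaved
  x <- (adc - baselines) / gains
  header <- list()
  for (cm in comments) {
    body <- sub("^\\s*#\\s*", "", cm)
    if (grepl(":", body)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      header[[key]] <- val
    }
  }
  ECGTimeSeries(x, fs = fs, leadNames = lead_names, header = header)
}
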