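#' Band-pass-filtered recording trace
#'
#' @param samples Numeric vector (one channel) or matrix with channels in
#'   columns, uV. Assumed already band-pass filtered upstream; filtering
#'   is standard signal processing and deliberately out of scope here.
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @return An object of class `"recording_trace"`.
#' @export
recording_trace <- function(samples, sampling_rate) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be > 0 Hz")
  m <- as.matrix(samples)
  if (any(!is.finite(m))) stop("trace samples must be finite")
  structure(list(samples = m, sampling_rate = sampling_rate),
            class = "recording_trace")
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf("Recording trace: %d samples x %d channel(s) at %g Hz (%.3g s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Read a trace from delimited text or raw binary with a JSON sidecar
#'
#' Delimited text: one channel per column, optional header. Raw binary:
#' little-endian values with a JSON sidecar (`<path>.json`) supplying
#' `sampling_rate_hz`, `n_channels`, `dtype` (`"double"`, `"float"` or
#' `"int16"`) and an optional `uv_per_unit` scale (default 1); samples are
#' interleaved by channel.
#'
#' @param path Input file.
#' @param format `"text"` or `"binary"`; guessed from the presence of a
#'   sidecar when omitted.
#' @param sampling_rate Required for text input.
#' @param sep,header Passed to the text reader.
#' @return A [recording_trace()].
#' @export
read_trace <- function(path, format = NULL, sampling_rate = NULL,
                       sep = "", header = FALSE) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (is.null(format)) format <- if (file.exists(sidecar)) "binary" else "text"
  if (format == "text") {
    if (is.null(sampling_rate))
      stop("`sampling_rate` is required for delimited-text traces")
    m <- as.matrix(utils::read.table(path, sep = sep, header = header))
    storage.mode(m) <- "double"
    return(recording_trace(m, sampling_rate))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("sampling_rate_hz", "n_channels", "dtype"))
    if (is.null(meta[[k]])) stop("binary sidecar missing field '", k, "'")
  size <- switch(meta$dtype, double = 8L, float = 4L, int16 = 2L,
                 stop("unsupported dtype '", meta$dtype, "'"))
  what <- if (meta$dtype == "int16") integer() else double()
  n <- file.info(path)$size / size
  raw <- readBin(path, what, n = n, size = size, endian = "little")
  scale <- if (is.null(meta$uv_per_unit)) 1 else meta$uv_per_unit
  m <- matrix(as.numeric(raw) * scale, ncol = meta$n_channels, byrow = TRUE)
  recording_trace(m, meta$sampling_rate_hz)
}

#' Noise floor from spike-free snippets
#'
#' The noise floor of a channel is the RMS voltage of five 100-ms
#' snippets of filtered, spike-free recording joined into a single 500-ms
#' block. Snippet selection is the caller's responsibility (the snippets
#' must not contain sorted units or amplifier saturation);
#' [flag_artifacts()] helps locate unusable stretches.
#'
#' @param trace A [recording_trace()] (single channel, or give `channel`).
#' @param snippet_windows Matrix or data.frame with columns `start`, `end`
#'   in seconds: `n_windows` non-overlapping windows of `window_s` each
#'   (length tolerance: one sample), all inside the trace.
#' @param channel Channel index for multichannel traces.
#' @param n_windows,window_s Window-count and window-length convention;
#'   defaults five windows of 0.1 s.
#' @return Vrms of the concatenated block, uV.
#' @examples
#' tr <- recording_trace(sin(2 * pi * 50 * seq(0, 1, by = 1e-4)), 1e4)
#' w <- cbind(start = seq(0, 0.4, by = 0.1), end = seq(0.1, 0.5, by = 0.1))
#' noise_floor(tr, w)   # ~ 1/sqrt(2)
#' @export
noise_floor <- function(trace, snippet_windows, channel = 1L,
                        n_windows = 5L, window_s = 0.1) {
  stopifnot(inherits(trace, "recording_trace"))
  w <- as.matrix(as.data.frame(snippet_windows)[, c("start", "end")])
  if (nrow(w) != n_windows)
    stop("expected ", n_windows, " snippet windows, got ", nrow(w))
  fs <- trace$sampling_rate
  ns <- nrow(trace$samples)
  tol <- 1 / fs                                   # one sample of slack
  if (any(abs((w[, 2L] - w[, 1L]) - window_s) > tol))
    stop("each snippet window must be ", window_s, " s long (+/- one sample)")
  if (any(w[, 1L] < 0) || any(w[, 2L] > ns / fs + tol))
    stop("snippet windows must lie within the trace")
  o <- order(w[, 1L])
  if (any(w[o, 1L][-1L] < w[o, 2L][-n_windows] - tol / 2))
    stop("snippet windows must not overlap")
  x <- trace$samples[, channel]
  nper <- round(window_s * fs)
  idx <- unlist(lapply(w[, 1L], function(s) {
    from <- floor(s * fs) + 1L
    from:(from + nper - 1L)
  }))
  idx <- idx[idx >= 1L & idx <= ns]
  sqrt(mean(x[idx]^2))
}

#' Flag likely-unusable samples for snippet selection
#'
#' Marks samples whose magnitude exceeds `sigma_mult` robust standard
#' deviations (MAD-based, so spikes do not inflate the estimate) and
#' samples sitting at the amplifier rails. Windows overlapping flagged
#' samples should not be used for [noise_floor()]; the original study
#' chose snippets manually, this helper automates the screen.
#'
#' @param trace A [recording_trace()].
#' @param channel Channel index.
#' @param sigma_mult Threshold multiplier (default 5).
#' @param rail_uv Optional rail magnitude; samples with `|x| >= rail_uv`
#'   are flagged as saturation.
#' @return Logical vector, `TRUE` where a sample is unusable.
#' @export
flag_artifacts <- function(trace, channel = 1L, sigma_mult = 5,
                           rail_uv = NULL) {
  stopifnot(inherits(trace, "recording_trace"))
  x <- trace$samples[, channel]
  sigma <- stats::mad(x)
  bad <- abs(x - stats::median(x)) > sigma_mult * sigma
  if (!is.null(rail_uv)) bad <- bad | abs(x) >= rail_uv
  bad
}

#' Sorted-unit waveform
#'
#' @param waveform Numeric vector of waveform samples, uV.
#' @return Object of class `"unit_waveform"` with the peak-to-peak
#'   voltage `vpp = max - min`.
#' @export
unit_waveform <- function(waveform) {
  stopifnot(is.numeric(waveform), length(waveform) >= 1L,
            all(is.finite(waveform)))
  structure(list(waveform = as.numeric(waveform),
                 vpp = max(waveform) - min(waveform)),
            class = "unit_waveform")
}

#' Unit signal-to-noise ratio
#'
#' SNR of a sorted unit: the waveform's peak-to-peak voltage divided by
#' three times the channel's RMS noise floor,
#' `snr = vpp / (3 * vrms_channel)`.
#'
#' @param unit A [unit_waveform()], or a bare numeric vpp in uV.
#' @param vrms Channel noise floor from [noise_floor()], uV (> 0).
#' @return List of class `"snr_result"`: `vrms_channel`, `vpp`, `snr`.
#' @examples
#' unit_snr(unit_waveform(c(-40, 80)), vrms = 10)  # vpp 120 -> snr 4
#' @export
unit_snr <- function(unit, vrms) {
  vpp <- if (inherits(unit, "unit_waveform")) unit$vpp else as.numeric(unit)
  if (!is.numeric(vrms) || vrms <= 0)
    stop("`vrms` must be > 0 uV")
  structure(list(vrms_channel = vrms, vpp = vpp, snr = vpp / (3 * vrms)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("Unit SNR: vpp %.3g uV / (3 x %.3g uV rms) = %.3g\n",
              x$vpp, x$vrms_channel, x$snr))
  invisible(x)
}

#' Synthetic filtered trace with ground-truth spikes
#'
#' Gaussian noise of standard deviation `noise_sd` with copies of a spike
#' template added at homogeneous-Poisson times, for testing the noise and
#' SNR metrics against known ground truth.
#'
#' @param duration_s Trace duration, s.
#' @param sampling_rate Hz.
#' @param noise_sd Noise standard deviation, uV.
#' @param template Numeric spike template, uV (may be NULL / length 0 for
#'   pure noise).
#' @param rate_hz Mean spike rate, Hz.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List: `trace` (a [recording_trace()]), `spike_index` (integer
#'   sample indices of template onsets), `template`.
#' @export
synth_trace <- function(duration_s, sampling_rate, noise_sd,
                        template = NULL, rate_hz = 0, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- round(duration_s * sampling_rate)
  x <- stats::rnorm(n, 0, noise_sd)
  spike_index <- integer()
  if (!is.null(template) && length(template) && rate_hz > 0) {
    k <- stats::rpois(1L, rate_hz * duration_s)
    if (k > 0) {
      spike_index <- sort(sample.int(n - length(template), k))
      for (s in spike_index) {
        span <- s:(s + length(template) - 1L)
        x[span] <- x[span] + template
      }
    }
  }
  list(trace = recording_trace(x, sampling_rate),
       spike_index = spike_index, template = template)
}
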