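#' Construct a cough waveform object
#'
#' A voltage-sampled cough recording with its sampling rate and trial index.
#'
#' @param samples numeric vector of microphone voltages (V); all finite.
#' @param fs sampling rate (Hz).
#' @param participant_id identifier (character or integer).
#' @param trial_index trial number within the session (1-based).
#' @return an object of class `coughvc_waveform`.
#' @export
waveform <- function(samples, fs, participant_id = NA_character_,
                     trial_index = 1L) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  structure(list(samples = as.numeric(samples), fs = fs,
                 participant_id = participant_id,
                 trial_index = as.integer(trial_index)),
            class = "coughvc_waveform")
}

#' @export
print.coughvc_waveform <- function(x, ...) {
  cat(sprintf("<cough waveform: %d samples @ %g Hz (%.2f s), participant %s, trial %d>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              as.character(x$participant_id), x$trial_index))
  invisible(x)
}

#' Microphone calibration model
#'
#' Maps sound pressure to microphone voltage: a sensitivity S in dB re
#' 1 V/Pa gives the voltage output per pascal Vs = 10^(S/20). The default
#' S = -35 dB matches an electret in-ear condenser microphone; the
#' reference pressure P0 = 20 uPa is the standard SPL reference.
#'
#' @param sensitivity_db microphone sensitivity S (dB re 1 V/Pa).
#' @param reference_pressure reference sound pressure P0 (Pa).
#' @return an object of class `coughvc_mic` with the derived
#'   `voltage_per_pa`.
#' @export
microphone_model <- function(sensitivity_db = -35.0,
                             reference_pressure = 20e-6) {
  if (reference_pressure <= 0) stop("reference_pressure must be > 0")
  structure(list(sensitivity_db = sensitivity_db,
                 reference_pressure = reference_pressure,
                 voltage_per_pa = 10^(sensitivity_db / 20)),
            class = "coughvc_mic")
}

#' Extract the peak-containing segment of a recording
#'
#' Returns a contiguous segment of the given duration containing the global
#' maximum of the rectified signal. The maximum is centered in the segment,
#' shifted only as needed to keep the segment inside the recording; ties go
#' to the earliest maximum.
#'
#' @param w a [waveform()].
#' @param duration segment length in seconds (default 5).
#' @return a waveform of `round(duration * fs)` samples with attribute
#'   `segment_bounds` = c(first, last) sample indices in the input.
#' @export
extract_peak_segment <- function(w, duration = 5.0) {
  stopifnot(inherits(w, "coughvc_waveform"))
  n <- length(w$samples)
  n_seg <- round(duration * w$fs)
  if (n < n_seg)
    stop("recording (", n / w$fs, " s) shorter than the requested segment (",
         duration, " s)")
  idx <- which.max(abs(w$samples))            # earliest on ties
  start <- idx - floor(n_seg / 2)
  start <- max(1L, min(start, n - n_seg + 1L))
  out <- w
  out$samples <- w$samples[start:(start + n_seg - 1L)]
  attr(out, "segment_bounds") <- c(start, start + n_seg - 1L)
  out
}

#' Instantaneous sound pressure level trace
#'
#' Converts a voltage waveform to a samplewise SPL trace
#' Lp(t) = 20 log10(|Vr(t)| / (P0 * Vs)). Voltages are rectified (the
#' downstream statistic is a maximum, so only magnitude matters); exact
#' zeros map to `-Inf` and are excluded from maxima. An optional short RMS
#' window (in seconds) smooths the trace for noisy inputs.
#'
#' @param w a [waveform()].
#' @param mic a [microphone_model()].
#' @param rms_window optional RMS window length (s); `NULL` (default) for
#'   samplewise operation.
#' @return numeric vector of dB values, one per sample (or per window).
#' @export
spl_trace <- function(w, mic, rms_window = NULL) {
  stopifnot(inherits(w, "coughvc_waveform"), inherits(mic, "coughvc_mic"))
  ref <- mic$reference_pressure * mic$voltage_per_pa
  x <- abs(w$samples)
  if (!is.null(rms_window)) {
    nw <- max(1L, round(rms_window * w$fs))
    nwin <- floor(length(x) / nw)
    x <- sqrt(colMeans(matrix(x[seq_len(nwin * nw)]^2, nrow = nw)))
  }
  out <- rep(-Inf, length(x))
  nz <- x > 0
  out[nz] <- 20 * log10(x[nz] / ref)
  out
}

#' Maximum SPL of a single trial
#'
#' @param trace dB trace from [spl_trace()].
#' @return the maximum finite value (dB).
#' @export
trial_max_spl <- function(trace) {
  if (length(trace) == 0) stop("empty trace")
  finite <- trace[is.finite(trace)]
  if (length(finite) == 0) stop("silent trial: no finite SPL values")
  max(finite)
}

#' Session sound pressure level from repeated cough trials
#'
#' Applies the full per-trial chain -- band-pass filter, peak-segment
#' extraction, SPL trace, trial maximum -- and takes the session SPL as the
#' maximum across trials. At least three acceptable trials are required.
#'
#' @param trials list of [waveform()]s (>= 3).
#' @param mic a [microphone_model()].
#' @param low,high,order band-pass settings (see [bandpass_filter()]).
#' @param segment_duration peak-segment length (s).
#' @param rms_window see [spl_trace()].
#' @param edge_margin settling margin (s) discarded from each end of the
#'   filtered recording before the peak search. Zero-phase filtering
#'   cannot fully suppress boundary transients when strong out-of-band
#'   components run through the record edges, so the first/last fraction
#'   of a second is excluded (coughs are recorded mid-trial).
#' @return an object of class `coughvc_spl` with `per_trial_max_db`,
#'   `session_spl_db` and `segment_bounds` (indices into the original
#'   recording).
#' @export
session_spl <- function(trials, mic, low = 140, high = 2000, order = 4,
                        segment_duration = 5.0, rms_window = NULL,
                        edge_margin = 0.25) {
  if (length(trials) < 3)
    stop("at least three acceptable trials are required (got ",
         length(trials), ")")
  per_trial <- numeric(length(trials))
  bounds <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    wf <- bandpass_filter(trials[[i]], low = low, high = high, order = order)
    off <- 0L
    n_margin <- round(edge_margin * wf$fs)
    if (n_margin > 0 &&
        length(wf$samples) >= segment_duration * wf$fs + 2 * n_margin) {
      wf$samples <- wf$samples[(n_margin + 1):(length(wf$samples) - n_margin)]
      off <- n_margin
    }
    seg <- extract_peak_segment(wf, duration = segment_duration)
    per_trial[i] <- trial_max_spl(spl_trace(seg, mic, rms_window = rms_window))
    bounds[[i]] <- attr(seg, "segment_bounds") + off
  }
  structure(list(per_trial_max_db = per_trial,
                 session_spl_db = max(per_trial),
                 segment_bounds = bounds),
            class = "coughvc_spl")
}

#' @export
print.coughvc_spl <- function(x, ...) {
  cat(sprintf("<session SPL %.2f dB over %d trials (per-trial: %s)>\n",
              x$session_spl_db, length(x$per_trial_max_db),
              paste(sprintf("%.2f", x$per_trial_max_db), collapse = ", ")))
  invisible(x)
}
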