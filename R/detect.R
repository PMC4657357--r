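# Pulse detection: noise-level estimation, call-onset detection, pulse
# peak picking with reflection rejection and low-amplitude recovery, call
# segmentation over a session, and IPI extraction.

#' Estimate the background noise level
#'
#' Robust envelope statistic (median of the analytic-signal envelope) over
#' a quiet window. The envelope is taken of the waveform as given; pass a
#' band-passed signal to estimate the in-band noise level.
#'
#' @param waveform numeric vector.
#' @param fs sampling rate, Hz.
#' @param quiet_window length-2 numeric, window in seconds (inside the
#'   recording); NULL uses the whole waveform.
#' @return scalar noise level, linear amplitude units.
#' @export
estimate_noise_level <- function(waveform, fs, quiet_window = NULL) {
  n <- length(waveform)
  if (is.null(quiet_window)) {
    seg <- waveform
  } else {
    i0 <- floor(quiet_window[1] * fs) + 1
    i1 <- ceiling(quiet_window[2] * fs)
    if (i0 < 1 || i1 > n || i1 < i0)
      stop_arg("quiet window lies outside the recording")
    seg <- waveform[i0:i1]
  }
  if (length(seg) == 0) stop_arg("empty quiet window")
  stats::median(envelope(seg))
}

#' Detect the onset of a call
#'
#' First time the signal envelope exceeds `factor` times the noise level;
#' returns NULL when the threshold is never crossed. The default factor
#' of 3 follows the convention of thresholding at roughly three times the
#' noise level; for wideband noise a larger factor (4-5) avoids spurious
#' crossings from noise-envelope excursions.
#'
#' @param waveform numeric vector (band-pass before calling to detect in
#'   the analysis band).
#' @param fs sampling rate, Hz.
#' @param noise_level linear noise amplitude (>= 0).
#' @param factor threshold ratio.
#' @return onset time in seconds, or NULL if no crossing.
#' @export
detect_call_onset <- function(waveform, fs, noise_level, factor = 3.0) {
  if (noise_level < 0) stop_arg("noise_level must be >= 0")
  thr <- factor * noise_level
  if (thr == 0) {
    # degenerate threshold: the envelope criterion reduces to signal
    # support, i.e. the first nonzero sample
    idx <- which(waveform != 0)
    if (length(idx) == 0) return(NULL)
    return((idx[1] - 1) / fs)
  }
  env <- envelope(waveform)
  idx <- which(env > thr)
  if (length(idx) == 0) return(NULL)
  (idx[1] - 1) / fs
}

#' Default pulse-detector parameters
#'
#' @param threshold_factor envelope threshold as a multiple of the noise
#'   level for the primary pass. The onset rule uses ~3x noise; the
#'   per-pulse threshold defaults to 5x so that noise-envelope maxima
#'   between pulses stay below threshold at moderate SNR.
#' @param min_ipi_ms refractory minimum IPI, ms (pulse repetition rates
#'   up to ~250 pulses/s leave margin at 1 ms).
#' @param echo_window_ms reflection window after a stronger pulse, ms.
#' @param echo_ratio candidates inside the echo window below this
#'   amplitude ratio of the preceding stronger pulse are discarded.
#' @param recovery_factor threshold multiplier for the secondary
#'   low-amplitude pass inside suspicious gaps.
#' @param gap_ratio length-2 numeric: gaps between `gap_ratio[1]` and
#'   `gap_ratio[2]` times the local median IPI trigger the recovery pass
#'   (a single missed pulse leaves a gap of ~2x the local IPI; wider
#'   gaps are treated as genuine pauses, not missed pulses).
#' @param recovery_center_frac the recovered candidate must lie within
#'   this fraction of the gap around its centre, where the missing pulse
#'   of a locally regular train is expected.
#' @return list of detector parameters.
#' @export
pulse_params <- function(threshold_factor = 5.0, min_ipi_ms = 1.0,
                         echo_window_ms = c(0.1, 1.0), echo_ratio = 0.7,
                         recovery_factor = 0.5, gap_ratio = c(1.7, 2.4),
                         recovery_center_frac = 0.4) {
  if (length(gap_ratio) == 1) gap_ratio <- c(gap_ratio, 2.4)
  list(threshold_factor = threshold_factor, min_ipi_ms = min_ipi_ms,
       echo_window_ms = echo_window_ms, echo_ratio = echo_ratio,
       recovery_factor = recovery_factor, gap_ratio = gap_ratio,
       recovery_center_frac = recovery_center_frac)
}

#' Detect pulse peaks within a call
#'
#' Envelope local maxima above threshold, subject to (a) a refractory
#' minimum IPI (the stronger of two close candidates wins), (b)
#' reflection rejection -- a candidate inside the echo window after a
#' stronger pulse and below an amplitude ratio of it is discarded, and
#' (c) a low-amplitude recovery pass with a lowered threshold inside
#' gaps of roughly twice the local median IPI.
#'
#' @param waveform full recording channel (numeric).
#' @param fs sampling rate, Hz.
#' @param call_interval length-2 numeric, call interval in seconds.
#' @param noise_level linear noise amplitude in the analysis band; when
#'   NULL it is estimated from the whole interval envelope median.
#' @param params detector parameters from [pulse_params()].
#' @param band analysis band, Hz; NULL to skip filtering.
#' @param call_id identifier carried into the result.
#' @param channel channel id carried into the result.
#' @param env optional precomputed analysis-band envelope of the full
#'   waveform (skips filtering and envelope computation; used by the
#'   session pipeline to avoid repeated work).
#' @return object of class `pulse_train` with `peak_times` (s, strictly
#'   increasing, absolute within the recording), `peak_amplitudes`,
#'   `noise_level`, `onset_time`, `call_id`, `channel`, `fs`. Zero
#'   detected pulses gives an empty train flagged with `empty = TRUE`.
#' @export
detect_pulses <- function(waveform, fs, call_interval, noise_level = NULL,
                          params = pulse_params(), band = c(6e3, 170e3),
                          call_id = NA, channel = NA, env = NULL) {
  n <- length(waveform)
  i0 <- max(1L, floor(call_interval[1] * fs) + 1L)
  i1 <- min(n, ceiling(call_interval[2] * fs))
  if (i1 <= i0) stop_arg("empty call interval")
  if (is.null(env)) {
    seg <- waveform[i0:i1]
    if (!is.null(band)) seg <- band_pass(seg, fs, band)
    env <- envelope(seg)
  } else {
    env <- env[i0:i1]
  }
  if (is.null(noise_level)) noise_level <- stats::median(env)
  thr <- params$threshold_factor * noise_level
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr]
  acc <- pick_pulses(cand, env[cand], fs, params, thr)
  # secondary pass (single): recover a low-amplitude pulse inside gaps of
  # ~2x the local median IPI, near the gap centre where a missed pulse of
  # a locally regular train is expected. The median is local (a window of
  # neighbouring intervals) so that slow contour ramps spanning a 2-3x
  # IPI range do not masquerade as missed-pulse gaps.
  if (length(acc$idx) >= 3) {
    ipis <- diff(acc$idx) / fs * 1000
    local_med <- vapply(seq_along(ipis), function(g) {
      w <- max(1, g - 5):min(length(ipis), g + 5)
      stats::median(ipis[w])
    }, numeric(1))
    gap_at <- which(ipis > params$gap_ratio[1] * local_med &
                    ipis < params$gap_ratio[2] * local_med)
    low_thr <- params$recovery_factor * thr
    recovered <- integer(0)
    for (g in gap_at) {
      gap_len <- acc$idx[g + 1] - acc$idx[g]
      half <- round(params$recovery_center_frac / 2 * gap_len)
      centre <- acc$idx[g] + round(gap_len / 2)
      lo <- max(acc$idx[g] + round(params$min_ipi_ms / 1000 * fs),
                centre - half)
      hi <- min(acc$idx[g + 1] - round(params$min_ipi_ms / 1000 * fs),
                centre + half)
      if (hi <= lo) next
      sub <- local_maxima(env[lo:hi]) + lo - 1L
      sub <- sub[env[sub] > low_thr]
      if (length(sub) == 0) next
      recovered <- c(recovered, sub[which.max(env[sub])])
    }
    acc$idx <- sort(unique(c(acc$idx, recovered)))
  }
  idx <- acc$idx
  empty <- length(idx) == 0
  structure(list(
    call_id = call_id, channel = channel,
    peak_times = (i0 - 1 + idx - 1) / fs,
    peak_amplitudes = env[idx],
    noise_level = noise_level,
    onset_time = if (empty) NA_real_ else (i0 - 1 + idx[1] - 1) / fs,
    fs = fs, empty = empty
  ), class = "pulse_train")
}

# refractory non-maximum suppression followed by echo rejection;
# cand = candidate sample indices, amp = envelope there
pick_pulses <- function(cand, amp, fs, params, thr) {
  if (length(cand) == 0) return(list(idx = integer(0)))
  refr <- round(params$min_ipi_ms / 1000 * fs)
  ord <- order(amp, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0 || all(abs(accepted - cand[i]) >= refr))
      accepted <- c(accepted, cand[i])
  }
  accepted <- sort(accepted)
  amp_of <- amp[match(accepted, cand)]
  # reflection rejection: weaker candidate in the echo window of a
  # stronger accepted pulse
  keep <- rep(TRUE, length(accepted))
  w <- params$echo_window_ms / 1000 * fs
  for (i in seq_along(accepted)) {
    if (i == 1) next
    earlier <- which(accepted < accepted[i] & keep)
    for (e in earlier) {
      dt <- accepted[i] - accepted[e]
      if (dt >= w[1] && dt <= w[2] &&
          amp_of[i] < params$echo_ratio * amp_of[e]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  list(idx = accepted[keep])
}

#' Segment a recording into candidate calls
#'
#' Detects supra-threshold envelope peaks across the whole channel and
#' groups them into calls separated by quiet gaps. A call ends at the
#' last supra-threshold pulse followed by at least `gap_s` of
#' sub-threshold envelope.
#'
#' @param waveform recording channel.
#' @param fs sampling rate, Hz.
#' @param noise_level in-band noise amplitude; estimated from the full
#'   envelope median when NULL.
#' @param params detector parameters ([pulse_params()]).
#' @param band analysis band, Hz.
#' @param gap_s quiet gap that terminates a call, s.
#' @param min_pulses discard clusters with fewer peaks than this.
#' @param env optional precomputed analysis-band envelope.
#' @return data.frame with `start_s`, `end_s`, `n_peaks` per call.
#' @export
segment_calls <- function(waveform, fs, noise_level = NULL,
                          params = pulse_params(), band = c(6e3, 170e3),
                          gap_s = 0.05, min_pulses = 5, env = NULL) {
  if (is.null(env)) {
    seg <- if (!is.null(band)) band_pass(waveform, fs, band) else waveform
    env <- envelope(seg)
  }
  if (is.null(noise_level)) noise_level <- stats::median(env)
  thr <- params$threshold_factor * noise_level
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr]
  acc <- pick_pulses(cand, env[cand], fs, params, thr)$idx
  if (length(acc) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_peaks = integer(0)))
  gaps <- which(diff(acc) > gap_s * fs)
  starts <- c(1, gaps + 1)
  ends <- c(gaps, length(acc))
  out <- data.frame(
    start_s = (acc[starts] - 1) / fs,
    end_s = (acc[ends] - 1) / fs,
    n_peaks = ends - starts + 1L)
  out <- out[out$n_peaks >= min_pulses, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the IPI contour of a pulse train
#'
#' IPIs are the time differences from the peak of each pulse to the peak
#' of the following pulse, in ms; interval i is led by pulse i (1-based).
#'
#' @param train a `pulse_train` from [detect_pulses()].
#' @return object of class `ipi_contour`: `ipis` (ms) and `pulse_index`
#'   (leading pulse of each interval).
#' @export
extract_ipis <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  n <- length(train$peak_times)
  if (n < 2) stop_arg("at least 2 pulses are required to extract IPIs")
  ipis <- diff(train$peak_times) * 1000
  stopifnot(all(ipis > 0))
  structure(list(ipis = ipis, pulse_index = seq_len(n - 1L)),
            class = "ipi_contour")
}
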