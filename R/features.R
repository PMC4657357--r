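# Per-call measurements: the five temporal parameters (two averaged IPIs,
# duration, pulse count, pulse repetition rate), pulse power spectra
# (Hamming / FFT 256 / 5-point smoothing / relative dB), the four spectral
# parameters (peak frequency and the 10 dB bandwidth with its edges), and
# a rule-based surrogate for the broad call-type categories.

#' Temporal call parameters
#'
#' Computes the two averaged IPIs (intervals led by pulses 11-20, and the
#' mirrored set 11-20 counted from the last pulse), the call duration
#' (first to last pulse peak), the pulse count and the pulse repetition
#' rate PRR = pulses / duration. Interval i spans pulses i to i+1, so
#' "pulse nos. 11-20" selects the ten intervals with leading index
#' 11..20 (this indexing convention is a documented choice). Calls with
#' fewer than 21 pulses average the available subset and are flagged
#' truncated; calls with fewer than 12 pulses have undefined averages
#' (NA, flagged missing) while duration and PRR are still returned.
#'
#' @param contour an `ipi_contour` from [extract_ipis()].
#' @param train the parent `pulse_train`.
#' @return object of class `temporal_features`: `avg_ipi_11_20`,
#'   `avg_ipi_11_20_last` (ms), `duration_s`, `n_pulses`, `prr`,
#'   `truncated`, `missing_averages`.
#' @export
temporal_features <- function(contour, train) {
  stopifnot(inherits(contour, "ipi_contour"), inherits(train, "pulse_train"))
  n <- length(train$peak_times)
  if (n < 2) stop_arg("at least 2 pulses are required")
  stopifnot(length(contour$ipis) == n - 1)
  duration <- train$peak_times[n] - train$peak_times[1]
  prr <- n / duration
  first_idx <- intersect(11:20, seq_len(n - 1))
  last_idx <- intersect((n - 20):(n - 11), seq_len(n - 1))
  missing <- n < 12
  truncated <- !missing && n < 21
  a1 <- if (missing || length(first_idx) == 0) NA_real_ else mean(contour$ipis[first_idx])
  a2 <- if (missing || length(last_idx) == 0) NA_real_ else mean(contour$ipis[last_idx])
  structure(list(
    avg_ipi_11_20 = a1, avg_ipi_11_20_last = a2,
    duration_s = duration, n_pulses = n, prr = prr,
    truncated = truncated, missing_averages = missing
  ), class = "temporal_features")
}

#' Power spectrum of one pulse
#'
#' Averaged magnitude-squared spectrum of Hamming-windowed 256-sample
#' frames (50% overlap) tiling the 1.5 ms of data centred on the pulse
#' peak, smoothed with a five-point moving window and expressed in dB
#' relative to the band maximum (the maximum level inside `band` is set
#' to 0 dB). Frequency resolution is fs/256 (1953 Hz at 500 kHz) and the
#' frame length is 0.512 ms.
#'
#' @param waveform recording channel.
#' @param peak_time pulse peak time, s.
#' @param fs sampling rate, Hz.
#' @param band normalization band, Hz (default 6-170 kHz).
#' @param window_s analysis window length, s.
#' @param nfft FFT size.
#' @param pulse_location optional tag in {"third", "middle",
#'   "third_from_last"}.
#' @return object of class `call_spectrum`: `freq` (bin centres, Hz),
#'   `level_db` (band maximum = 0), `bin_width_hz`, `time_res_ms`,
#'   `pulse_location`.
#' @export
pulse_spectrum <- function(waveform, peak_time, fs, band = c(6e3, 170e3),
                           window_s = 1.5e-3, nfft = 256,
                           pulse_location = NA_character_) {
  n <- length(waveform)
  half <- round(window_s / 2 * fs)
  i0 <- round(peak_time * fs) + 1 - half
  i1 <- i0 + 2 * half - 1
  if (i0 < 1 || i1 > n) stop_arg("analysis window exceeds the recording")
  seg <- waveform[i0:i1]
  hop <- nfft / 2
  starts <- seq(1, length(seg) - nfft + 1, by = hop)
  w <- signal::hamming(nfft)
  P <- rowMeans(vapply(starts, function(s) {
    sp <- stats::fft(seg[s:(s + nfft - 1)] * w)
    Mod(sp[1:(nfft / 2 + 1)])^2
  }, numeric(nfft / 2 + 1)))
  # five-point moving average with edge replication
  Ppad <- c(rep(P[1], 2), P, rep(P[length(P)], 2))
  Ps <- stats::filter(Ppad, rep(1 / 5, 5), sides = 2)
  Ps <- as.numeric(Ps[3:(length(Ppad) - 2)])
  freq <- (0:(nfft / 2)) * fs / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) stop_arg("normalization band contains no bins")
  ref <- max(Ps[in_band])
  level <- 10 * log10(pmax(Ps, .Machine$double.xmin) / ref)
  structure(list(freq = freq, level_db = level, bin_width_hz = fs / nfft,
                 time_res_ms = nfft / fs * 1000,
                 pulse_location = pulse_location),
            class = "call_spectrum")
}

#' Representative pulse locations within a call
#'
#' The third pulse, the middle pulse and the third pulse from the last.
#' For even counts the middle pulse is `ceiling(n/2)` (the earlier one).
#'
#' @param train a `pulse_train` (or an integer pulse count).
#' @return named integer vector `c(third, middle, third_from_last)`.
#' @export
select_pulse_locations <- function(train) {
  n <- if (inherits(train, "pulse_train")) length(train$peak_times) else as.integer(train)
  if (n < 5) stop_arg("at least 5 pulses are required")
  c(third = 3L, middle = as.integer(ceiling(n / 2)),
    third_from_last = n - 2L)
}

#' Spectral call parameters
#'
#' Peak frequency and the 10 dB bandwidth inside the analysis band
#' (default 11-170 kHz; below 10 kHz all individuals share a common ~6
#' kHz energy peak so that range is excluded from individual
#' comparisons). The 10 dB band is scanned outward from the peak: the
#' lower and upper edges are the outermost contiguous bins whose level
#' stays within 10 dB of the peak. Ties for the peak resolve to the
#' lowest-frequency maximal bin; an all-equal spectrum is flagged
#' degenerate.
#'
#' @param spec a `call_spectrum`.
#' @param analysis_band length-2 numeric, Hz.
#' @return object of class `spectral_features`: `peak_freq`, `bw10`,
#'   `lower10`, `upper10` (Hz), `degenerate`.
#' @export
spectral_features <- function(spec, analysis_band = c(11e3, 170e3)) {
  stopifnot(inherits(spec, "call_spectrum"))
  sel <- which(spec$freq >= analysis_band[1] & spec$freq <= analysis_band[2])
  if (length(sel) == 0) stop_arg("spectrum does not cover the analysis band")
  lev <- spec$level_db[sel]
  fr <- spec$freq[sel]
  degenerate <- length(unique(lev)) == 1
  pk <- which.max(lev)  # first maximal bin
  cut <- lev[pk] - 10
  lo <- pk
  while (lo > 1 && lev[lo - 1] >= cut) lo <- lo - 1
  hi <- pk
  while (hi < length(lev) && lev[hi + 1] >= cut) hi <- hi + 1
  structure(list(
    peak_freq = fr[pk], lower10 = fr[lo], upper10 = fr[hi],
    bw10 = fr[hi] - fr[lo], degenerate = degenerate
  ), class = "spectral_features")
}

#' Tonality score of a call segment
#'
#' Surrogate for aural/visual tonal-vs-pulsed judgement: fraction of
#' spectral energy concentrated around the five largest peaks of the
#' cepstrally smoothed log spectrum. Near 1 for narrowband tonal calls,
#' small for broadband pulse trains. The default decision threshold used
#' by [categorize_call()] is 0.6.
#'
#' @param waveform call samples.
#' @param fs sampling rate, Hz.
#' @param nfft FFT size for the long-window spectrum.
#' @param n_keep cepstral coefficients kept for smoothing.
#' @param peak_halfwidth bins on each side of a peak counted as its
#'   energy.
#' @return scalar in [0, 1].
#' @export
tonality_score <- function(waveform, fs, nfft = 4096, n_keep = 60,
                           peak_halfwidth = 2) {
  n <- length(waveform)
  if (n < nfft) waveform <- c(waveform, numeric(nfft - n))
  starts <- seq(1, max(1, length(waveform) - nfft + 1), by = nfft / 2)
  w <- signal::hamming(nfft)
  P <- rowMeans(vapply(starts, function(s) {
    sp <- stats::fft(waveform[s:(s + nfft - 1)] * w)
    Mod(sp[1:(nfft / 2 + 1)])^2
  }, numeric(nfft / 2 + 1)))
  P <- pmax(P, .Machine$double.xmin)
  logP <- log(P)
  # cepstral smoothing: keep low quefrencies
  cep <- stats::fft(c(logP, rev(logP[-c(1, length(logP))])))
  m <- length(cep)
  mask <- numeric(m)
  mask[c(1:n_keep, (m - n_keep + 2):m)] <- 1
  sm <- Re(stats::fft(cep * mask, inverse = TRUE)) / m
  sm <- sm[seq_along(logP)]
  pk <- local_maxima(sm)
  if (length(pk) == 0) return(0)
  pk <- pk[order(sm[pk], decreasing = TRUE)][seq_len(min(5, length(pk)))]
  sel <- unique(unlist(lapply(pk, function(i)
    max(1, i - peak_halfwidth):min(length(P), i + peak_halfwidth))))
  sum(P[sel]) / sum(P)
}

#' Measure categorization descriptors of a call segment
#'
#' Duration (envelope above 10% of its peak, first to last crossing --
#' robust whether the segment is mostly call or mostly silence),
#' tonality score, broadband coverage (fraction of 6-170 kHz bins within
#' 25 dB of the spectral maximum) and the number of disjoint spectral
#' components (contiguous regions within 25 dB separated by wide gaps).
#'
#' @param waveform call samples.
#' @param fs sampling rate, Hz.
#' @return list: `duration_s`, `tonality`, `band_coverage`,
#'   `n_components`.
#' @export
call_descriptors <- function(waveform, fs) {
  env <- envelope(waveform)
  thr <- 0.1 * max(env)
  idx <- which(env > thr)
  duration <- if (length(idx) >= 2) (idx[length(idx)] - idx[1]) / fs else 0
  nfft <- 4096
  pad <- if (length(waveform) < nfft) c(waveform, numeric(nfft - length(waveform))) else waveform
  starts <- seq(1, length(pad) - nfft + 1, by = nfft / 2)
  w <- signal::hamming(nfft)
  P <- rowMeans(vapply(starts, function(s) {
    sp <- stats::fft(pad[s:(s + nfft - 1)] * w)
    Mod(sp[1:(nfft / 2 + 1)])^2
  }, numeric(nfft / 2 + 1)))
  freq <- (0:(nfft / 2)) * fs / nfft
  in_band <- freq >= 6e3 & freq <= min(170e3, fs / 2 * 0.95)
  lev <- 10 * log10(pmax(P[in_band], .Machine$double.xmin) / max(P[in_band]))
  above <- lev >= -25
  coverage <- mean(above)
  r <- rle(above)
  comp_lengths <- r$lengths[r$values]
  gap_bins <- round(5e3 / (fs / nfft))  # gaps wider than ~5 kHz split components
  n_comp <- 0
  if (length(comp_lengths) > 0) {
    runs <- which(r$values)
    n_comp <- 1
    if (length(runs) > 1) {
      for (k in 2:length(runs)) {
        gap <- sum(r$lengths[(runs[k - 1] + 1):(runs[k] - 1)])
        if (gap > gap_bins) n_comp <- n_comp + 1
      }
    }
  }
  list(duration_s = duration, tonality = tonality_score(waveform, fs),
       band_coverage = coverage, n_components = n_comp)
}

#' Categorize a call into the five broad types
#'
#' Rule-based surrogate for aural/visual categorization, applied in
#' order: broadband pulsed energy lasting at least 150 ms -> `PS1`
#' (shorter broadband bursts -> `O`); two concurrent non-overlapping
#' spectral components with some broadband content -> `C1`; tonal calls
#' shorter than 150 ms -> `S`, 150 ms or longer -> `W`; everything else
#' -> `O`. The broadband test precedes the component count because a
#' pulsed call's common low-band energy peak can sit apart from its main
#' high-frequency lobe without making the call a combined type.
#'
#' @param duration_s call duration, s.
#' @param tonality tonality score in [0, 1] (see [tonality_score()]).
#' @param band_coverage fraction of the analysis band with energy near
#'   the maximum.
#' @param n_components number of disjoint concurrent spectral components.
#' @param tonal_threshold tonality decision threshold.
#' @param coverage_threshold broadband decision threshold.
#' @return character: one of "PS1", "C1", "S", "W", "O".
#' @export
categorize_call <- function(duration_s, tonality, band_coverage,
                            n_components = 1, tonal_threshold = 0.6,
                            coverage_threshold = 0.4) {
  if (band_coverage >= coverage_threshold && tonality < tonal_threshold) {
    if (duration_s >= 0.150) return("PS1")
    return("O")
  }
  if (n_components >= 2 && band_coverage >= 0.15 && tonality < 0.9)
    return("C1")
  if (tonality >= tonal_threshold) {
    if (duration_s < 0.150) return("S")
    return("W")
  }
  "O"
}

#' Full nine-parameter feature vector for one call
#'
#' Runs pulse detection output through [temporal_features()],
#' [pulse_spectrum()] at the middle pulse and [spectral_features()],
#' returning the nine-parameter row used by the individuality analysis.
#'
#' @param waveform recording channel containing the call.
#' @param train `pulse_train` of the call.
#' @param fs sampling rate, Hz.
#' @param analysis_band spectral analysis band, Hz.
#' @param label optional individual label.
#' @return one-row data.frame of class `call_features`: `call_id`,
#'   `label`, the five temporal and four spectral parameters, and flags.
#' @export
call_features <- function(waveform, train, fs, analysis_band = c(11e3, 170e3),
                          label = NA_character_) {
  contour <- extract_ipis(train)
  tf <- temporal_features(contour, train)
  n <- length(train$peak_times)
  mid <- if (n >= 5) select_pulse_locations(train)[["middle"]] else ceiling(n / 2)
  spec <- pulse_spectrum(waveform, train$peak_times[mid], fs,
                         pulse_location = "middle")
  sf <- spectral_features(spec, analysis_band)
  out <- data.frame(
    call_id = train$call_id,
    label = label,
    avg_ipi_11_20 = tf$avg_ipi_11_20,
    avg_ipi_11_20_last = tf$avg_ipi_11_20_last,
    duration_s = tf$duration_s,
    n_pulses = tf$n_pulses,
    prr = tf$prr,
    peak_freq = sf$peak_freq,
    bw10 = sf$bw10,
    lower10 = sf$lower10,
    upper10 = sf$upper10,
    truncated = tf$truncated,
    missing_averages = tf$missing_averages,
    degenerate_spectrum = sf$degenerate,
    stringsAsFactors = FALSE)
  class(out) <- c("call_features", class(out))
  out
}

#' Names of the nine candidate parameters
#' @return character vector of feature column names.
#' @export
feature_names <- function() {
  c("avg_ipi_11_20", "avg_ipi_11_20_last", "duration_s", "n_pulses",
    "prr", "peak_freq", "bw10", "lower10", "upper10")
}

#' Average relative power spectra
#'
#' Linear-power average of relative (0 dB = band maximum) spectra across
#' calls, re-normalized to the band maximum -- the per-individual
#' averaged spectrum from which representative peak frequencies and
#' 10 dB bandwidths are read.
#'
#' @param specs list of `call_spectrum` objects on a common bin grid.
#' @return a `call_spectrum` containing the averaged relative spectrum.
#' @export
average_spectra <- function(specs) {
  stopifnot(length(specs) >= 1)
  f0 <- specs[[1]]$freq
  P <- rowMeans(vapply(specs, function(s) {
    stopifnot(isTRUE(all.equal(s$freq, f0)))
    10^(s$level_db / 10)
  }, numeric(length(f0))))
  lev <- 10 * log10(P / max(P))
  structure(list(freq = f0, level_db = lev,
                 bin_width_hz = specs[[1]]$bin_width_hz,
                 time_res_ms = specs[[1]]$time_res_ms,
                 pulse_location = specs[[1]]$pulse_location),
            class = "call_spectrum")
}
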