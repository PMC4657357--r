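# Temporal and spectral feature extraction and call categorization.

fs <- 5e5

fake_train <- function(times) {
  structure(list(peak_times = times, call_id = 1, channel = 1, fs = fs,
                 empty = FALSE), class = "pulse_train")
}

test_that("constant-contour temporal parameters are exact", {
  tr <- fake_train(seq(0, by = 0.005, length.out = 101))
  tf <- temporal_features(extract_ipis(tr), tr)
  expect_equal(tf$avg_ipi_11_20, 5)
  expect_equal(tf$avg_ipi_11_20_last, 5)
  expect_equal(tf$duration_s, 0.5)
  expect_equal(tf$prr, 202)
  expect_equal(tf$prr * tf$duration_s, tf$n_pulses)  # exact identity
  expect_false(tf$truncated)
})

test_that("averaged IPIs match a direct-indexing oracle on a ramped contour", {
  p <- individual_profile("H0", ipi_initial_ms = 2.9, ipi_terminal_ms = 7.8,
                          plateau_pulses = 30, slope_ms_per_pulse = 0.05,
                          ipi_jitter_sd = 0, n_pulses_mean = 144)
  n <- 144
  ipis <- ipi_contour_template(p, n_pulses = n)
  tr <- fake_train(c(0, cumsum(ipis)) / 1000)
  tf <- temporal_features(extract_ipis(tr), tr)
  # independent oracle: rebuild the piecewise rule by hand
  oracle <- vapply(seq_len(n - 1), function(i) {
    if (i < 31) 2.9 else min(2.9 + 0.05 * (i - 30), 7.8)
  }, numeric(1))
  expect_equal(tf$avg_ipi_11_20, mean(oracle[11:20]), tolerance = 1e-9)
  expect_equal(tf$avg_ipi_11_20_last, mean(oracle[(n - 20):(n - 11)]),
               tolerance = 1e-9)
})

test_that("short trains flag truncated or missing averages", {
  tr10 <- fake_train(seq(0, by = 0.004, length.out = 10))
  tf10 <- temporal_features(extract_ipis(tr10), tr10)
  expect_true(tf10$missing_averages)
  expect_true(is.na(tf10$avg_ipi_11_20))
  expect_equal(tf10$duration_s, 9 * 0.004)
  tr15 <- fake_train(seq(0, by = 0.004, length.out = 15))
  tf15 <- temporal_features(extract_ipis(tr15), tr15)
  expect_true(tf15$truncated)
  expect_equal(tf15$avg_ipi_11_20, 4)  # available subset 11..14
})

test_that("representative pulse locations follow the (3, mid, n-2) rule", {
  expect_equal(unname(select_pulse_locations(7)), c(3, 4, 5))
  expect_equal(unname(select_pulse_locations(8)), c(3, 4, 6))
  expect_equal(unname(select_pulse_locations(5)), c(3, 3, 3))
  expect_error(select_pulse_locations(4), "5 pulses")
})

test_that("pulse spectrum is normalized to 0 dB at the band maximum", {
  tt <- (0:999) / fs
  x <- sin(2 * pi * 50e3 * tt)
  sp <- pulse_spectrum(x, 500 / fs, fs)
  expect_equal(sp$bin_width_hz, 1953.125)
  expect_equal(sp$time_res_ms, 0.512)
  in_band <- sp$freq >= 6e3 & sp$freq <= 170e3
  expect_equal(max(sp$level_db[in_band]), 0)
  sf <- spectral_features(sp)
  expect_lte(abs(sf$peak_freq - 50e3), sp$bin_width_hz)
  expect_error(pulse_spectrum(x, 1e-5, fs), "exceeds")
})

test_that("two-tone levels are preserved within 1 dB", {
  tt <- (0:999) / fs
  x <- sin(2 * pi * 60e3 * tt) + 10^(-10 / 20) * sin(2 * pi * 80e3 * tt)
  sp <- pulse_spectrum(x, 500 / fs, fs)
  near <- function(f0) {
    i <- which.min(abs(sp$freq - f0))
    max(sp$level_db[(i - 1):(i + 1)])
  }
  expect_equal(near(60e3), 0)
  expect_lt(abs(near(80e3) - (-10)), 1)
})

test_that("10 dB band edges match a brute-force scan of the spectrum", {
  p <- individual_profile("Y", 5, 5, plateau_pulses = 100,
                          slope_ms_per_pulse = 0, ipi_jitter_sd = 0,
                          n_pulses_mean = 10, spectral_peak_hz = 110e3,
                          spectral_bw10_hz = 60e3, amp_jitter_db_sd = 0)
  rc <- render_call(p, fs, rng_seed = 3, n_pulses = 10)
  sp <- pulse_spectrum(rc$wave, rc$truth$peak_times_s[5], fs)
  sf <- spectral_features(sp, c(11e3, 170e3))
  # oracle: independent outward scan over the computed spectrum grid
  sel <- sp$freq >= 11e3 & sp$freq <= 170e3
  lev <- sp$level_db[sel]
  fr <- sp$freq[sel]
  pk <- which(lev == max(lev))[1]
  lo <- pk; while (lo > 1 && lev[lo - 1] >= lev[pk] - 10) lo <- lo - 1
  hi <- pk; while (hi < length(lev) && lev[hi + 1] >= lev[pk] - 10) hi <- hi + 1
  expect_equal(sf$peak_freq, fr[pk])
  expect_equal(sf$lower10, fr[lo])
  expect_equal(sf$upper10, fr[hi])
  expect_equal(sf$bw10, fr[hi] - fr[lo])
  expect_true(sf$lower10 <= sf$peak_freq && sf$peak_freq <= sf$upper10)
})

test_that("a 0 dB plateau is bracketed with the peak at its first bin", {
  freq <- seq(0, 250e3, by = 1953.125)
  lev <- rep(-40, length(freq))
  plateau <- freq >= 80e3 & freq <= 90e3
  lev[plateau] <- 0
  spec <- structure(list(freq = freq, level_db = lev,
                         bin_width_hz = 1953.125, time_res_ms = 0.512,
                         pulse_location = NA), class = "call_spectrum")
  sf <- spectral_features(spec)
  expect_equal(sf$peak_freq, min(freq[plateau]))
  expect_equal(sf$lower10, min(freq[plateau]))
  expect_equal(sf$upper10, max(freq[plateau]))
})

test_that("per-individual averaged spectra recover the profile peaks", {
  pack <- default_profile_pack(spectral_jitter_cv = 0)
  for (lab in names(pack)) {
    specs <- lapply(1:4, function(k) {
      rc <- render_call(pack[[lab]], fs, rng_seed = 400 + k)
      mid <- select_pulse_locations(rc$truth$n_pulses)[["middle"]]
      pulse_spectrum(rc$wave, rc$truth$peak_times_s[mid], fs)
    })
    avg <- average_spectra(specs)
    sf <- spectral_features(avg, c(11e3, 170e3))
    expect_lte(abs(sf$peak_freq - pack[[lab]]$spectral_peak_hz),
               avg$bin_width_hz)
  }
})

test_that("categorization rules reproduce the five broad types", {
  # descriptor-level rules
  expect_equal(categorize_call(0.7, 0.05, 0.6, 1), "PS1")
  expect_equal(categorize_call(0.10, 0.9, 0.02, 1), "S")
  expect_equal(categorize_call(0.40, 0.9, 0.02, 1), "W")
  expect_equal(categorize_call(0.40, 0.5, 0.25, 2), "C1")
  expect_equal(categorize_call(0.05, 0.05, 0.6, 1), "O")   # short burst
  expect_equal(categorize_call(0.40, 0.3, 0.05, 1), "O")   # unresolvable
})

test_that("measured descriptors route rendered calls to their types", {
  rc <- render_call(default_profile_pack()$G, fs, rng_seed = 8)
  d <- call_descriptors(rc$wave, fs)
  expect_equal(categorize_call(d$duration_s, d$tonality, d$band_coverage,
                               d$n_components), "PS1")
  tone <- function(dur_s, f0 = 9e3) {
    tt <- (0:(dur_s * fs - 1)) / fs
    c(numeric(5000), sin(2 * pi * f0 * tt), numeric(5000))
  }
  ds <- call_descriptors(tone(0.1), fs)
  expect_equal(categorize_call(ds$duration_s, ds$tonality, ds$band_coverage,
                               ds$n_components), "S")
  dw <- call_descriptors(tone(0.4), fs)
  expect_equal(categorize_call(dw$duration_s, dw$tonality, dw$band_coverage,
                               dw$n_components), "W")
  # concurrent low tone + narrowband high pulse train -> combined call
  p <- individual_profile("c", 4, 4, plateau_pulses = 100,
                          ipi_jitter_sd = 0, n_pulses_mean = 60,
                          spectral_peak_hz = 100e3, spectral_bw10_hz = 30e3,
                          amp_jitter_db_sd = 0)
  rcc <- render_call(p, fs, rng_seed = 1, n_pulses = 60)
  w <- rcc$wave + 0.01 * sin(2 * pi * 8e3 * seq_along(rcc$wave) / fs)
  dc <- call_descriptors(w, fs)
  expect_equal(categorize_call(dc$duration_s, dc$tonality, dc$band_coverage,
                               dc$n_components), "C1")
})
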