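# Synthetic scene generation: IPI contour templates, call rendering,
# session rendering with geometry and ground truth.

fs <- 5e5

const_profile <- function(n = 11, jitter = 0) {
  individual_profile("X", ipi_initial_ms = 5, ipi_terminal_ms = 5,
                     plateau_pulses = 200, slope_ms_per_pulse = 0,
                     ipi_jitter_sd = jitter, n_pulses_mean = n,
                     amp_jitter_db_sd = 0)
}

test_that("jitter-free constant template yields exactly the template", {
  ipis <- ipi_contour_template(const_profile(), n_pulses = 11)
  expect_length(ipis, 10)
  expect_equal(ipis, rep(5, 10))
  expect_error(ipi_contour_template(const_profile(), n_pulses = 1),
               "n_pulses")
})

test_that("rising adult-male-like contour has lower early than late IPIs", {
  p <- individual_profile("H0", ipi_initial_ms = 2.9, ipi_terminal_ms = 7.8,
                          plateau_pulses = 30, slope_ms_per_pulse = 0.05,
                          ipi_jitter_sd = 0, n_pulses_mean = 144)
  ipis <- ipi_contour_template(p, n_pulses = 144)
  n <- length(ipis)
  expect_lt(mean(ipis[11:20]), mean(ipis[(n - 9):n]))
  expect_equal(mean(ipis[11:20]), 2.9, tolerance = 1e-12)
})

test_that("IPI jitter has the configured scale", {
  p <- const_profile(jitter = 0.5)
  draws <- vapply(1:1000, function(k)
    ipi_contour_template(p, n_pulses = 5, rng_seed = k)[3], numeric(1))
  expect_lt(abs(sd(draws) - 0.5) / 0.5, 0.20)
})

test_that("rendered pulse spectrum peaks at the profile setting", {
  p <- individual_profile("Y", 5, 5, plateau_pulses = 100,
                          slope_ms_per_pulse = 0, ipi_jitter_sd = 0,
                          n_pulses_mean = 10, spectral_peak_hz = 110e3,
                          spectral_bw10_hz = 90e3, amp_jitter_db_sd = 0)
  rc <- render_call(p, fs, rng_seed = 3, n_pulses = 10)
  sp <- pulse_spectrum(rc$wave, rc$truth$peak_times_s[5], fs)
  sf <- spectral_features(sp)
  expect_lte(abs(sf$peak_freq - 110e3), sp$bin_width_hz)
})

test_that("tonal component produces a narrowband line, absent otherwise", {
  mk <- function(tonal) individual_profile(
    "Ht", 2.9, 7.8, plateau_pulses = 30, ipi_jitter_sd = 0,
    n_pulses_mean = 80, spectral_peak_hz = 113e3, spectral_bw10_hz = 126e3,
    tonal_freq_hz = tonal, amp_jitter_db_sd = 0)
  long_level_13k <- function(rc) {
    i0 <- rc$truth$peak_samples[10]
    i1 <- rc$truth$peak_samples[40]
    x <- rc$wave[i0:i1]
    n <- 2^floor(log2(length(x)))
    P <- Mod(stats::fft(x[1:n] * signal::hamming(n))[1:(n / 2 + 1)])^2
    f <- (0:(n / 2)) * fs / n
    10 * log10(P[which.min(abs(f - 13e3))] / max(P))
  }
  with_t <- long_level_13k(render_call(mk(13e3), fs, rng_seed = 4, n_pulses = 80))
  without <- long_level_13k(render_call(mk(NULL), fs, rng_seed = 4, n_pulses = 80))
  expect_gt(with_t - without, 20)
})

test_that("silent profile renders an all-zero waveform", {
  p <- const_profile()
  p$source_level_db <- -Inf
  rc <- render_call(p, fs, rng_seed = 1, n_pulses = 10)
  expect_true(all(rc$wave == 0))
})

test_that("Nyquist violation is rejected", {
  p <- individual_profile("Z", 5, 5, n_pulses_mean = 10,
                          spectral_peak_hz = 160e3, spectral_bw10_hz = 120e3)
  expect_error(render_call(p, fs = 300e3, rng_seed = 1, n_pulses = 10),
               "Nyquist")
})

test_that("session truth TDOA follows the geometry", {
  pk <- light_pack()
  # source equidistant from both hydrophones -> TDOA 0
  sc0 <- session_scene(pk, isolated = "A", n_calls = 2, snr_db = 30,
                       seed = 5, fs = 250e3, isolated_fraction = 1,
                       isolated_region = rbind(x = c(3.75, 3.75),
                                               y = c(2, 2), z = c(-1, -1)))
  rec0 <- render_session(sc0)
  expect_equal(rec0$truth[[1]]$tdoa_s, 0)
  # path difference 1.5 m at 1500 m/s -> TDOA exactly 1 ms
  sc1 <- session_scene(pk, isolated = "A", n_calls = 2, snr_db = 30,
                       seed = 5, fs = 250e3, isolated_fraction = 1,
                       isolated_region = rbind(x = c(3, 3), y = c(0, 0),
                                               z = c(-1, -1)))
  rec1 <- render_session(sc1)
  expect_equal(rec1$truth[[1]]$tdoa_s, 1e-3, tolerance = 1e-12)
  # geometric bound: |TDOA| <= spacing / c for every call
  sc <- session_scene(pk, isolated = "B", n_calls = 6, snr_db = 30,
                      seed = 6, fs = 250e3)
  rec <- render_session(sc)
  td <- vapply(rec$truth, `[[`, numeric(1), "tdoa_s")
  expect_true(all(abs(td) <= 7.5 / 1500 + 1e-12))
})

test_that("identical scenes render bit-identical sessions", {
  sc <- session_scene(light_pack(), isolated = "A", n_calls = 3,
                      snr_db = 25, seed = 17, fs = 250e3)
  r1 <- render_session(sc)
  r2 <- render_session(sc)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)
})

test_that("default pack is qualitatively ordered like the study animals", {
  pack <- default_profile_pack()
  set.seed(31)
  stats_by <- lapply(pack, function(p) {
    contours <- lapply(1:20, function(k)
      ipi_contour_template(p, n_pulses = 80))
    list(
      avg_11_20 = mean(vapply(contours, function(v) mean(v[11:20]),
                              numeric(1))),
      roughness = mean(vapply(contours, function(v) sd(diff(v)),
                              numeric(1))))
  })
  avg <- vapply(stats_by, `[[`, numeric(1), "avg_11_20")
  rough <- vapply(stats_by, `[[`, numeric(1), "roughness")
  # the adult male opens with the shortest IPIs; the calf's contour is
  # by far the least stereotyped pulse-to-pulse
  expect_equal(names(which.min(avg)), "H")
  expect_equal(names(which.max(rough)), "M")
})

test_that("16-bit WAV round trip preserves samples and rate", {
  set.seed(8)
  x <- matrix(runif(2000, -0.9, 0.9), ncol = 2)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, fs = 48000, normalize = FALSE)
  back <- read_wav(path)
  expect_equal(back$fs, 48000)
  expect_equal(dim(back$samples), dim(x))
  expect_lt(max(abs(back$samples - x)), 1 / 32767)
})

test_that("scene YAML round trip reproduces the same session", {
  sc <- session_scene(light_pack(), isolated = "B", n_calls = 2,
                      snr_db = 25, seed = 23, fs = 250e3)
  path <- tempfile(fileext = ".yaml")
  write_scene_yaml(sc, path)
  sc2 <- read_scene_yaml(path)
  expect_identical(render_session(sc)$samples, render_session(sc2)$samples)
})
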