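# Shared synthetic corpora, built once per test run and cached.
# - corpus_bank(): 30 calls per individual from the default profile pack
#   at 20 dB SNR, detected and featurized (the parameter-recovery and
#   classification corpus).
# - corpus_tdoa(): ten 10-call two-hydrophone sessions (100 calls) with
#   the isolated caller cycling through the pack, analyzed end to end
#   (the attribution corpus).

.corpus_cache <- new.env(parent = emptyenv())

corpus_bank <- function() {
  if (is.null(.corpus_cache$bank)) {
    .corpus_cache$bank <- simulate_call_bank(
      default_profile_pack(), n_per = 30, snr_db = 20, seed = 101)
  }
  .corpus_cache$bank
}

corpus_tdoa <- function() {
  if (is.null(.corpus_cache$tdoa)) {
    pack <- default_profile_pack()
    labs <- names(pack)
    .corpus_cache$tdoa <- lapply(1:10, function(k) {
      sc <- session_scene(pack, isolated = labs[(k - 1) %% 5 + 1],
                          n_calls = 10, snr_db = 20, seed = 200 + k)
      rec <- render_session(sc)
      ana <- analyze_session(rec$samples, rec$fs, rec$zone)
      list(rec = rec, ana = ana)
    })
  }
  .corpus_cache$tdoa
}

# quiet, fast two-caller pack for pipeline plumbing tests (low pulse
# counts, spectra inside a 250 kHz Nyquist)
light_pack <- function() {
  list(
    A = individual_profile("A", ipi_initial_ms = 4, ipi_terminal_ms = 6,
                           plateau_pulses = 8, slope_ms_per_pulse = 0.2,
                           ipi_jitter_sd = 0.1, n_pulses_mean = 28,
                           n_pulses_sd = 2, spectral_peak_hz = 60e3,
                           spectral_bw10_hz = 30e3),
    B = individual_profile("B", ipi_initial_ms = 7, ipi_terminal_ms = 9,
                           plateau_pulses = 8, slope_ms_per_pulse = 0.2,
                           ipi_jitter_sd = 0.1, n_pulses_mean = 24,
                           n_pulses_sd = 2, spectral_peak_hz = 90e3,
                           spectral_bw10_hz = 30e3)
  )
}

# brute-force leave-one-out QDA oracle: per-fold Gaussian refit,
# independent of the package implementation
loocv_refit_oracle <- function(x, g, prior) {
  x <- as.matrix(x)
  g <- factor(g)
  lv <- levels(g)
  vapply(seq_len(nrow(x)), function(i) {
    xt <- x[-i, , drop = FALSE]
    gt <- g[-i]
    scores <- vapply(lv, function(l) {
      xi <- xt[gt == l, , drop = FALSE]
      S <- cov(xi)
      as.numeric(-0.5 * determinant(S)$modulus -
                   0.5 * mahalanobis(x[i, , drop = FALSE], colMeans(xi), S) +
                   log(prior[l]))
    }, numeric(1))
    lv[which.max(scores)]
  }, character(1))
}

# permutation-null LOOCV rate (%) over n_perm label permutations
permutation_null_rate <- function(x, labels, n_perm = 20, seed = 1) {
  rates <- pulsecall:::with_seed(seed, {
    replicate(n_perm, {
      qda_loocv(x, sample(labels))$overall_pct
    })
  })
  mean(rates)
}
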