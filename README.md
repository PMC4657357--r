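# pulsecall

Individuality analysis of odontocete pulsed contact calls from
two-hydrophone recordings.

Beluga whales exchange a stereotyped broadband pulsed call (the "PS1"
type) as a contact/isolation call. Whether such calls can carry caller
identity — the way bottlenose dolphin signature whistles do — is usually
assessed by measuring, per call, a handful of temporal and spectral
parameters, comparing their variation between and within individuals,
and asking how well a classifier can assign calls back to their callers.
`pulsecall` implements that entire workflow for researchers in
bioacoustics and animal communication:

* **Synthetic scene generation** — configurable caller profiles with
  individual inter-pulse-interval (IPI) contour templates, asymmetric
  spectral envelopes, an optional narrowband tonal component, and
  two-hydrophone session rendering (straight-path delays, 1/r spreading,
  a noise floor elevated below 5 kHz), every object carrying its ground
  truth. No field recordings are required to exercise or validate any
  stage.
* **Pulse detection** — analytic-envelope peak picking with a refractory
  minimum IPI, reflection (echo) rejection, and a secondary
  low-amplitude recovery pass; call segmentation over a session.
* **Caller attribution** — signed time-difference-of-arrival (TDOA) of
  each call across the hydrophone pair, and an interval test against the
  isolation-zone TDOA range (verdicts: `isolated`, `other`,
  `ambiguous`).
* **Feature extraction** — the five temporal parameters (average IPI of
  pulses 11–20, the mirrored average counted from the last pulse,
  duration, pulse count, pulse repetition rate PRR) and four spectral
  parameters (peak frequency, 10 dB bandwidth and its lower/upper edges)
  from Hamming/FFT-256 spectra with 5-point smoothing, relative-dB
  normalized over 6–170 kHz.
* **Individuality statistics** — the potential-for-individual-coding
  statistic

  `CVb = 100 · SD/mean` (all calls pooled),
  `CVw = 100 · (SD/mean) · (1 + 1/(4n))` (per individual, small-sample
  corrected), `PIC = CVb / mean(CVw)`;

  Kruskal–Wallis and one-way ANOVA group tests, VIF multicollinearity
  screening, robust (MCD) Mahalanobis outlier flagging, class-size
  balancing, quadratic discriminant analysis with jack-knife
  leave-one-out cross-validation, and forward stepwise feature ranking.

## Worked example

```r
library(pulsecall)

# five synthetic callers (one adult male, two adult females, one
# sub-adult, one calf) parameterized from published per-individual call
# statistics; 30 calls each at 20 dB SNR
pack <- default_profile_pack()
bank <- simulate_call_bank(pack, n_per = 30, snr_db = 20, seed = 101)

rep <- analyze_individuality(bank$features, bank$features$label, seed = 5)
format_pic_table(rep$pic)[c("parameter", "cvb", "mean_cvw", "pic")]
#>             parameter   cvb mean_cvw  pic
#> 1       avg_ipi_11_20 32.70    20.19 1.62
#> 2  avg_ipi_11_20_last 26.27    23.59 1.11
#> 3          duration_s 46.46    43.20 1.08
#> 4            n_pulses 42.72    32.76 1.30
#> 5                 prr 39.73    21.50 1.85
#> 6           peak_freq 39.35    25.46 1.55
#> 7                bw10 34.73    26.73 1.30
#> 8             lower10 82.28    37.92 2.17
#> 9             upper10 20.73    19.88 1.04

rep$dfa$overall_pct       # leave-one-out correct classification, %
#> [1] 91.33333
rep$stepwise$selected     # most informative parameters, in order
#> [1] "avg_ipi_11_20" "peak_freq" "avg_ipi_11_20_last"
```

PIC > 1 marks parameters whose between-individual variation exceeds the
within-individual variation — candidates for identity coding. Here the
initial averaged IPI and the PRR carry the most identity information,
duration carries almost none, and the stepwise ranking puts the averaged
IPI first followed by peak frequency, the same qualitative picture as in
captive-beluga isolation studies.

A full two-hydrophone session (rendering, segmentation, TDOA
attribution, features, statistics, report bundle):

```r
scene <- session_scene(pack, isolated = "T", n_calls = 10, snr_db = 20,
                       seed = 7)
bundle <- run_pipeline(list(mode = "full", scene = scene, seed = 7,
                            out_dir = "report"))
bundle$analysis$assignments   # per-call TDOA (ms) and verdict
```

A thin command-line wrapper (`inst/scripts/pulsecall.R`) exposes
`simulate` / `analyze` / `full` over scene YAML configs and 16-bit WAV
session audio.

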