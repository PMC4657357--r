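Package: pulsecall
Title: Individuality Analysis of Pulsed Contact Calls from Two-Hydrophone Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying individual distinctiveness in odontocete
    pulsed contact calls (e.g. beluga PS1 calls) recorded on a pair of
    hydrophones. Provides a ground-truthed synthetic scene generator with
    per-individual inter-pulse-interval (IPI) contour templates and spectral
    envelopes, envelope-based pulse detection with reflection rejection,
    time-difference-of-arrival attribution of calls to the isolated caller,
    extraction of the five temporal and four spectral call parameters,
    the potential-for-individual-coding (PIC) statistic built from between-
    and within-individual coefficients of variation, and quadratic
    discriminant classification of calls to individuals with jack-knife
    leave-one-out cross-validation and stepwise feature ranking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
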