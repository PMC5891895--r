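Package: localwake
Title: Local Use-Dependent Sleep in Wakefulness: Behavior, Delta Half-Waves and Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking use-dependent local sleep in the waking
    EEG to performance errors in a repeated wayfinding task. Provides behavioral
    change-point (breakpoint) detection and IQR-based error classification,
    Welch band-power estimation (delta and theta) grouped by behavioral
    condition, individual delta half-wave (off-period proxy) detection with
    amplitude-percentile thresholding, cluster-based permutation statistics over
    electrodes, nonparametric univariate statistics with effect-size
    conversions, and a recursive path model of learning-related use-dependent
    local sleep, together with synthetic behavioral and EEG data generators
    carrying full ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
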