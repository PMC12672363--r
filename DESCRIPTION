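Package: pressvigor
Title: Kinematics and Dopamine Photometry Analysis for Self-Paced Lever-Press Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing head-fixed self-paced lever-pressing sessions
    recorded together with striatal dopamine fiber photometry. Implements the
    online trial state machine (hold period, press/reward thresholds, reward
    delay, timeout, inter-trial interval, uncued mid-session threshold shift),
    offline press detection with movement-segment kinematics and let-go
    artifact exclusion, bootstrap median vigor statistics, photometry
    preprocessing (decimation, zero-phase Butterworth filtering, initial-epoch
    normalization, bleach-ratio correction against a saline reference),
    multitaper power spectra with a phasic 0.5-4 Hz excess index,
    event-triggered averaging, optogenetic artifact blanking and inpainting,
    and the session-level inferential layer (vigor-dopamine regression,
    mixed-effects session contrasts, normality-gated test selection, and
    many-to-one Dunnett comparisons). A synthetic-session generator with full
    ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    lme4,
    lmerTest,
    multcomp,
    arrow,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
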