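Package: stimspect
Title: Spectral, Phase-Locking and Oscillation Analysis of Stimulation-Evoked Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured intracranial EEG recorded
    during single-pulse transcranial magnetic stimulation (TMS) with sham
    control. Provides preprocessing (bipolar and common-average re-referencing,
    stimulation-artifact interpolation, multitaper F-test line-noise removal,
    anti-aliased downsampling, epoching), multitaper band power with
    pre-stimulus baseline correction, Morlet time-frequency decomposition,
    inter-trial phase locking with trial-count matching and mirror buffering,
    periodic/aperiodic spectral parameterization for per-trial oscillation
    detection, and hierarchical group statistics (contact-level t-statistics,
    intercept-only mixed models with Wald tests, Benjamini-Hochberg FDR).
    Includes a multi-subject synthetic-data generator with known injected
    evoked, induced and suppression effects for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
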