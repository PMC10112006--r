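Package: hgconn
Title: Dynamic High-Gamma Functional Connectivity for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts multichannel intracranial EEG recordings into
    millisecond-scale dynamic functional-connectivity networks. Implements
    event-related high-gamma (70-110 Hz) amplitude extraction by complex
    demodulation with a Gaussian finite-impulse-response filter,
    percent-change normalization against a pre-stimulus baseline,
    studentized-bootstrap significance testing of region-of-interest (ROI)
    timelines with a run-length criterion, detection of sustained high-gamma
    co-augmentation between ROI pairs gated by direct white-matter streamline
    adjacency, an analytic chance-probability (Type I error) bound for
    coincident significance runs, sliding-epoch dynamic connectome summaries,
    and nonparametric behavioral statistics (Friedman, Wilcoxon signed-rank,
    effect size r). A synthetic-data generator produces 1000-Hz
    common-average-referenced recordings with 1/f background noise and planted
    band-limited amplitude bursts with known ground truth, so that the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
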