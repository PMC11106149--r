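Package: rewardpace
Title: Behavioral Microstructure of Natural Reward Pacing in Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the temporal microstructure of natural reward seeking
    in male rats from annotated behavior logs and operant timestamp streams.
    Segments copulation ethograms into ejaculation series, mount bouts and
    time-outs; computes pacing and motivation measures (intromission ratio,
    post-ejaculatory intervals, censored latencies, percent-time budgets);
    scores sexual incentive motivation tests from arena tracking traces
    (zone occupancy, preference score, locomotion); analyzes fixed-ratio and
    progressive-ratio sucrose self-administration sessions (reward pacing
    curves, press-bout detection via scree-plot knee finding, breakpoints);
    counts c-Fos immunoreactive cells in brain-section images by particle
    analysis with size and circularity filters; and runs the matching
    post-hoc contrast layer (one-sample, paired and one-tailed independent
    t-tests with Bonferroni correction and a rank-based fallback). Includes
    synthetic generators with exact ground truth for every input stream so
    the whole pipeline is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    EBImage
Config/testthat/edition: 3
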