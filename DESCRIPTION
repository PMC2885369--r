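Package: sfpkit
Title: Single Feature Polymorphism Detection and Evaluation for
    Short-Oligomer Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, annotation, calling, and evaluation toolkit for
    single feature polymorphism (SFP) detection on Affymetrix-style 25-mer
    expression arrays. Generates synthetic genome pairs with planted
    variants, designs perfect-match/mismatch probe sets, and simulates
    genomic-DNA and transcript hybridization intensities with
    affinity-, amount-, and expression-dependent signal. Classifies probes
    by uniqueness against a reference genome with a BLASTN-equivalent
    local-alignment score, derives sequence-predicted SFP ground truth
    against a second genome, and calls SFPs from log10 perfect-match
    intensities by a two-class SAM permutation statistic, per-probe ANOVA,
    or robust within-probe-set outlier detection, in genome or transcript
    mode. Evaluation includes sensitivity and false-call-rate reports, ROC
    curves with slope-1 optimal threshold selection, nearest-neighbor
    duplex free-energy filtering, sliding-window genome tracks, and a
    binomial clustering test for false positives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
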