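---
title: "Detecting single feature polymorphisms on 25-mer expression arrays"
author: "sfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single feature polymorphisms on 25-mer expression arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfpkit)
```

## The problem

A single feature polymorphism (SFP) is a probe on a short-oligomer
expression array whose hybridization intensity differs between two strains
because the target sequence of one strain mismatches the 25-mer probe.
When both strains have sequenced genomes, the set of probes whose targets
are polymorphic can be predicted from sequence alone, which turns SFP
detection into a supervised problem: hybridize both strains (labeled
whole-genome DNA, or transcript-derived cRNA), call SFPs from the probe
intensities, and score the calls against the sequence-predicted truth.

sfpkit implements that whole loop at desk scale. A synthetic genome pair
with planted variants stands in for the two strains, so every stage —
probe uniqueness classification, intensity simulation, calling, and
evaluation — is testable end to end without any external data.

## Probe annotation

Probes are 25-mers; the mismatch (MM) partner of each perfect-match (PM)
probe substitutes the complementary base at position 13. Uniqueness is
decided by an exhaustive local-alignment search of both genome strands
under the classic nucleotide-search scoring (match +1, mismatch −3, gap of
length $k$ costing $5 + 2k$): a complete match scores 25, a single inner
mismatch 21 (distal mismatches trim to 24–22), a single inserted base in
the target 24 down to 18, and hits below 18 are discarded. A probe is
*unique* when it has exactly one hit and that hit is perfect; *multi-hit*
with two or more hits; *no-perfect-match* otherwise. SFP truth for a
unique probe is the absence of any perfect full-length match in the second
genome — a genome-wide criterion, so probes whose targets are duplicated
in the second genome are retained and count as non-SFPs.

The search is seeded by exact 11-mer matches. Under this scoring scheme,
any alignment scoring at least 18 must contain an exact run of at least 11
bases (a gapless hit at 18 tolerates one inner mismatch and at least 21
matching bases, whose longer run is at least 11; a gapped hit at 18 needs
all 25 bases matched around one gap), so the seeded scan is provably
complete at the default threshold and no fallback full scan is needed.
Candidate diagonals within 5 bp are merged so one locus is scored once.

## The intensity model

`simulate_intensities()` draws log10 intensities as

$$ y = \ell + \beta\,(\Delta G - \overline{\Delta G}) + s + \varepsilon $$

* $\ell$ — signal level: baseline plus an additive amount-class term
  (1/5/40 µg of labeled product) in gDNA mode, or a per-gene expression
  draw in transcript mode;
* $\beta$ — affinity slope (default −0.08 per kcal/mol): stronger-binding
  probes are brighter. $\Delta G$ is the nearest-neighbor duplex free
  energy at the 50 °C wash temperature (below);
* $s$ — strain term: probes whose footprint overlaps a planted variant
  lose a per-probe lognormal effect (mean 0.5, SD 0.35 log10 units) in
  strain B; optionally the effect shrinks for strong binders
  (`sfp_affinity_coupling`);
* $\varepsilon$ — Gaussian noise (default SD 0.15 log10 units).

Two distortions then act on the raw scale. A non-specific
cross-hybridization background adds to the specific signal; its level
rises with the applied amount *faster* than the specific signal
(`crosshyb_amount_slope`, default 2), because non-specific binding does
not saturate the way specific targets do. This additive background is
what makes high amounts counterproductive: it floors weak signals, props
up the intensity of mismatched targets, and thereby erodes the very
deficit the callers look for. Finally the total is soft-capped at the
scanner saturation ceiling (a smooth soft-minimum; the upper tail
compresses without hard clipping). MM probes follow the same model minus
a fixed penalty (default 0.45 log10).

A note on why the background, not the ceiling, carries the
amount-dependence: noise in this model enters before any squashing, and a
smooth monotone squash applied identically to all replicates compresses
the between-strain deficit and the noise by nearly the same local factor,
leaving the signal-to-noise ratio — and hence any calibrated test —
almost unchanged. A ceiling alone therefore cannot reproduce the observed
inferiority of the 40 µg condition. An additive background can, because
it is asymmetric: it lifts the low (mismatched, strain-B) side of the
comparison while leaving the bright side untouched.

Defaults were chosen once as the package's standing study conditions:
SNP rate 0.004/bp (4 SNPs per kb, one expected SFP probe in ten), four
gDNA and five transcript replicates per strain, amount classes 1/5/40 µg,
sets of 11 probe pairs inside 400 bp spans. The lognormal spread of the
SFP effect (SD 0.35) encodes that a central mismatch in a GC-rich probe
behaves very differently from a terminal one in an AT-rich probe; it puts
operating sensitivities in the tens of percent, the regime real arrays
live in, rather than in a trivially separable one. The per-gene
expression law is a two-component normal mixture (40% low, means 1.5 and
3.2, SD 0.4 log10), so a controllable fraction of probe sets falls below
the 2.5 expression cutoff. Amplification-polymorphism mode
(`frag_dropout_rate`) drops random 100–250 bp fragments in strain B to
plant *clustered* false positives.

What the generator does not emulate: probe-specific cross-hybridization
(the background level is common to all probes), position-dependent
mismatch thermodynamics, fragment-level amplification chemistry, scanner
pixelation, or spatial artifacts. Passing tests therefore demonstrate
correctness of the statistical machinery under a faithful but idealized
signal model, not performance on real arrays.

## Binding affinity

`delta_g()` evaluates the unified nearest-neighbor parameter set for DNA
duplexes (16 dinucleotide stacks, duplex initiation terms for terminal
G·C and A·T pairs): $\Delta G(T) = \sum (\Delta H - T\Delta S)$ plus both
terminal initiation terms, at 323.15 K by default, no salt correction,
for the probe paired with its exact complement. Initiation and terminal
terms are included; since every 25-mer carries exactly two of them, the
choice shifts all values by a near-constant and does not affect
rank-based filtering. The table ships as a TSV
(`inst/extdata/nn_unified_1998.tsv`) and round-trips bit-exactly.
Typical random 25-mers land near −23 to −25 kcal/mol; `affinity_filter()`
keeps probes with $\Delta G$ strictly above −26 kcal/mol, dropping the
very strong binders that stay bright even over mismatched targets.

## The callers

All callers work on log10 *raw* PM intensities (`log_transform()`, floor
of 1 raw unit — no background correction, no normalization, which is
also the best-performing choice on real data).

**SAM** (two-class unpaired): $d_i = (\bar{x}_{B,i} - \bar{x}_{A,i}) /
(s_i + s_0)$ with $s_i$ the pooled standard error and $s_0$ chosen by the
standard coefficient-of-variation recipe over $s$-quantile windows.
Expected order statistics $\bar{d}_{(i)}$ come from strain-label
permutations — all balanced permutations when the groups allow it (36
for 4+4), otherwise all label assignments, capped at `n_perm` with a
seeded subsample. At threshold $\delta$ the loss-side cutoff is the
largest ranked $d$ whose deviation from its expectation reaches
$\delta$; everything at or below is called, so calls nest in $\delta$.

**ANOVA**: per-probe two-group test; the two-group $F$ equals the squared
pooled t. With the default one-sided direction (an SFP can only lose
intensity in the mismatched strain) the one-sided t tail probability is
used, which keeps the null false-call fraction at $\alpha$ exactly — a
two-sided p plus a direction gate would instead yield $\alpha/2$.

**SNEP-style robust outlier calling**: per probe set (or per random
pseudo-set of 500 probes in gDNA mode, where no transcript structure
exists), the per-probe mean differences $d_i$ are standardized by the
set's median and MAD (×1.4826), and a probe is called when the one-sided
lower normal tail of its z-score falls below $\alpha$ (the useful grid
spans $10^{-6}$ down to $10^{-18}$). This median/MAD surrogate keeps the
estimator's intent — an SFP is an *outlier* among its set's differences,
robust to set-wide expression shifts — without reproducing the original
estimator; its thresholds are not claimed to coincide numerically with
that implementation, and the MAD's small-sample bias can inflate tail
calls by a bounded factor (the null-calibration test tolerates 2×).
Transcript mode first drops sets with fewer than seven unique probes and,
via `expression_filter()`, sets whose median log10 intensity is not above
2.5 in both strains — below that level PM and MM probes barely separate,
so intensity carries no sequence signal.

Sidedness is a deliberate design choice exposed as a flag on every
caller: the physics says mismatches reduce binding, so loss-side calling
is the default, but two-sided calling is available.

## Evaluation

`evaluate_calls()` reports the field's two headline ratios: sensitivity
(true calls / sequence-predicted SFPs) and the false-call rate fpr
(false calls / all calls) — note this is a false-discovery proportion,
*not* 1 − specificity; the conventional 1 − specificity is emitted
alongside under an explicit name to prevent misuse, and fpr is defined
as 0 when nothing is called. `roc_curve()` strings nested call sets from
strict to loose; `optimal_threshold()` returns the threshold where the
adjacent-point secant slope of sensitivity against fpr first reaches 1 —
the point where one more false call stops buying a true call — using raw
secants rather than smoothing (reproducible, no bandwidth parameter),
with ties broken toward the stricter threshold and a warning when the
slope never crosses 1. `window_track()` produces left-aligned, 0-based
half-open sliding windows (1 Mb window, 0.1 Mb step by default) with
per-window counts and sensitivity, leaving sensitivity *missing* (not
zero) where a window holds no predicted SFP so that genome-wide averages
are not deflated. `fp_cluster_test()` compares the per-set counts of
false positives against the binomial expectation
$\sum_{\text{sets}} \binom{n_{set}}{k} p^k (1-p)^{n_{set}-k}$, using as
$n_{set}$ the probes actually at risk of a false call (the non-SFP
probes of the set); clustered amplification-polymorphism artifacts show
up as an excess at $k \ge 2$.

## A worked example

```{r example}
params <- sim_params()
gp <- generate_genome_pair(100000, params, seed = 1)
gp
probes <- design_probe_sets(gp, n_sets = 100, seed = 2)
im <- simulate_intensities(probes, gp, mode = "gdna", amount_class = 5,
                           params = params, seed = 3)
im
lmx <- log_transform(im)
truth <- data.frame(probe_id = im$probes$probe_id,
                    sfp_truth = im$probes$sfp_truth)
fit <- sam_fit(lmx, seed = 4)
calls <- sam_call(fit, delta = 0.378)
evaluate_calls(calls, truth)
```

The alignment-based annotation reproduces the planted truth exactly on
synthetic genomes of this size:

```{r annotation}
ann <- classify_probes(probes, gp$seq_a)
ann <- predict_sfp_truth(ann, probes, gp$seq_b)
table(alignment = ann$sfp_truth, planted = truth$sfp_truth)
```

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally and in
  BED-like exports; human-readable reports are 1-based and say so.
* `log_transform()` floors raw values at 1 unit, so zero intensity maps
  to log10 = 0 and the log never diverges.
* ANOVA with zero within-group variance: identical constants give p = 1
  (uninformative, never called); an exact separation gives p = 0 and is
  flagged `degenerate`.
* SNEP sets with zero robust scale are skipped with a warning rather
  than dividing by zero.
* `choose_s0()` on all-equal standard errors returns a configured
  fraction of that value with a warning.
* Random pseudo-set remainders of at least 50 probes form their own
  group; smaller remainders merge into the last group, deterministically
  under the seed.
* All randomness flows through explicit integer seeds (`withr`-scoped,
  so the global RNG state is never disturbed); the pipeline writes a
  seed manifest next to its outputs.

## Problem sizes

The shipped tests run the full stack on genome pairs of 20–500 kb with
up to ~10,000 probes: large enough that binomial checks on planted
variant counts, regression recovery of the affinity slope, and
caller-calibration checks over 20 seeds are sharp, while the whole suite
stays interactive. Replicate counts follow the study conditions (4 gDNA,
5 transcript); one figure-level analysis in the source study used four
transcript replicates, so the counts are configurable rather than fixed.

## Known limitations

* The SNEP surrogate (median/MAD + normal tail) approximates the
  original set-outlier estimator; absolute significance levels are not
  comparable between the two.
* Sequence-predicted truth is genome-wide ("no perfect hit anywhere"),
  so a deleted-but-duplicated target counts as a non-SFP; an
  orthology-restricted truth is not implemented.
* The scoring search interprets scores 25…18 only; multi-gap alignments
  and E-values are out of scope, as are unplaced contigs.
* gDNA pseudo-set grouping assumes exchangeable probes; strong regional
  trends (e.g. copy-number segments) would violate it.
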