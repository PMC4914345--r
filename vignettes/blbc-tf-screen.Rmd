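---
title: "An integrated three-assay screen for basal-like breast cancer transcription factors"
author: "blbcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated three-assay screen for basal-like breast cancer transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blbcscreen)
```

# The screening problem

Basal-like breast cancer (BLBC) — largely overlapping the clinically
defined triple-negative subtype (TNBC) — lacks the receptor targets that
endocrine and HER2-directed therapy exploit. One route to new targets is
to ask which transcription factors (TFs) are both *elevated* and *active*
specifically in basal-like tumors, and then which of those the tumor cells
actually need to grow. `blbcscreen` implements that strategy as a tested
pipeline with four layers:

1. **RNA screen** — a median-rank meta-analysis of TF differential
   expression (TNBC vs non-TNBC) across many expression cohorts.
2. **DNA screen** — over-representation of TF binding motifs in the
   promoters of a basal-like signature gene set, against a random control
   gene set, using TRANSFAC-style position weight matrices (PWMs).
3. **Protein screen** — a reference-normalized protein/DNA-binding array
   comparison between basal-like and luminal cell lines.
4. **Integration and follow-up** — candidates are TFs found by at least
   two of the three assays; a secondary siRNA growth screen classifies
   them by growth dependence and specificity, and survival analysis
   (Kaplan–Meier, log-rank, multivariate Cox) evaluates prognostic value.

Because the original inputs (a licensed motif library, a commercial
meta-analysis platform, raw array images, clinical cohorts) are not
redistributable, the package ships a seeded synthetic-data generator that
emulates every input with planted ground truth, so each stage — and the
pipeline end to end — is verified by recovery of known signal.

# The RNA stage: median-rank meta-analysis

Within each cohort, every gene gets a one-sided Welch two-sample *t*-test
p-value for higher expression in the case group (`dePValues()`). Welch's
unequal-variance form is used because the per-cohort test statistic of the
original meta-analysis platform is not published; Welch is the robust
default and reduces to Student's test when variances agree. Genes are
ranked by p-value within each cohort (ties averaged), and a gene's summary
statistic is its **median rank** across the cohorts that measured it. The
reported summary p-value is the p-value from the cohort that *realizes*
the median rank — a deliberate design point: the summary is always an
actually observed significance, not an interpolation.

Two conventions needed fixing where the rule is ambiguous:

* **Even cohort count.** The median is defined as the *less significant*
  (larger) of the two middle ranks, so a realizing cohort always exists
  and the choice is conservative. If several cohorts share the median
  rank, the largest of their p-values is reported, again conservative.
* **Degenerate tests.** A gene with zero variance in both groups and equal
  means gets p = 0.5, the one-sided p of *t* = 0 (with a warning); all
  p-values are clamped into (0, 1].

Selection keeps whitelist TFs with median-rank p below α = 0.05, raw. No
multiple-testing correction is applied because the screen's published rule
uses raw p-values; `selectCandidates(adjust = "BH")` exposes the
correction for users who want it.

A property worth knowing: under a global null with *k* ≥ 3 cohorts the
median-rank rule selects **far fewer** than α of the genes, because the
median of several uniform ranks concentrates near the middle of the list.
The aggregation is therefore conservative by construction, and the
package's null-calibration checks run single-cohort screens — where the
median-rank statistic reduces to the per-cohort test and α is the correct
nominal reference — plus a separate test asserting the multi-cohort null
rate stays below α.

# The DNA stage: signature set, controls, and motif over-representation

The signature gene set is the intersection, across three independent
cohorts, of genes case-elevated at one-sided p < 0.01
(`deriveSignatureGeneSet()`); controls are a seeded uniform sample of
genes outside the case-elevated sets (`sampleControlGenes()`). The
control draw is made once per run and recorded; resampling per run would
only add variance.

Promoters are the region from 1 kb upstream of the TSS through the end of
exon 1, on the gene's strand (`extractPromoters()`); interface tables are
1-based inclusive, internal arithmetic 0-based, and regions running off a
contig are truncated with a warning.

## Matrix similarity scoring

PWM scanning uses the information-weighted, min–max-normalized **matrix
similarity score**. With per-position base frequencies
$f_i(b)$ (counts plus a 0.25 pseudocount per base, so no frequency is
zero) and information weights $I(i) = \sum_b f_i(b)\,\ln 4 f_i(b)$,

$$\mathrm{MSS}(s) = \frac{S - S_{\min}}{S_{\max} - S_{\min}},\qquad
  S = \sum_i I(i)\, f_i(s_i),$$

so the consensus sequence scores exactly 1 and the worst sequence exactly
0; an `N` contributes the position minimum. The scan threshold defaults to
0.85, a conventional default for this score family; the original tool's
exact cutoffs are not published, so the threshold is an explicit,
documented parameter rather than a hidden constant. Both strands are
scanned and positions are reported 1-based on the forward strand,
deterministically ordered (position, then `+` before `-`). The scanner's
inner loop is compiled code; an exhaustive pure-R enumeration is kept in
the test suite as an independent oracle and the two are required to agree
on a thousand random instances.

## The enrichment test

Per promoter the statistic is binary occurrence (≥ 1 hit), not total site
count — this matches the "% of promoters" semantics of promoter-scanning
tools and keeps the binomial model well-defined. Both an upper-tail exact
binomial test (target hits at the control occurrence proportion) and a
one-sided Fisher exact test on the 2×2 occurrence table are computed; the
**binomial** p decides by default because the screen's methods name it,
while the Fisher p is carried in every record (the two disagree mildly on
small counts, and having both documented the discrepancy beats silently
choosing). When controls show zero occurrences the null proportion is
floored at 0.5/n to keep the test defined, with a warning.

# The protein stage

Spot intensities are divided by the reference (TFIID) spot of the same
membrane, making all values relative and removing membrane-level exposure
scale — rescaling a membrane by any constant provably leaves every
downstream number unchanged. Replicate membranes are averaged per cell
line, and the **cell line** (not the replicate) is the unit of
replication: the group comparison is a two-sided Student equal-variance
*t*-test on per-line means (4 vs 4 in the reference design). Pooling all
replicates (12 vs 12) is deliberately not the default: replicates of one
line share its biology, so pooling is anticonservative. The selection
filter is strict on both sides: fold change > 1.4 *and* p < 0.05; a fold
change of exactly 1.4 fails.

One subtlety the synthetic arrays expose: because every spot on a membrane
is divided by the *same* realized reference intensity, reference noise
couples all spots of that membrane. Per-motif tests remain correctly
calibrated, but *across* motifs of one array the tests are positively
correlated, so a nominal-level check must average over independent
arrays. The package's calibration therefore simulates many independent
null arrays and tests one motif per array.

# Integration, growth screen, survival

Integration is set arithmetic made reproducible: the candidate table marks
each gene's presence in the three assay outputs, candidates need at least
two, and output order is fixed (support descending, then alphabetical).
The seven Venn region counts are attached to every table and obey exact
identities that the tests assert on random sets.

The growth screen bins relative growth (percent of a non-targeting
control) as below 33, 33–66, above 66. An siRNA is **critical** when at or
below 66 — growth suppressed by at least a third — in at least two of the
basal-like lines. The 66 boundary is *inclusive*: the published
classification counts a non-basal line at exactly 66 as that hit's single
non-basal reduction, which forces the convention. Among critical hits,
zero reduced non-basal lines means basal-specific, one means moderately
specific, two or more means a general growth regulator. Calls use the
reported means only; the SDs are carried for display but do not enter the
rule. The package ships the published 29-siRNA × 6-line table as a
plain-text fixture and reproduces its printed structure exactly: 8
critical TFs, of which one (SOX11) is basal-specific, four moderately
specific, three general.

Survival analysis dichotomizes expression at the **median** by default
(the figure-legend convention) with the mean available — the source
material uses both, so the choice is an explicit logged parameter. The
Kaplan–Meier, log-rank and Cox machinery is delegated to the `survival`
package; Cox models use Efron tie handling because a dichotomized marker
produces heavy ties, with Breslow available for cross-checks. Hand-built
product-limit tables, a first-principles O−E/V log-rank computation, and
brute-force maximization of the explicit partial likelihood serve as
oracles in the tests. Missing tumor grade is retained as an explicit
level rather than dropped, mirroring how prognostic tables account for
it.

# The synthetic-data generator

One master seed expands into fixed per-generator substreams, so
regenerating one input never shifts another, and every generator is
byte-deterministic under a fixed seed. Defaults mirror the reference
study's dimensions: 15 cohorts, a 702-gene TF whitelist, a 117-gene
target set versus 1500 controls, a 345-motif library, 2 kb promoters,
triplicate arrays on 4 + 4 cell lines, a 1992-subject survival cohort
with ~70% censoring, and true survival log-hazards set to the published
prognostic-table values (marker HR 1.42, node 2.22, and so on).

Choices a user should know:

* **Expression**: unit-variance Gaussian log-expression; planted TFs get a
  mean shift of `effectSize` in the case group of every cohort; optional
  per-cohort gene dropout emulates platform differences.
* **Motifs**: sharply peaked synthetic count matrices (19 of 20
  observations on the consensus base, length 10), giving each motif an
  unambiguous consensus, a usable score range, and ~80% per-site
  detection at the 0.85 threshold.
* **Promoters**: i.i.d. background (uniform base composition by default,
  configurable GC), PWM-sampled sites overwritten at uniform positions in
  a `motifPlantRate` fraction of target promoters; insertion positions are
  recorded in the planted truth. A toy genome and 1-based gene table are
  emitted so promoter extraction can be round-tripped, with both strands
  represented.
* **Arrays**: lognormal baselines, mean-one multiplicative lognormal noise
  at CV `arrayCv`, a lognormal membrane exposure factor (removed by
  normalization), bound motifs multiplied by `arrayFc` in basal lines.
* **Growth**: planted critical TFs get mean growth 50 in basal lines and
  95 in non-basal lines; everything else centers at 100, with Gaussian
  noise of SD `growthNoiseSd`.
* **Survival**: exponential event times under exact proportional hazards
  (the simplest model satisfying the assumption exactly), covariates with
  realistic marginals, and independent uniform censoring whose upper bound
  is solved analytically so the expected censored fraction equals
  `censorRate`.

What the generator does **not** emulate: cross-gene correlation,
platform-specific intensity distributions, batch effects, sequence
composition structure (CpG islands), array spatial artifacts, or
informative censoring. Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under its stated model, not
robustness to every pathology of real data.

# Verification sizes and numerical choices

The test and acceptance runs use desk-scale problem sizes chosen so the
full suite completes in well under a minute of compute per stage: null
calibrations use 200 single-cohort screens of 100 TFs, a 250-motif
unplanted library against 117 target / 600 control promoters of 1 kb, and
250 independent null arrays; the end-to-end recovery run uses 5 cohorts ×
400 genes with 10 planted TFs in a 60 TF whitelist, 40 motifs, and 60/300
promoters; Cox recovery uses 200 cohorts of n = 2000. These sizes are the
package's own verification settings; the generator's defaults remain the
full study dimensions. The end-to-end synthetic screen annotates every
planted differential TF to a motif (remaining motifs cycle over the rest
of the whitelist) so the planted truth is structurally recoverable by the
motif-based assays — with fewer motifs than TFs, truth planted on
motif-less TFs could never reach two assays.

Numerical conventions: p-values are clamped into (0, 1]; the enrichment
null proportion is floored when controls are empty; near-zero variances
(at machine precision, as produced by noiseless simulations) are treated
as degenerate rather than fed to a *t*-test; score normalization rejects
matrices whose best and worst scores coincide (fully uniform PWMs);
sampling helpers save and restore the global RNG state.

# Limitations

The screen inherits the reference design's limits: raw-p selection at
every stage (by design, no FDR control), promoter-proximal motifs only
(no enhancers or conservation filtering), growth calls from point
estimates without uncertainty, and a motif→TF map that is an input rather
than a curated product. The published candidate counts (132 TFs, the
117-gene set, 95 motifs, 11 array motifs, 33 candidates) depend on
proprietary inputs and are not reproducible here; the package instead
verifies the machinery by oracle equivalence, null calibration, and
planted-truth recovery, and reproduces exactly those published results
whose inputs are printed — the growth-screen table and the integration
arithmetic.
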