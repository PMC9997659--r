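---
title: "Methods: junction-level splicing analysis, PSI, trait association, and force-ramp unfolding"
author: "spliceforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-level splicing analysis, PSI, trait association, and force-ramp unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceforce)
```

# Scope and model of the data

`spliceforce` implements the computational arc by which a non-annotated
cassette exon can be discovered from splice-junction read counts and
then characterized: differential junction expression (DJE) with
empirical-Bayes moderated statistics, classification of novel
junctions against a gene model, percent-spliced-in (PSI)
quantification from inclusion/skipping junction trios, robust
correlation of junction or event profiles with continuous sample
traits, in-silico RT-PCR validation of the implied isoforms, and — for
the mechanical side of the biology — detection of unfolding steps in
single-molecule force-ramp traces.

The observational unit of the expression modules is the *splice
junction*, keyed by the 1-based first and last base of its intron (the
STAR `SJ.out.tab` convention; every export states this in its
headers).  A `JunctionExperiment` is a `RangedSummarizedExperiment`
whose rows are junctions, whose single assay holds uniquely-mapping
read counts, and whose `colData` carries the per-sample library sizes
used for normalization.

# Junction annotation and novel-junction classes

A junction is assigned to the gene whose span contains its whole
intron; ties are broken by matching strand, then by the smallest gene
span, and anything still ambiguous is left unassigned — a
deterministic, conservative rule.  Against the assigned gene's
transcripts the junction is `annotated` when both splice sites *and*
their pairing occur between consecutive exons of some transcript;
`novel_combination` when both sites are known but never paired;
`novel_donor`/`novel_acceptor` when one site is unknown; `novel_both`
otherwise.  Donor/acceptor naming is strand-aware: the donor is the
transcription-upstream site, so on a minus-strand gene the donor is
the intron *end* boundary.  Junctions of each gene are indexed 1..n
along the direction of transcription, which makes splice-plot indices
of reverse-strand genes run right-to-left on the genome.

# Differential junction expression

Counts are filtered at a mean of 10 reads per junction, then
transformed to `log2 CPM` with the standard offsets
(`log2((count + 0.5) / (library_size + 1) * 1e6)`); the offsets are a
convention choice, stated here because the downstream moderation is
insensitive to them only to first order.

**Observation weights.** Each junction's logCPM is regressed on the
two-group design; a lowess trend of the square root of the residual
standard deviation against mean logCPM is interpolated at each
observation's fitted value, and the weight is the predicted
`sqrt-sd^-4`, i.e. inverse predicted variance.  This is the classical
mean-variance-trend weighting for overdispersed count data.  With a
single junction there is no trend to estimate and unit weights are
used.

**Moderated statistics.** Per-junction weighted least squares gives
the absolute log fold change; residual variances `s^2` with `d`
degrees of freedom are shrunk toward a prior `s0^2` with prior degrees
of freedom `d0` estimated by method of moments on `log s^2` (the
posterior `s_post^2 = (d0 s0^2 + d s^2)/(d0 + d)` always lies between
`s^2` and `s0^2`; `d0` is capped at `1e6` to represent infinity
finitely).  Two-sided p-values use a t distribution on `d0 + d`
degrees of freedom.  Setting the prior df to zero recovers the
ordinary weighted t-test exactly, which the tests exploit as an
oracle; the same quantities computed through `limma` serve as an
independent cross-check, never as the implementation.

**Relative logFC (usage).** A junction's relative log fold change is
its absolute logFC minus the mean absolute logFC of the gene's *other*
retained junctions — a difference-from-gene-average contrast that
isolates changes in usage from changes in overall gene expression.
Its variance combines the moderated variances of the junctions
entering the contrast (independence across junctions is assumed; this
is documented as an interpretation, since "usage" admits several
contrasts).  Genes with a single retained junction are flagged and
excluded from relative testing.

**Significance classes.** A junction is `up` iff its absolute logFC
exceeds the cutoff *and* both the absolute and the relative FDR are
below the level (default 0.05); `down` symmetric.  Reading
significance as a conjunction of the two statistics follows the
convention that junctions failing either test are displayed as
non-significant in splice plots.  The default cutoff is 1.0 in log2
units; 0.5 is conventional for milder condition contrasts and is a
plain argument.

# Cassette events and PSI

A cassette event is a trio: two inclusion junctions flanking the exon
plus one skipping junction spanning exactly the union of the two
flanking introns and the cassette.  The estimator is
`psi = mean(c_inc1, c_inc2) / (mean(c_inc1, c_inc2) + c_skip)`.  The
*mean* of the two inclusion junctions (not their sum) makes the
estimator unbiased for the true inclusion fraction when both flanks
have equal expected depth; with the sum, pure-inclusion samples would
be biased toward 1 at ratio 2:1.  Samples whose denominator is below
`min_cov` (default 10, aligned with the junction filter) are missing;
missing PSI is handled pairwise-complete everywhere, with no
imputation.  Cross-event Pearson correlation with BH adjustment across
all tested pairs screens for trans-mutually exclusive splicing
(strongly anti-correlated inclusion in different genes).

# Trait association

The biweight midcorrelation standardizes each vector by its median and
MAD with Tukey biweights (tuning constant 9), so single outliers
cannot dominate; a zero-MAD vector cannot be standardized and the
implementation falls back to Pearson with an explicit flag.  P-values
use the Student-t approximation on `n_used - 2` degrees of freedom —
standard bicor practice — with BH across all (feature, trait) pairs
and ranking by `|rho|`.  The radar export keeps pairs with FDR below
the level and `|rho|` above 0.2 and fixes the radial axis to
[-0.5, 0.5], the conventional display range.  Over-representation of a
selected gene list is a set-agnostic hypergeometric tail with BH
across sets; a preranked running-sum enrichment is deliberately not
implemented — the hypergeometric form is exactly testable against
closed forms, and gene-set databases are supplied by the user.

# In-silico RT-PCR

Primer matching is exact on both orientations; the published 18–23-mer
primers at stringent annealing justify omitting a mismatch model
(documented limitation).  Multiple binding sites produce all pairwise
products up to a 5 kb cap rather than erroring, mirroring multi-band
gels.  Insert translation locates the insert by prefix/suffix
comparison, rejects non-multiple-of-3 inserts as frameshifts, flags
in-frame stops, and verifies that deleting the insert restores the
original sequence.  Interval arithmetic is always explicit about its
convention: 1-based inclusive (`end - start + 1`) or half-open.

# Force-ramp traces

**Simulator.** Under a linear ramp `F(t) = f_start + r t`, a domain
with Bell–Evans kinetics `k(F) = k0 exp(F dx / kBT)` unfolds at a
force drawn from the exact closed-form quantile of the ramp survival
function.  To leading order the modal unfolding force is
`F* = (kBT/dx) log(r dx / (k0 kBT))`, which serves as an independent
oracle for the sampler; `bellEvansK0()` inverts it so a domain can be
parameterized by its modal force.  Each unfolding adds a fixed step to
the bead height; Gaussian noise of 1 nm emulates the instrument's
extension resolution at 200 Hz.  Defaults (1 pN/s, start 1 pN, ceiling
35 pN, three domains with modal forces near 5/15/25 pN and steps of
25/22/28 nm) emulate a talin R1–R3-like construct.  Refolding within a
scan is not simulated — one unfolding per domain per scan — matching
per-scan histogramming of unfolding forces.  Domains whose sampled
force exceeds the ramp ceiling are marked unresolved rather than
erroring.

**Detector.** Steps are found by penalized binary segmentation for
mean shifts on the height series: recursively split where the SSE gain
`n1 n2/(n1+n2) (m1-m2)^2` is maximal, accept splits whose gain exceeds
`3 sigma^2 log n` with `sigma` estimated robustly from first
differences, and keep positive jumps of at least `min_step` (default
10 nm — half the >20 nm scale of rod-domain unfolding steps).  On
step-plus-noise traces this mean-shift search is equivalent to
segmenting the differentiated series without an extra filtering stage,
so no derivative pre-filter is applied; baseline drift within a
segment is not modeled, and traces with strong drift would need
detrending first (known limitation).  Step times are reported at the
midpoint of the last pre-step and first post-step samples, which keeps
the assigned force unbiased to within half a sample interval
(0.0025 pN at 200 Hz and 1 pN/s).  Domain assignment for modal-force
reporting uses fixed force bands rather than unsupervised clustering —
simpler and deterministic — with the mode estimated as the kernel
density peak within each band.

# The synthetic cohort

The generator defines the study conditions for every expression-side
test: two groups of 60 samples each by default, 30 genes of 5
junctions, one cassette gene with inclusion fractions 0.7 (group A,
the case group) versus 0.05 (group B), expected junction abundance 100
at the nominal library size, negative-binomial dispersion 0.1, and
library sizes uniform on [0.8, 1.2] million.  The cassette exon is 51
nt wide, hidden from the annotation, centred in the middle intron of a
minus-strand gene, so discovery exercises the strand-aware novel
classes.  Usage conserves gene abundance: inclusion-path plus
skipping-path expected reads equal the gene abundance in every sample.
The negative-binomial noise model is an assumption — cohort-scale
junction counts have no published noise model — and is the
distribution the observation-weight machinery is designed for; library
sizes are drawn uniformly as a simple spread.  What the generator does
*not* emulate: positional read biases, shared splicing factors
coupling many events, unequal flank depths, annotation errors, or
batch structure.  Passing tests therefore demonstrate correctness of
the estimators and their calibration under the stated model, not
robustness to every artifact of real cohorts.

Default problem sizes used by the test suite (60 + 60 samples, ~150
junctions for the discovery cohort; 200 junctions for null
calibration; 500 scans for force histograms) were chosen as the
smallest cohorts at which the programmed effects are comfortably
resolved by the statistics themselves.

# Reproducibility

Every generator takes an explicit integer seed and restores the RNG
state afterwards; identical spec plus seed gives byte-identical
output.  `runPipeline()` validates its YAML/list configuration against
a closed key schema (unknown keys are an error naming the offending
keys), stamps each artifact directory with the package version and an
FNV-1a hash of the key-sorted configuration, and reproduces all data
artifacts byte-for-byte on re-run; the wall-clock timestamp lives only
in `run.log`, outside the identity guarantee.  This package is a
library with a function-level driver rather than a shell tool; the
exported functions and `runPipeline()` are the composition surface.

```{r example, eval = FALSE}
sim <- simulateCohort(cohortSpec())
je  <- filterJunctions(annotateJunctions(sim$junctions, sim$annotation))
dje <- fitDJE(je)
exportSplicePlot(dje, "G2")
```
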