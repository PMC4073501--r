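---
title: "Copy-number analysis of bovine aCGH panels: models and methods"
author: "cnvherd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of bovine aCGH panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Array comparative genomic hybridization (aCGH) co-hybridises test and
reference DNA on an oligo array; each probe reports
log2(test/reference) intensity. Against a two-copy reference, the expected
signal at a locus carried in CN copies is log2(CN/2): 0 for two copies,
-1 for one copy, +0.585 for three, +1 for four. `cnvherd` treats a sample's
profile as piecewise-constant in this expectation plus independent Gaussian
probe noise, the working model behind every downstream step.

```{r, eval = FALSE}
library(cnvherd)
cfg <- runConfig(seed = 7)
res <- runAll(cfg, outdir = "cnvherd_out")
res$report$counts
```

# Segmentation

Scanner-vendor segmentation software is proprietary; `segmentProfile()`
replaces it with an explicit, reproducible objective of the same modelling
intent (piecewise-constant means): minimise total within-segment sum of
squared deviations plus a per-segment penalty, solved *exactly* by an
O(n^2) dynamic program in compiled code. Ties are broken toward fewer
segments, then earliest breakpoints, so output is deterministic. Before
segmentation each sample is median-centred (`normalizeRatios()`), the
minimal analogue of array-level normalisation: the two-copy background sits
at 0.

`choosePenalty()` selects the penalty from a candidate grid by an
information criterion, `n log(SSE/n) + 2 K log(n)` for K segments. Each
segment is charged **two** parameters — its mean and its boundary. The
factor 2 matters: charging only one parameter per segment (`K log n`)
admits a spurious split on a pure-noise profile of n = 500 about a quarter
of the time, because the best of the n-1 candidate breakpoints behaves like
the maximum of many correlated test statistics and routinely buys more than
`log n` of fit. With 2 parameters per segment, pure-noise profiles stay
whole in roughly 99% of simulations while a genuine 10-probe,
1-log2-unit shift is still recovered to within one probe. The default grid
is geometric, scaled by a robust noise-variance estimate (median absolute
successive difference) times `log n`.

# CNV calling

A segment is a CNV when its mean log2 ratio is at least 0.5 in magnitude
(inclusive, so a mean of exactly -0.5 calls a loss) *and* it spans at least
5 consecutive probes. Calls carry only a direction, gain or loss — no
integer copy number is inferred from array magnitude, which saturates and
compresses. Two numerical choices are worth stating:

* Adjacent qualifying segments of the same state with no probes between
  them are merged into one call. An exact optimiser may split a long event
  into two segments of slightly different means; merging is conservative
  and does not change carrier frequencies.
* Whether a probe lies inside an event is decided at the probe midpoint,
  which is unambiguous for events that cut a probe.

The thresholds (`threshold = 0.5`, `minProbes = 5`) are exposed as
arguments; the mitochondrial contig carries exactly 5 probes by design, so
a whole-contig copy shift is callable under the same rule.

# CNVR aggregation and accounting

Per group, CNVRs (`buildCnvrs()`) are the connected components of the
interval-overlap graph over all samples' calls — the transitive union, so a
chain A∩B, B∩C becomes one region even if A and C never touch. Overlap
means at least one shared base under the package's 0-based half-open disk
convention; bookended intervals do not merge. A region's state is `both`
when its carriers include at least one gain and one loss call. Frequency
divides carrier count by the *group size*, not by the number of CNV-bearing
samples. Cross-group merging (`mergeGroups()`) applies the same closure
across groups' CNVR sets and records, per merged region, which groups
contributed — the Venn accounting of `vennCounts()`. `summarizeCnvrs()`
reports the per-group table (count, per-sample mean, single-carrier
"unique" regions, state counts, total length, percent of assembly) and
`chromCoverage()` the per-chromosome percentages.

# Gene/QTL annotation

`overlapFeatures()` computes, for every CNVR-feature pair, the overlap in
base pairs and its fraction *of the feature length* — the convention under
which "44.79% of a gene overlapped" reads naturally — and flags a positive
hit only when the fraction strictly exceeds 0.5: a gene covered at exactly
half is not contained. Strand is ignored; copy number is unstranded.

# Group structure: clustering and indicator values

The sample-by-CNVR presence matrix feeds two analyses. Hierarchical
clustering uses Jaccard distance with average linkage; an all-zero profile
(a sample carrying nothing) is defined to sit at distance 1 from any
non-identical profile and 0 from another all-zero one, since the Jaccard
ratio is undefined on empty unions.

Group-indicative CNVRs are scored by the classic indicator value on binary
presence: specificity `A_g` (group-g mean presence over the sum of group
means), fidelity `B_g` (fraction of group-g samples carrying the CNVR), and
statistic `max_g sqrt(A_g B_g)`, tested by permuting group labels with
`p = (1 + #{perm >= obs}) / (nPerm + 1)`. The variant (square-root IndVal
on presence/absence, no group-size equalisation) is the widely used default
and is an assumption — the choice of variant is rarely reported in applied
work. No multiplicity correction is applied by default, matching the
per-test alpha convention of superscript-letter tables; Benjamini-Hochberg
is available via `adjust = "BH"`.

**A calibration caveat.** On binary data with equal group sizes the
permutation statistic is a monotone function of the *maximum per-group
carrier count*, a heavily discrete quantity. With 3 groups of 8, exact
enumeration shows the achievable rejection rate at nominal alpha = 0.05 is
between 0 and ~4% depending on a column's carrier count (zero below 4 or
above 15 carriers), so the test's null false-positive rate measures near
1.5%, not 5%. This conservatism is a property of discrete permutation
tests at this panel size, not an implementation defect: the sampled
p-values match exhaustive enumeration exactly on small panels
(`indval(..., exact = TRUE)`). Interpret significant CNVRs as a
high-confidence set, and expect conservative behaviour on panels of a few
dozen samples.

# Copy number and expression from qPCR

`relativeCopyNumber()` implements the delta-delta-Ct chain: technical
replicates are averaged first; `dCt = Ct(target) - Ct(control gene)` per
sample; `ddCt` subtracts the two-copy calibrator's dCt; relative copy
number is `2^-ddCt`, so the calibrator is 1 by construction and each copy
doubling subtracts one expected cycle. Amplification efficiency is fixed at
2 (the method's assumption); efficiency correction is out of scope. Samples
are typed gain/loss/normal at RCN cutoffs 1.4 and 0.6 — chosen near the
midpoints between the two-copy value (1.0) and the three-copy (1.5) and
one-copy (0.5) values, widened for replicate noise; no published boundary
exists for this typing, so both cutoffs are arguments.
`expressionFoldChange()` is the same chain with an expression normaliser
gene, and `compareGroups()` contrasts fold changes between CNV types with
two-sided Welch t-tests (types with fewer than two samples are skipped).

# Trait association

`fitModel()` fits the additive fixed-effects model
`trait = mu + farm + genotype + breed + error` by ordinary least squares,
treating farm and breed as crossed factors; if they are confounded with
genotype the aliased coefficients are reported as an explicit error rather
than silently dropped. Least-squares means (`lsm()`) average model
predictions over the Cartesian grid of farm-by-breed levels with genotype
held fixed — equal cell weights, so in a balanced design the LSM equals the
raw genotype mean. Standard errors come from the corresponding linear
contrast and the coefficient covariance. Pairwise genotype contrasts use
t-tests on the residual degrees of freedom; significance letters are
assigned from the maximal cliques of the not-significantly-different graph,
so two levels share a letter exactly when they do not differ at alpha.
Missing trait values are dropped listwise per trait.

# The synthetic-data generator

`makeProbes()`, `plantEvents()`, `simulateRatios()`, `makeFeatures()`,
`simulateQpcr()` and `simulatePhenotypes()` emulate the statistical
structure the analysis assumes: a ~720k-probe layout at 3,364 bp mean
spacing scaled to a desk-size genome (default: five 10-Mb autosomes plus a
16-kb mitochondrial contig with exactly 5 probes), planted events of 0-4
copies with shared/group/private sharing structure and loss-heavy copy
weights, Gaussian probe noise on the log2 scale, group-level mitochondrial
copy shifts, qPCR Ct tables with one cycle per copy doubling, and
phenotypes drawn from the additive trait model. Probe gaps are uniform on
[0.5, 1.5] x spacing (a simple reading of "evenly distributed"); the CN = 0
expectation is floored at -3 log2 units because real arrays saturate rather
than report negative infinity; the Gaussian noise law is an assumption —
the noise distribution of real scanner output is not published.

What the generator does **not** emulate — dye-swap and normalisation
artifacts, GC-content bias, spatial array effects, probe-specific response,
real genome coordinates — bounds what passing tests show: they demonstrate
that the pipeline recovers the model it assumes, not that the model
captures every artifact of scanner data.

# Problem sizes and verification

The test-suite simulations are sized for desk-scale runtime: recovery runs
use 5 x 10 Mb chromosomes at 3 kb spacing (~16.7k probes) with 12 samples
in three groups and noise sd 0.2, where the pipeline's recall is >= 0.95
and precision >= 0.90 against planted truth; the dynamic program is checked
against exhaustive enumeration over all breakpoint patterns for n <= 12;
CNVR construction against a quadratic overlap-closure oracle; annotation
against per-base counting; IndVal against exact permutation enumeration on
6-sample panels; LSM against both a prediction-grid oracle and the
independent `emmeans` implementation. Recall misses at these settings are
almost exclusively three-copy gains whose segment mean (expectation 0.585,
standard error ~0.06 over 8+ probes) lands just below the inclusive 0.5
cutoff — the intrinsic marginality of CN = 3 on this noise level.

# Known limitations

* Segmentation equivalence with proprietary scanner software cannot be
  asserted; only the modelling intent is shared.
* The IndVal permutation test is conservative on small binary panels (see
  above).
* CNVR boundaries inherit probe resolution; no boundary refinement or
  reciprocal-overlap definition is provided.
* The association model is fixed-effects only: no covariates, repeated
  measures or mixed models.
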