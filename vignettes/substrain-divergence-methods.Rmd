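---
title: "Models and methods for substrain divergence analysis"
author: "SubstrainDrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for substrain divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubstrainDrift)
```

# The problem

An inbred mouse strain maintained by continued sibling mating accumulates
new spontaneous mutations, and each mutation that survives drifts to
homozygosity within a few generations. When colonies of the same strain
are bred separately — as the NOD substrains have been since the early
1980s — each colony fixes its own private set of mutations, and the
substrains diverge genetically even though they are all "the same"
strain. SubstrainDrift provides the quantitative machinery for studying
this process from homozygous variant calls: distance matrices and their
summaries, substrain distribution patterns, fixation-rate estimates,
small-panel phylogenies with a molecular-clock test, pooled-capture
artifact-rate estimation, and deletion calling from array probe
intensities. A simulation layer generates every input with the
statistical structure the analyses assume, so the whole pipeline is
testable without any external download.

# The drift model

Fixation is modeled as instantaneous: the analysis only ever sees fixed
homozygous differences (heterozygous calls are filtered on load), so the
transient segregating phase contributes nothing and is not simulated.
Along each branch of a dated genealogy (a `SeparationSchedule`, edge
lengths in years, converted at `generationsPerYear` — default 4, the
conventional breeding rate for mouse colonies), the number of fixed
mutations is Poisson with mean $\lambda \cdot g$ where $g$ is the branch
length in generations. A mutation that arises on a branch is carried by
exactly the substrains below that branch, which makes the expected
pairwise distance between tips $a$ and $b$ equal to
$\lambda \times (\text{generations on the } a\!\leftrightarrow\!b
\text{ path})$ — the property the Monte-Carlo tests verify.

The default parameters (`lambdaFix = 0.4` per lineage per generation
visible to the assay, 24% indels, 29% coding) were chosen once so that
the default five-substrain NOD genealogy yields totals of the same order
as the published exome screen (about 227 variants). The default
genealogy places the BomTac and Lt separations in 1984, MrkTac in 1985,
the ShiLt/ShiLtDvs split in 1992, treats ShiJcl as the continuation of
the source colony, and samples everything in 2014. The MrkTac date is
the one genuinely undocumented value (the progenitors moved through a
research colony in the mid-1980s); 1985 is a declared choice, and every
date is overridable through `SeparationSchedule()`, a dated newick
string, or a JSON schedule file. Variant positions are drawn uniformly
without replacement over a 20-chromosome mouse-like genome; recurrent
mutation is excluded.

# Distances, patterns and rates

`pairwiseDistance()` counts, per variant class, the sites at which two
substrains carry different homozygous alleles — a Hamming distance on
the 0/1 call matrix, hence symmetric, zero-diagonal and triangle-valid,
which the `DistanceMatrix` validity method enforces. Variants whose
alternate allele is carried by no substrain or by all substrains
distinguish no pair; `sdpTable()` flags them non-informative. Because
polarity against the reference genome is arbitrary for substrain
comparisons, "unique" variants (carried by exactly one substrain) and
complement-unique variants (all but one) are reported separately rather
than folded together.

`fixationRate()` divides each pair's coding distance by elapsed
separation time. Whether that time should count one lineage or two is a
genuine convention choice: both lineages accumulate mutations, so the
default divisor is $2\times$ years since the split, but the
`singleLineage = TRUE` flag reproduces the convention that reports the
pairwise count per calendar year of separation. Printed ranges are
rounded half-up to two decimals only at reporting time
(`roundHalfUp()`), never internally.

# Phylogenies and the molecular clock

SNP calls concatenate into an alignment with one column per SNP
(`genotypeToAlignment()`). Two tree estimators are provided, because
with a handful of taxa both are standard practice: neighbor joining on
the fixed-difference matrix (`njTree()`, with lexicographic tie-breaking
in the Q criterion and negative-branch clamping that shifts the deficit
to the sister edge, so results are deterministic and additive matrices
are recovered exactly), and maximum likelihood under the general
time-reversible model (`mlFit()`).

The GTR likelihood is computed by Felsenstein pruning with transition
matrices $P(t) = e^{Qt}$ obtained from the symmetric eigendecomposition
of the scaled rate matrix; the C++ kernel collapses the alignment to
site patterns first. With at most eight taxa, topology search is
exhaustive enumeration — 15 unrooted or 105 rooted topologies for five
taxa — which keeps the fit deterministic; beyond eight taxa the fit is
refused rather than silently switched to a heuristic search.

Free fits optimize one branch length per edge ($2n-3$ parameters);
clock fits parameterize $n-1$ nested node heights (each non-root height
a fraction of its parent's), so clock trees are exactly ultrametric by
construction. Both use coordinate-descent with Brent line searches to a
log-likelihood tolerance of $10^{-8}$. Base frequencies are estimated
empirically from the alignment (with a half-count pseudocount so no
frequency is zero); exchangeabilities (last fixed at 1 for
identifiability) are profile-estimated once on a neighbor-joining
starting topology and then held fixed during topology enumeration, a
standard economy that also guarantees the clock model stays nested in
the free model for the likelihood-ratio test. Rooted-topology
enumeration uses a loose screening pass followed by full-tolerance
refinement of the leaders; this is purely a numerical scheduling choice
and does not change which topology wins. As a final safeguard the free
model is re-optimized from the clock solution whenever optimizer noise
leaves it below the clock likelihood, so `clockLRT()`'s statistic
$2(\ln L_\text{free} - \ln L_\text{clock})$ is nonnegative. Degrees of
freedom are $n-2$ and the statistic is referred to the plain $\chi^2$
upper tail, without a boundary-mixture correction, matching how such
tests are conventionally reported.

One caveat is inherited from the data type: SNP-only alignments carry
no constant sites, an ascertainment the GTR model does not correct for.
The LRT is computed on the concatenated SNP columns exactly as reported
in practice; branch lengths should be read as relative, not as absolute
substitution rates. The calibration tests therefore simulate full
(unascertained) alignments: under clock-true simulation the test's
type-I error at $\alpha = 0.05$ stays within its nominal band and the
p-values pass a Kolmogorov–Smirnov uniformity check.

# Pooled-capture artifacts

When individually indexed libraries are pooled for hybridization
capture and then PCR-amplified, a nascent strand can switch templates
between libraries ("jumping PCR"), so a read indexed as substrain $s$
can carry another pooled substrain's allele. The estimator
(`estimateArtifactRates()`) works on read-level base counts at
high-coverage loci (every substrain at or above 100 reads, the
`selectHighCoverage()` default) and splits each cell's reads into three
buckets: the focal substrain's own allele, bases that are the major
allele of another same-pool substrain (jump bucket), and everything
else (error bucket). A base that is both a possible miscall and an
in-pool allele goes to the jump bucket — the observable quantity is the
in-pool minor-variant frequency, and the optional `jumpCorrected`
column subtracts the expected miscall contribution. Cells whose pool
mates all share the focal allele have no jump bucket; they are excluded
from jump summaries but still inform the error summaries, and the
`errorRate` column rescales the error-bucket mass to a per-base miscall
rate (`errorFreq * 3 / (3 - nJumpBases)`).

The simulator (`simulatePooledReads()`) draws each read's emitted base
as: template switch with probability $j$ to a uniformly chosen other
pool member (equal pooling assumed; pool proportions are not modeled),
else miscall with probability $e$ uniform over the three alternative
bases (no quality scores), else the true allele. Under this model, in a
two-library pool differing at a locus, the expected jump-bucket mass is
$j + e/3$ and the error-bucket mass is $2e/3$ — the oracle values the
recovery tests assert at three standard errors. Defaults ($j = 1.6\%$,
$e = 0.05\%$) are the study conditions for the packaged pipeline.

# Deletion calling from probe intensities

Array probes report a continuous intensity per substrain;
`scaleIntensities()` centers each probe by its across-substrain median,
so a deletion private to a minority of substrains appears as a run of
strongly negative values while shifts shared by a majority are absorbed
into the median (a warning is raised when the median series steps
sharply, the signature of such masking). `callDeletions()` then scans
each substrain for maximal runs of at least `minRun` probes below
`threshold`, merging identical spans across substrains into one call
with the union substrain set. The defaults (threshold $-0.5$, minimum
run 3, simulator noise SD 0.1) make a 13-probe, $\delta = -2$ deletion
— the scale of the documented ~110-kb Chromosome 3 event — essentially
always recoverable while pure-noise tracks call nothing: per cell,
$P(x < -0.5) \approx 2.9\times 10^{-7}$ at SD 0.1, so even one
three-probe false run is vanishingly rare. Reported coordinates are the
first and last probe positions of the run: probe spans bracket, but do
not equal, the true breakpoints, and no sub-probe refinement is
attempted. Duplications can be scanned with a mirrored threshold via
`gains = TRUE` but are off by default since the motivating analyses
concern losses.

# The pipeline and reproducibility

`runPipeline()` drives all stages from one JSON configuration with a
single mandatory seed, expanded per stage by a fixed affine scheme
(`base * 131 + stage` modulo $2^{31}-1$); identical configuration and
seed give byte-identical artifacts, which the test suite checks by
comparing raw bytes of two runs. Every stochastic function in the
package takes an explicit seed (0 is valid) and restores the caller's
RNG state.

# What the simulations do and do not establish

The generators reproduce the statistical structure the estimators
assume: Poisson-distributed fixed differences partitioned by a known
genealogy, multinomial read counts with known error and jumping rates,
Gaussian probe noise with rectangular intensity shifts. Passing tests
therefore demonstrate correct recovery of known truth under the assumed
model, at the documented scales (for example 400 clock-true replicates
of 5 taxa by 2,000 sites for LRT calibration, 100 replicates of 5,000
sites for topology recovery, 200 replicates for deletion recall —
problem sizes chosen to give stable Monte-Carlo answers on a single
CPU). They do not establish robustness to what real data add on top:
mapping and calling error correlated along the genome, capture-bias
coverage structure, segmental duplications mimicking CNV signal,
non-uniform mutation spectra, or pool-imbalance effects on jumping
rates. Real-data conclusions should lean on the validation built into
the analyses themselves (load reports, validity-checked matrices,
probe-resolution honesty of CNV spans) rather than on the simulation
results.

# Session info

```{r}
sessionInfo()
```
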