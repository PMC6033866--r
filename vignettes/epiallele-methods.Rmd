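---
title: "Epiallele analysis of targeted bisulfite amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele analysis of targeted bisulfite amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidiv)
```

## The problem

Targeted deep bisulfite amplicon sequencing reads out the methylation state
of every CpG site on every sequenced DNA molecule of a short (300-450 bp)
region. Because each merged read is one molecule from one cell, the data
resolve not just the *average* methylation of a region but the distribution
of *epialleles* -- the specific combinations of methylated and unmethylated
CpGs per molecule. Two tissues can share an average yet differ sharply in
how that average is assembled across cells; epiallele composition,
summarised with the diversity machinery of community ecology, is the
statistic that sees the difference. `epidiv` implements the full path from
merged reads to those statistics, with a ground-truth-known synthetic
generator so every stage is testable without controlled-access data.

## Coordinate and reference model

Amplicons are anchored to the transcriptional start site: position +1 is the
first transcribed base, there is no position 0, so a span written $-a/+b$
contains $a+b$ bases (e.g. $-104/+221$ is 325 bp, $-330/+104$ is 434 nt).
`tss_label()`/`tss_index()` implement the bijection; `tss_span()` the span
arithmetic.

Every internal cytosine of the top (primer-targeted) bisulfite strand is
classified once by its following base: CpG, or CpH with H in {A, C, T}. The
terminal cytosine of a sequence has no observable context and belongs to
neither inventory -- an explicit choice over guessing. Only the top strand is
modelled: single-strand bisulfite PCR makes the two strands non-complementary,
and read orientation is resolved at alignment time by scoring both
orientations. Lowercase and ambiguity codes are rejected rather than
silently normalised. An optional primer mask can drop CpG sites that fall
under primer annealing regions; no mask is applied by default.

## Synthetic data: what it emulates, and what it does not

`make_synthetic_reference()` plants an exact number of CpGs into an A/C/T
background (G appears only in planted CpGs, so no CpG can arise or vanish by
adjacency), with a minimum CpH count. `sample_epialleles()` draws molecules
from a discrete pattern mixture (multinomial), with i.i.d. per-site Bernoulli
CpH methylation. `emit_bisulfite_reads()` applies the chemistry model:

* methylated C is read as C;
* unmethylated C is read as T, except it survives conversion (read as C)
  with probability `conversion_failure_rate` (default 1%, within the
  0.5-2% band typical of the assay);
* substitution sequencing errors at `sequencing_error_rate`
  (default 0.002); no indels by default;
* per-read qualities from a two-state PHRED model (Q20/Q40), giving the
  mean-quality filter a known truth to be checked against.

`simulate_cohort()` arranges samples as three brain areas (HIPP, DLPFC, CB)
by two diagnosis groups (CTRL, SCZ), the study-shaped design, and emits an
unmethylated spike-in per sample. `example_area_mixtures()` provides the
default area profiles: two cortical-like mixtures rich in epiallele species
spread over intermediate classes, and a cerebellum-like mixture dominated by
the fully methylated molecule plus an unmethylated fraction -- fewer species,
lower diversity, a distinct class profile. These were fixed once, as a
qualitative emulation of the area contrast the assay targets, and give
region averages in the 60-70% range typical of a methylated promoter.

What the generator does **not** model: PCR amplification bias and chimeras,
paired-end merging artefacts (reads are emitted pre-merged), indel
sequencing error (an option exists to exercise ambiguous calls), spatially
correlated CpH methylation, and cell-type deconvolution. Passing tests
therefore demonstrate correctness of the *computation* under a faithful
chemistry model, not robustness to every artefact of real libraries.

Everything is seeded: identical (spec, seed) reproduce byte-identical FASTQ,
and read IDs encode sample, locus and molecule index so truth joins are
exact. Default simulated depths (2,000-10,000 reads/sample; the assay
itself yields ~200,000) were chosen so the full suite runs in minutes;
every statistical check scales its tolerance to the depth it uses.

## Read processing

**Quality filter.** A read passes if the arithmetic mean of its per-base
PHRED scores is at least 33, the conventional threshold for this assay.

**Alignment.** Reads are aligned with an affine-gap global-local
(pattern-global) `Biostrings::pairwiseAlignment` against the fully
converted (C-to-T) reference: match +2, mismatch -3, gap open -5, gap
extend -2, all configurable. Rather than collapsing the read's own Cs, the
substitution matrix scores read-C against reference-T as a match -- exactly
score-equivalent to collapsing both strings (the standard
bisulfite-insensitive trick), while keeping original read bases available
per reference position for methylation calling. Both orientations are
scored and the better kept. The test suite pins the implementation to an
independently written Gotoh dynamic program on 100 randomised cases.

**Calling.** Per CpG: C gives 1 (methylated), T gives 0 (unmethylated),
anything else -- mismatching base *or* an alignment gap -- gives 2
(ambiguous). Per CpH, C and T accumulate into the per-read conversion
evidence; `bisulfite_efficiency` is converted/(converted+retained). A read
with zero aligned CpH has undefined efficiency and fails the efficiency
filter rather than passing vacuously.

**Filtering.** Four criteria, each applied to every read so per-criterion
tallies are interpretable: length within 10% of the reference, efficiency
at least 0.98, at most 10% ambiguous CpG calls, at least 60% of the
reference aligned. The upstream pipeline this emulates uses the same four
criteria without publishing values; these defaults are package choices,
exposed in `filter_thresholds()`. Note the efficiency default assumes low
CpH methylation; for loci with substantial genuine mCpH (which depresses
apparent "efficiency"), lower it deliberately.

**Spike-in.** Conversion efficiency is estimated from a fully unmethylated
control amplicon (M13mp18-like): the pooled fraction of aligned
reference-cytosine positions (all contexts) read as T. Estimation is
per-sample where a per-sample spike FASTQ exists, with a pooled fallback --
the pipeline supports both because per-sample spikes are not always
available.

## Epiallele statistics

Molecules with any ambiguous call are excluded from the count table (their
pattern is undefined) but still contribute sitewise to methylation
averages -- the choice that maximises data use while keeping patterns exact.
Count conservation (table + ambiguous tally = retained reads) is asserted
in tests.

**Rarefaction** subsamples each sample without replacement to a common
depth (default: the minimum sample depth), as a single seeded draw whose
seed is recorded in the table and its BIOM serialisation. A single concrete
draw keeps all downstream tables reproducible; repeat draws across seeds
estimate rarefaction variance, and the expected richness of a draw has the
hypergeometric closed form the tests check against.

**Summaries.** Class distributions count methylated CpGs per molecule
(0..N) ignoring position. Per-site percent excludes ambiguous calls
sitewise and reports empty sites as missing, not zero. The regional average
pools all unambiguous calls (each call equally weighted); it equals the
depth-weighted mean of site percents, and the unweighted site-mean variant
is one `mean(per_site_methylation(...))` away when the two differ.

**mCpH.** With $p$ the observed fraction of aligned CpH positions read as C
and $f$ the spike-in residual-C fraction:

* `mcph_percent` $= 100p$; `mcph_per_molecule_raw` = total mCpH / reads;
* `mcph_percent_corrected` $= 100\,\max(0, p-f)$ and its per-molecule
  analogue -- the conventional spike-in subtraction, clamped at zero;
* `mcph_percent_calibrated` $= 100\,(p-f)/(1-f)$.

The subtraction is the field's convention but is biased low by $f \cdot
p_{\text{true}}$ (at $f$=1% and a true rate of 20%, it reads 19.8%);
the calibrated estimator inverts the conversion-failure mixture
$p = p_{\text{true}} + (1-p_{\text{true}})f$ exactly and is what the
recovery tests hold to the planted rate. Both are reported so either
convention can be followed.

## Diversity and inference

* **Alpha**: observed epialleles and Shannon index in bits (base 2, the
  convention of the ecology toolchain this mirrors; configurable).
  Computing on an unrarefied table warns rather than errors.
* **Beta**: Bray-Curtis via `vegan::vegdist`; zero-sum samples yield NA
  with a warning rather than a silent 0 or 1.
* **PCoA**: classical scaling of the double-centred squared dissimilarities
  (`cmdscale`); negative eigenvalues (Bray-Curtis is generally
  non-Euclidean) are reported, and variance fractions are taken over the
  positive eigenvalues only.
* **ANOSIM**: `vegan::anosim`, 999 permutations by default, average ranks
  at ties, seeded; $R$ is rank-based and thus invariant to monotone
  transformation of the dissimilarities (tested by squaring).
* **Cramér two-sample test**: implemented in-package (the CRAN
  implementation is not a dependency): $T = \frac{mn}{m+n}\bigl[
  \frac{2}{mn}\sum\phi(\|x_i-y_j\|) - \frac{1}{m^2}\sum\phi(\|x_i-x_j\|)
  - \frac{1}{n^2}\sum\phi(\|y_i-y_j\|)\bigr]$ with the original kernel
  $\phi(z)=z/2$ (configurable). Each observation is one sample's class
  frequency vector. Resampling is label permutation by default -- exact
  exchangeability under the null -- with the parametric-bootstrap variant
  of the reference implementation available by flag; the two can differ
  slightly in small samples.
* **Permutation p-values** everywhere use the inclusive convention
  $p = (1 + \#\{T^* \ge T\})/(B+1)$, so $p > 0$ always and the support is
  known.
* **Univariate layer**: per-site pooled-variance Student t tests (Welch by
  flag) with Bonferroni over the locus's sites; one-way ANOVA of alpha
  metrics across areas with Tukey HSD (Tukey-Kramer at unequal n).
  Zero-variance-in-both-groups sites are flagged NA, not fabricated.

ANOSIM across areas permutes labels without stratifying by diagnosis
group: the two diagnosis groups within an area share a mixture in the
synthetic design, making unrestricted permutation the natural null.

## Numerical and degenerate-input choices

Frequencies must sum to 1 within 1e-9; rarefaction at depth 0 yields a
valid all-zero row (0 observed species); rarefaction deeper than a sample
errors naming the sample; the empty count table serialises to a valid
degenerate BIOM JSON and round-trips; tables carry locus, depth and seed
through the BIOM `id` field so provenance survives serialisation. All
stochastic functions take an explicit seed and restore the caller's RNG
state (`withr::with_seed`), so library calls never perturb user code.

## Validation strategy and known limits

Tests pin each statistic to an independent route: direct-summation Shannon
and Bray-Curtis, exhaustive relabelling for ANOSIM and Cramér p-values at
tiny n, a hypergeometric closed form for rarefied richness, a from-scratch
Gotoh aligner, and truth joins against the generator (100% pattern recovery
at zero noise; binomial-tolerance recovery of site rates, class
frequencies, conversion failure and planted mCpH under noise). Operating
characteristics are measured by simulation: power about 1 at the built-in
area contrast (10 samples/area, 300 molecules/sample) and type-I error
near 0.05 under identical mixtures (500 replicates). Problem sizes
(10,000-read recovery runs, 300-molecule inference cohorts) are the
package's validation choices; they keep the full suite within minutes
while leaving every tolerance binomially justified at its own n.

Limits worth restating: per-sample cohort numbers from any specific study
are not reproducible from synthetic data -- the package reproduces the
*method*, with its analytic invariants, not a cohort; and the read model's
fidelity bounds what read-level tests can claim (see the generator section).
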