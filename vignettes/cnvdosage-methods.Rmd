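---
title: "Methods: genome size, CNV and dosage compensation in cnvdosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome size, CNV and dosage compensation in cnvdosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdosage)
```

`cnvdosage` analyses heritable genome size variation driven by gene copy
number variation (CNV) in haploid microbial eukaryotes — the motivating
system is a unicellular zygnematophycean alga in which strains of the same
species complex differ more than two-fold in genome size, largely through
genome-wide gene duplication. The package covers five analysis stages and a
synthetic-data generator that emulates every input, so the whole pipeline
is testable without sequencing data.

## k-mer genome sizing

A k-mer frequency histogram from haploid short-read data has three
landmarks: an error spike at low multiplicity, the haploid coverage peak
`Xb`, and (for whole-cell DNA) high-multiplicity organelle peaks. The error
boundary `Xa` is the first local minimum scanning upward; the bounded
genome size is

\[
\hat G_{\mathrm{basic}} = \frac{1}{X_b} \sum_{m=X_a}^{20 X_b} m\,c(m),
\qquad
\hat G_{\mathrm{total}} = \frac{1}{X_b} \sum_{m \ge X_a} m\,c(m),
\]

where `c(m)` is the count of distinct k-mers of multiplicity `m`. The
summation is over k-mer *instances* (`m·c(m)`), the only reading that
returns a genome length when divided by coverage; the lower limit is
inclusive of `Xa`. The unbounded estimate includes organelle k-mers; each
organelle contributes roughly `length × (X_o / X_b)` where `X_o` is its
coverage peak, so the nuclear size is recovered by subtracting
`L_m X_m / X_b + L_p X_p / X_b` with the organelle genome lengths taken from
organelle assemblies. The mitochondrial peak is assigned to the smaller of
the two detected multiplicities (mitochondrial coverage is the lower of the
two in this system).

Numerical choices: local-extremum ties resolve to the smallest multiplicity
of a plateau; organelle peaks above multiplicity 500 are ranked by
prominence after a 3-point moving average; `Xb` is located as the
multiplicity attaining the maximum (optionally smoothed) count after `Xa`
rather than by a literal first-local-maximum scan — identical on clean
histograms, but robust to sampling noise in the nearly empty valley between
the error spike and the coverage peak. Subtraction results below the
bounded estimate are flagged (`below_floor`) rather than overwritten,
because the bounded estimate itself absorbs organelle mass whenever an
organelle peak sits near the `20·Xb` bound; only negative results are
clamped. `k` is metadata and never enters the arithmetic.

## Flow cytometry and inheritance

Events are gated to pulse widths in `[40, 80]` (inclusive, exactly as the
exclusion rule "<40 or >80" implies), and intensity modes are found as
local maxima of a Gaussian kernel density estimate with Silverman's
rule-of-thumb bandwidth. In log-phase cultures the replicated 2C nuclei
dominate, so the sample's *second* peak is read as 2C content. The leaf
nuclei of the internal standard (tomato, 1C = 958 Mb) likewise dominate at
2C, so

\[
\widehat{1C} = 958 \,\mathrm{Mb} \times
\frac{I_{\mathrm{sample,2}}}{I_{\mathrm{standard,1}}}
\]

— both numerator and denominator are 2C signals, so the 2C factors cancel
and the standard's 1C constant scales the result directly. This calibration
arithmetic is a documented assumption (the convention is standard, but
peak-caller and formula choices vary between labs); the estimate is
invariant to any common instrument gain.

Heritability of genome size across F1 lines is the between-line fraction of
a one-way random-effects decomposition estimated from ANOVA mean squares
(`sigma_b^2 = (MSB - MSW)/n0`, clamped at zero, with the usual effective
replicate number `n0` for unbalanced designs), with the p-value from the F
test. Unimodality of the F1 genome-size distribution is assessed with a
Silverman critical-bandwidth bootstrap (the smallest bandwidth making the
KDE unimodal, calibrated by smoothed bootstrap); this is a stand-in for
published dip/excess-mass tests — no such test ships with base R — and the
output labels the method accordingly.

## Depth-based CNV calling

Per-gene mapped-read counts are normalized to depth per million: counts are
divided by gene length in kb (RPK) and scaled so each strain's RPK sums to
one million (DPM). DPM is summed over each ortholog group (OG); the depth
log-ratio is `log2(DPM_B) − log2(DPM_A)` and the *total depth* is the
linear sum `DPM_A + DPM_B`. The linear reading is forced by the arithmetic
of the depth scale itself — a three-copy OG at a single-copy DPM of ~24.6
has total depth ~75 — even though "total depth" is sometimes described as a
sum of log-transformed values; the package treats this as a resolved
inconsistency and documents it here. An OG with zero depth on one side
receives a pseudodepth of half the smallest nonzero per-gene DPM of that
strain (flagged); OGs with zero depth on both sides are excluded.

CNV is called when `|log-ratio| > 0.5` at total depth `< 90`, or
`|log-ratio| > 0.36` at total depth `>= 90`. The depth-dependent threshold
reflects the smaller expected log-ratios of unequal splits of larger copy
totals (2:3 gives 0.58 where 1:2 gives 1). Comparisons are strict, and the
absolute value makes the call symmetric in the strains — the underlying
ratio is signed by an arbitrary strain order, so sign cannot carry meaning
for "has CNV".

## Dosage response of expression

Expression counts are TPM-normalized with the same per-million kernel, and
between-sample scaling uses an in-package implementation of the trimmed
mean of M-values (TMM): genes zero in either sample are dropped, the most
extreme 30% of log-ratios and 5% of average log-intensities are trimmed
from each tail, and the factor is the precision-weighted mean of the
remaining M values, re-centred to geometric mean 1. The implementation
agrees with `edgeR::calcNormFactors` to 1e-8 on random matrices, and edgeR
serves only as a cross-check in the test suite.

For each CNV OG and stage, per-replicate expression log2-ratios (replicates
paired by index across strains; pseudo-TPM 0.01 before the log) are tested
against the DNA depth log-ratio `d` with three one-sided one-sample
t-tests, all oriented by the sign of `d`:

* **smaller** — mean ratio closer to zero than `d` (toward compensation);
* **inverse** — mean ratio on the opposite side of zero from `d`;
* **positive** — mean ratio beyond `d`, away from zero.

Each family is BH-adjusted across OGs within a stage. An OG is
**dosage-compensated** when `q_smaller < 0.05` and `q_inverse > 0.1`;
**inverse** when `q_smaller < 0.05` but the inverse gate fails
(`q_inverse <= 0.1`); **positive** when `q_positive < 0.05`; otherwise
**proportional**. The gray zone (`q_smaller < 0.05` with
`q_inverse <= 0.1`) resolves to "inverse" — the gate is printed as a strict
"FDR > 0.1" requirement for compensation. The replicate-level one-sample
formulation (ratios per replicate pair, test against `d`) is one of two
defensible readings of a verbally specified test; it is the implemented one
and is flagged as such.

The genome-wide dosage response is summarized by OLS of mean expression
log-ratio on DNA log-ratio over CNV OGs, with a one-sided t-test of slope
< 1: proportional response has slope 1, and compensation pulls it down.
The DEG caller behind the DEG/CNV enrichment test is a Welch t-test on
TMM/library-normalized `log2(count + 0.5)` with BH FDR — a deliberate
simplification (the contribution here is the dosage classification, not
the DE engine), labelled as such.

Fold enrichment is defined as `P(property | class) / P(property)`
throughout, with Fisher's exact test for significance.

## Duplication origin from gene trees

For OGs with 2–4 copies per focal group, a group's copies being
monophyletic with bootstrap support >= 70 indicates duplication after the
groups diverged; non-monophyly indicates a shared ancestral duplication
(or gene conversion, which this analysis cannot distinguish). Monophyly is
evaluated as a bipartition on the *unrooted* tree, making verdicts
invariant to the input rooting; the implementation roots at a tip outside
the query group and matches tip-descendant sets, which is equivalent and is
verified against a brute-force bipartition enumeration in the tests. At a
multifurcation a group counts as monophyletic if some resolution of the
polytomy makes it a clade; such unresolved clades carry no support value
and are reported `monophyletic_unsupported`.

OGs containing anciently diverged paralogs are removed by a maximum
pairwise Ks filter (`Ks < 1`), computed by the Nei–Gojobori (1986) method:
fractional synonymous-site counting per codon position, pathway-averaged
difference counting for multi-substitution codons (pathways through stop
codons excluded), and the Jukes–Cantor correction
`Ks = -(3/4) ln(1 - (4/3) ps)`. Short sequences saturate easily — a single
synonymous change over 4/3 synonymous sites already drives the correction
argument to zero — in which case Ks is undefined, flagged, and the OG is
treated as failing the filter. The NG86 engine replaces heavier Ks
machinery deliberately: the filter only needs the ordering of Ks values
near 1.

## GO enrichment

Per-term one-sided Fisher (hypergeometric) tests over terms annotating at
least 10 universe genes (i.e. "more than nine"), with fold enrichment
`(k/n_interest)/(K/N)` and no multiple-testing correction, matching the
`P < 0.05` reporting convention of per-term GO scans. Graph-aware
decorrelation ("weight01"-style algorithms) is out of scope; an optional
parent map propagates annotations to ancestor terms before testing.

## The synthetic-data generator

The generator produces every input with the statistical structure the
estimators assume, and always returns ground truth alongside:

* **k-mer histograms** — per-k-mer Poisson multiplicities around the
  nuclear coverage (distinct-k-mer mass = genome length), organelle blocks
  at configured coverage multiples, and an error spike decaying
  geometrically from multiplicity 1 (the analysis defines only the error
  *boundary*, so the spike's shape is a modelling choice).
* **DNA depth** — per-gene negative-binomial counts with mean proportional
  to copy number. Copy numbers are drawn with a configurable CNV fraction
  (default 0.35, matching the observed 30–36% range in the motivating
  system); gains are assigned to a randomly chosen strain so neither strain
  is systematically larger and the per-million normalization centres
  equal-copy OGs at log-ratio zero, as in a balanced comparison.
* **expression** — negative-binomial counts whose OG mean scales as
  `copy^theta` (`theta = 1` proportional, `0` compensated, negative
  inverse), three replicates per stage by default.
* **flow events** — Gaussian intensity mixtures at 1C and 2C with the 2C
  peak dominating 3:1 (the data only require "more prominent"; 3:1 is a
  typical log-phase ratio), a shared instrument gain with the standard, and
  a configured fraction of widths outside the 40–80 gate.
* **F1 lines** — line means at the mid-parent value with line effects
  standardized so the realized between-line variance is exactly
  `f · sigma_total^2`; replicate noise is random. The generator's
  decomposition is thus the nominal one, which is what "data with
  between-line variance fraction f" should mean.
* **gene trees** — "post" batches nest each group's copies in a clade;
  "pre" batches nest same-index copies across groups, so no group is
  monophyletic; supports are set from configuration.

Dispersion defaults are free parameters (no empirical dispersions are
available for this system): expression uses 0.01 — near-technical
replicates of clonal haploid cultures — and DNA depth uses 0.002, since
genomic coverage of a fixed locus is close to Poisson. These were chosen
a priori from the character of each library type, not fitted; DNA depth
being much less dispersed than expression is the empirically universal
pattern. The default per-copy means (500 counts) correspond to a typical
30–60x short-read experiment over ~2 kb genes. Note that the per-OG DPM of
a single-copy gene is an *emergent* quantity — one million divided by the
summed copy number — so at 2,000 simulated OGs it is ~370 rather than the
~25 of a 40k-gene genome; classifier truth-table tests therefore construct
depth values on the 24.64-DPM scale directly.

What the generator does **not** emulate: mappability and GC biases,
repeat-driven multi-mapping, isoform structure, batch effects, cell-cycle
substructure in flow data, and gene-tree estimation error (supports are
assigned, not inferred). Passing tests therefore demonstrate correctness
of the estimators under their stated models, not robustness to the full
messiness of real libraries.

## Problem sizes and reproducibility

The test suite and the acceptance script use 1 Mb genomes at 30x coverage
(20 replicate histograms), 2,000 OGs for depth/expression simulations
(50–100 seeds for calibration rates, 20–50 for recovery), 18 F1 lines x 3
replicates (the real crossing design), 100-tree batches per topology
scenario, and 5,000 flow events — sizes chosen so every property is
estimated with comfortable Monte-Carlo margins while a full run stays in
the tens of seconds. All generators are bit-identical given `sim_config`
seeds and leave the session RNG untouched.

`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
the headline quantities (estimator errors, CNV sensitivity/specificity,
dosage calibration and power, slope recovery, heritability fraction,
monophyly accuracy, Ks and TMM identities) from scratch at those sizes.

## Known limitations

* The bounded/unbounded k-mer estimators are peak arithmetic, not mixture
  fits; heterozygosity and ploidy structure are out of scope (the target
  organisms are haploid).
* The 2C-based flow calibration assumes the standard's dominant peak is its
  2C; a standard measured at 1C would need `std_1c_mb` halved.
* The one-sample formulation of the dosage tests ignores uncertainty in
  the DNA log-ratio; with deep DNA coverage this is small relative to
  expression noise.
* Classic per-term GO tests inherit the usual term-correlation caveats;
  significant terms should be read as a ranked shortlist, not independent
  discoveries.
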