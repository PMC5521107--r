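---
title: "Estimating historical Ne from SNP-chip linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating historical Ne from SNP-chip linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nehist)
```

## The model

Linkage disequilibrium (LD) between two bi-allelic loci is measured
here by $r^2$, the squared correlation of allele indicators:

$$r^2 = \frac{[f(AB) - f(A)f(B)]^2}{f(A)f(a)f(B)f(b)}.$$

Under drift–recombination balance, Sved's approximation relates its
expectation to the effective population size $N_e$ and the
recombination distance $c$ (Morgans): $E(r^2) = 1/(1 + 4N_ec)$.
Because LD at distance $c$ regenerates on a timescale of roughly
$T = 1/(2c)$ generations, the inverted formula

$$N_e(c) = \frac{1}{4c}\left(\frac{1}{E(r^2)} - 1\right)$$

read along a grid of distances traces $N_e$ back through time: marker
pairs 50 cM apart speak to one generation ago, pairs 0.5 cM apart to
one hundred. These are approximations — the sample-size inflation of
$r^2$ (about $1/(2n)$ for $n$ diploids with unphased composite
estimates) is not removed by default, matching common practice; a
Weir–Hill-style correction is available via the `n` argument of
`sved_ne()` and `ne_history()`.

## Pipeline and assumptions

The intended flow is: quality control (`apply_qc()`), the LD-stage
MAF filter (`filter_maf()`, MAF < 0.05 removed, autosomes only), a
dense genetic map (`m1_positions()`, `m2_positions()`,
`m3_positions()`), the LD fit (`ld_decay()`), and the transform to an
Ne trajectory (`ne_history()`). All stages assume diploid, bi-allelic,
unphased genotypes; dosage 1 always codes the heterozygote, and
missing calls are a distinct state handled pairwise-complete
downstream of QC.

### Quality control

Defaults: SNP call rate ≥ 0.95; MAF > 0 (strict, so monomorphic SNPs
leave); Hardy–Weinberg removal at $p \le 10^{-6}$ (1-df chi-square
without continuity correction by default — at such an extreme
threshold the choice between chi-square and the exact test is
immaterial, and both are provided); non-autosomal SNPs removed after
the sex check; animals removed at call rate ≤ 0.95; duplicate pairs
at IBS ≥ 0.95 on 2000 randomly drawn autosomal markers (seeded draw;
the lower-call-rate member leaves). Sex is called female when more
than 3% of X calls are heterozygous, strictly. In the combined
(multi-breed) mode the per-dataset HWE test is skipped: a SNP is
removed only when it fails within *every* breed group, since HWE is
not expected to hold in a mixture of populations. We read
"fails in every group" literally; a switch to "fails in at least one"
is a one-line change in `apply_qc()` if a stricter reading is wanted.
HWE is evaluated on autosomes only — X genotypes in a mixed-sex
sample violate HWE by construction and are removed as non-autosomal
regardless.

### Genetic maps

M1 multiplies physical Mb by one genome-wide ratio (1 cM/Mb by
default; a genome-wide mean ratio such as 1.51 can be supplied). M2
uses per-chromosome ratios, total linkage cM over physical Mb, with
chromosome length defined as the last chip SNP position. M3 trims
linkage-map intervals and loess-interpolates anchor positions to all
chip SNPs.

Numerical choices in M3, all of which were genuinely open:

* *Interval trimming.* The genome-wide (not per-chromosome) empirical
  99.9th percentile of interval cM/Mb ratios, type-7 interpolation,
  removal iff ratio ≥ the percentile **and** strictly above the
  genome-wide median. The median guard exists because on a perfectly
  uniform map every interval ties at the percentile and the bare rule
  would delete the entire map; an "extreme" interval should at least
  be atypical. Negative-ΔcM intervals (implying an alternative marker
  order) are always removed.
* *Repair.* Removed intervals collapse to zero recombination (anchor
  positions are rebuilt by cumulative sums with trimmed intervals set
  to 0), and predictions are clamped non-decreasing by a running
  maximum. This keeps every chip SNP addressable for LD pairing and
  is deterministic, at the price of occasional zero-length intervals.
* *Smoother.* Local quadratic, span 0.3, on (Mb, cM) anchors, with a
  floor so a window never drops below a handful of anchors; both span
  and degree are arguments. Chromosomes with fewer than 10 surviving
  anchors fall back to M2 with a warning; chip SNPs beyond the anchor
  range extend linearly at the chromosome's M2 ratio.

### The LD fit

Per chromosome, `n_pairs` distinct SNP pairs are drawn uniformly
without replacement (all pairs when fewer exist) and the composite
$r^2$ — the squared Pearson correlation of dosages over
pairwise-complete animals — is computed for each. The
haplotype-frequency estimator (`r2_haplotype()` for phased data,
`r2_em()` with an EM step for unphased data) implements the displayed
formula directly; for random-mating data the two agree in
expectation, which the test suite checks by simulation. A loess of
$r^2$ on distance is evaluated at 2000 grid points on 0.5–50 cM
(clamped to $[0,1]$), the sampling is repeated `n_reps` times
(replicate $r$ seeded at `seed + r`), and per-grid-point means and
variances over replicates summarize each chromosome.

*Smoother defaults.* We use a local **quadratic** with span **0.05**
(floored so a window holds ≥ ~40 pairs). A wide local-linear smoother
(e.g. span 0.3) was tried first and rejected: the decay curve is
hyperbolic, so wide windows produce a large curvature (boundary) bias
at the short-distance end — in constant-size simulations it inflated
$E(r^2)$ at 2.5 cM by a factor of two and biased recent-generation
Ne downward by ~50%. The narrow quadratic tracks binned means closely
while the replicate resampling absorbs its extra variance.

Chromosomes are combined per grid point by inverse-variance
weighting: $\bar m = \sum w_c m_c / \sum w_c$ with $w_c = 1/v_c$,
standard error $\sqrt{1/\sum w_c}$, and a normal 95% interval. A
degenerate zero replicate variance has its weight capped at the
largest finite weight at that grid point so the mean stays defined.

### Ne trajectories and method comparison

`ne_history()` pushes each chromosome's mean decay curve through the
Sved inversion; per-chromosome Ne *variances* are obtained by pushing
each replicate-level curve through the same transform and taking
variances over replicates — mirroring how the LD variances were
formed, rather than a delta-method approximation. Combination and
intervals then reuse the LD rule. Table extraction at generations
1/5/20/50/100 interpolates linearly on the $T$ axis (the lookup rule
was unspecified; linear-in-$T$ is the least surprising choice).
`normality_screen()` applies Shapiro–Wilk per grid point at the
Bonferroni level $0.05/2000$.

`bootstrap_compare()` tests, at a grid point, equality of means and
of variances of the per-chromosome estimates produced by two map
methods. The statistics are declared choices (the procedure we
compare against names the bootstrap but not its statistics):
$T_{\text{mean}} = |\bar x_1 - \bar x_2|$ and
$T_{\text{var}} = |\log(s_1^2/s_2^2)|$, with parametric null draws
from normals sharing the pooled mean (mean test) or pooled variance
(variance test), and the $+1$-corrected p-value
$(1 + \#\{T^\ast \ge T\})/(B + 1)$ so p is never exactly zero. Under
a shared null both tests hold their 5% size within Monte-Carlo
tolerance (checked over 500 seeded trials).

## The simulator, and what passing tests do and do not show

`simulate_population()` is a discrete-generation Wright–Fisher
simulator: two parents drawn uniformly per offspring (selfing
allowed), gametes recombine with Poisson crossover counts placed
uniformly on the genetic map (Haldane model — no interference; the
Kosambi convention of real linkage maps matters only at the
recovery tolerances used here), initial haplotypes carry independent
alleles at frequencies U(0.05, 0.5), and there is no mutation, which
is negligible over the ≤ 100-generation horizon. The Ne trajectory is
piecewise constant, most recent epoch first; the burn-in runs at the
oldest epoch's size and warns below 4× max(N). When the genotyped
sample exceeds the final epoch's census, the final cohort is expanded
to the sample size — the extra offspring are drawn from the N parents,
so LD still reflects N everywhere except at $T \approx 1$.

What the simulator emulates: multi-chromosome bi-allelic genotypes
with drift–recombination LD under a known Ne, variable-rate maps with
sparse anchors (`simulate_map()`), missingness, duplicated samples
and X genotypes (`corrupt_geno()`). What it does not: genotyping
error structure, ascertainment bias of commercial chips (which
inflates common-allele MAF), family structure beyond random mating,
selection, migration, overlapping generations. Passing the recovery
tests therefore shows the estimator chain is consistent under its own
assumptions — not that real-chip estimates are unbiased; on real data
the ascertainment and pedigree structure push $r^2$ in ways no
neutral simulator reproduces.

Problem sizes used by the recovery checks (chosen as the smallest
sizes at which the quantities of interest are stable): constant
Ne = 100 with 3 chromosomes × 2000 SNPs, 400 burn-in generations,
200 sampled diploids, 5000 pairs × 8 replicates per chromosome, 5
simulation seeds, recovery judged on the combined Ne averaged over
$T \in [5, 20]$ — the window where pair counts are high and the
$1/(2n)$ floor is still small relative to the signal. Outside that
window the estimator is biased in known directions (see the README
example) and the tests do not claim otherwise.

## Other design decisions

* **GRM frequency models.** The breed-composition adjustment in the
  source workflow is cited without formulas, so `compute_grm()`
  exposes three centering models — pooled frequencies, per-group
  frequencies, and a per-SNP least-squares regression of dosage on
  breed-composition columns (our generic stand-in for a
  breed-composition GRM, not verified against any external code) —
  with pooled as default. Missing dosages contribute zero after
  centering (mean imputation), the conventional choice.
* **Outlier pruning.** The 1% most distant animals within a group are
  flagged by the sum of squared distances; the count is
  `ceiling(fraction × group size)` (so a group of 50 flags one),
  singleton groups flag nothing, ties break by animal id.
* **Ratios and units.** Genetic positions are stored in cM
  throughout; Morgans appear only inside the Sved and $T$ formulas.
* **Seeds.** Every stochastic step takes an explicit integer seed and
  restores the caller's RNG state; the pipeline derives stage seeds
  from one config seed by fixed offsets, trading independence for
  reproducibility.
* **Interfaces.** This is an R-library-first package: the exported
  functions and `run_pipeline()` (YAML config in, TSV/JSON artifacts
  and a manifest out) are the entry points; no shell wrapper is
  provided beyond the reproduction script.

## Known limitations

* Sved's formula ignores mutation and assumes equilibrium; trajectories
  with sharp recent bottlenecks blur across neighbouring $T$.
* The composite $r^2$ carries the $1/(2n)$ sampling floor; with the
  default (no correction) very recent Ne is biased low at small n.
* The bootstrap comparison treats chromosomes as exchangeable
  replicates; chromosome-length effects on $r^2$ variance make the
  variance test conservative when lengths differ grossly.
* `hwe_test(method = "exact")` enumerates the conditional
  distribution per SNP and is noticeably slower than the chi-square
  on chip-scale data; it is intended for spot checks.
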