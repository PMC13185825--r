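---
title: "Methods: repeat-mediated structural variant analysis with repsv"
author: "repsv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated structural variant analysis with repsv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsv)
```

## Scope and model of the data

`repsv` analyses structural variants (SVs) that overlap repetitive elements —
rep-SVs — in cohorts spanning two cattle subspecies (taurine and indicine)
plus admixed hybrids. The package treats an SV call set as a records table
(chromosome, 1-based position and end, type among INS/DEL/DUP/INV, absolute
length) plus a genotype matrix of alternate-allele counts (0/1/2, `NA` for
missing). Interval arithmetic is done on *effective intervals*, 0-based and
half-open: deletions, duplications and inversions span `[pos-1, end)`, while
an insertion's effective end is its start plus the insertion length,
`[pos-1, pos-1+svlen)`. This one rule makes insertion intervals comparable
with the reference-anchored types in overlap and reciprocal-overlap
computations.

An SV is a **rep-SV** when its effective interval overlaps at least one
annotated repeat by ≥ 1 bp *and* its length is strictly below 100 kbp. The
mediating repeat type is the one with the largest summed overlap; an exact
tie goes to the lexicographically smaller label, a deterministic rule chosen
because figures in this literature assign each SV a single mediating type
without stating a tie-break. Bovine SINE/LINE subfamilies (Bov-A2, Bov-tA,
BovB) are kept distinct from class/family labels such as `LINE/L1` because
the two granularities carry different signals in cattle.

**Evolutionary states** are defined on genotype presence patterns:

* *shared* — at least one taurine and one indicine carrier;
* *private* (per subspecies) — at least two carriers within one subspecies
  and none in the other;
* *specific* — exactly one carrier overall; these singletons are the
  *young* SVs;
* *unassigned* — anything else (e.g. one taurine plus one hybrid carrier).

Hybrids never decide shared/private status: the definitions name only the
two subspecies, and the admixed breeds' genotypes are not informative about
which subspecies a variant segregates in. Hybrid carriers do count toward
the overall carrier total, so a variant carried only by one hybrid is
*specific*.

## Call-set merging

`merge_callsets()` reproduces the behaviour class of SURVIVOR-style merging
with parameters distance = 1000 bp, support ≥ 2, type matching on, minimum
length 50 bp, and the 100-kbp cap: records cluster by chromosome and SV type
with single-linkage when both start and end breakpoints lie within the
distance. Single linkage means chained clusters can span more than the
pairwise distance; this is the simplest defensible reading of a "maximum
allowed pairwise distance" applied greedily, and it keeps the merge invariant
to input order. Because the published tool does not specify which member
represents a cluster, `repsv` fixes a deterministic rule: the member with
the smallest `(chrom, pos, end, source)` tuple supplies the coordinates and
id, and the merged length is the lower median of member lengths. Genotypes
combine per sample as the maximum allele count over members; samples not
covered by any member are recorded as absent, which is the pan-SV convention
for per-individual discovery call sets. SVs absent in every genotyped
individual are dropped. Strand is ignored throughout.

Missingness filtering retains SVs with a missing fraction of at most 0.5 —
the boundary is inclusive because the published rule excludes rates strictly
above 50%. Novelty against a published set requires ≥ 50% reciprocal
overlap of both effective intervals (boundary inclusive), with any SV type
allowed to establish "known" status.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses assume,
with full ground truth. Its defaults are fixed once and represent the study
conditions of a desk-scale two-subspecies cohort:

* 13 taurine + 13 indicine + 4 hybrid individuals; 3000 SVs on a genome of
  29 autosomes of 1 Mb plus an X of 1.5 Mb (mirroring the 29+X bovine
  karyotype at a size where a cohort simulates in under a second);
* 75% of SVs repeat-mediated, with a repeat-type mixture led by Bov-A2,
  LINE/L1, LTR/ERVK, Bov-tA, LINE/RTE-BovB, Satellite and Simple_repeat;
* a length law mixing a broad log-normal background (median 300 bp,
  log-sd 1.3, truncated to [50, 99999]) with four discrete peaks near 140,
  280, 1150 and 8400 bp drawn uniformly on the windows 125–158, 252–316,
  1018–1263 and 7686–9689 bp; peak draws carry the peak's dominant type
  (Bov-A2 for the two short peaks, LTR/ERVK for the two long ones) with
  probability 0.8;
* state proportions (shared 0.45, private 0.15 + 0.15, specific 0.25), a 2%
  genotype missing rate, and an optional X-placement multiplier `x_bias`
  applied to rep-SVs longer than 8000 bp.

Carrier patterns are generated per state by drawing per-subspecies presence
frequencies from Beta distributions conditional on the state (shared:
Beta(2,2) in both subspecies; private: Beta(1.5,2.5) in the carrier
subspecies, zero in the other) and sampling individuals as Bernoulli draws,
with vectorised rejection until the pattern satisfies the state definition;
after 50 rounds the few stragglers are minimally repaired (a deterministic
fallback that touches well under 1% of draws). Hybrid frequencies are the
mean of the two subspecies frequencies, consistent with the classifier that
ignores them. Because the presence patterns *define* the states, recomputing
states from the emitted genotypes reproduces the truth exactly; the
missingness mask is redrawn (up to 20 times, then dropped for that SV)
whenever it would alter the recomputed state, so truth consistency survives
masking.

The repeat track is generated jointly with the SVs rather than as an
independent genome annotation: every truth rep-SV receives one co-placed
repeat interval of its type inside its effective interval (covering 30–100%
of it), decoy repeats are scattered at 10 per Mb away from *all* SV
intervals, and SV intervals are placed disjointly (uniform gaps) so a
co-placed repeat can never touch a neighbouring SV. This guarantees the
classification truth — every truth rep-SV overlaps the track by ≥ 1 bp,
every truth nonrep-SV overlaps nothing — at the cost of genome-scale
realism. What the generator deliberately does *not* emulate: nucleotide
sequences, nested or overlapping SVs, linkage between neighbouring SVs,
caller-specific breakpoint noise, or reference bias. Passing tests therefore
demonstrate correctness of the statistical machinery on data satisfying the
model's assumptions, not robustness to the full messiness of real call sets.

Under a fixed seed the generator is byte-reproducible: all randomness flows
through R's Mersenne-Twister stream seeded once, rows are processed in a
fixed order, and no floating-point reduction depends on platform-specific
ordering.

## X-versus-autosome diagnostics

`chromosome_counts()` tallies rep- and nonrep-SVs of at least a given length
per chromosome (the Y chromosome is excluded throughout — genome models
refuse to contain one). Three diagnostics build on it:

* `regression_outlier_test()` fits ordinary least squares and reports
  externally studentized residuals; the outlier p-value is the
  Bonferroni-adjusted two-sided t tail of the largest |residual| at `n − 3`
  degrees of freedom, matching the conventional single-outlier test on a
  regression. If the full fit is numerically perfect all residuals are
  defined as zero; if deleting a point leaves an exact fit, that point's
  studentized residual is infinite.
* `cook_distance_sweep()` repeats the regression over a threshold grid
  (default 50–16000 bp; the 8000 bp split is exported as
  `LARGE_SV_THRESHOLD`) and records each chromosome's Cook's distance. Two
  regression modes exist because the source analyses describe two variants:
  the default regresses the per-chromosome rep/nonrep count ratio on
  chromosome length; the alternative regresses rep counts on nonrep counts.
* `density_ratio_profile()` compares X density with pooled, length-weighted
  autosomal density: `(count_X/len_X) / (Σcount_A/Σlen_A)`. Pooling is the
  default because a per-autosome mean is not well defined when small
  autosomes carry few large SVs.

`grubbs_single_outlier()` implements the two-sided single-outlier test on
the maximum absolute deviation, with the p-value in closed form through the
t-distribution, and reports a Shapiro–Wilk p alongside (with a warning below
0.05) since the test assumes normality. Two-sided is the right default here
because the X deviates in different directions for different statistics
(enrichment of large rep-SVs, depletion of some type-size combinations).

## Community ecology of repeat-type composition

The composition matrix counts, per individual and repeat type, the rep-SVs
of that dominant type the individual carries, optionally restricted to one
evolutionary state; an `all-overlaps` counting mode credits every
overlapped type instead of only the dominant one. Diversity uses the
natural logarithm throughout: Shannon `H = −Σ p ln p`, Pielou
`J = H / ln S`. The base cancels in `J`, so the choice only affects `H`'s
units (nats). Bray–Curtis is computed on raw counts by default (the
convention of the standard implementation this field uses), with a
`relative` switch for row-normalised input. These indices are delegated to
`vegan` and cross-checked in the tests against brute-force definitional
implementations.

Ordination suitability is assessed by the DCA axis-1 gradient length
(detrending by segments, *no* nonlinear rescaling — a documented
simplification; only the "< 3 SD units ⇒ linear methods" decision consumes
the value). The constrained ordination itself, `rda()`, is implemented
directly from its definition so every numerical convention is pinned down:
the response is column-centered (Hellinger optionally), the categorical
constraint is dummy-coded, fitted values are the multivariate least-squares
projection (group means, for a single factor), the constrained axes are the
singular vectors of the fitted matrix, and the constrained-variance fraction
is `trace(fitted'fitted)/trace(Yc'Yc)`. Significance uses free permutation
of rows with `p = (1 + #{perm ≥ obs})/(1 + n_perm)` and a mandatory seed.
The implementation is cross-checked against `vegan::rda` in the tests. No
response transformation is applied by default because the upstream analyses
do not state one. CCA is intentionally not implemented: the gradient-length
check recommends it only on data far from this package's use case, and the
recommendation string is all that is emitted.

Axis signs in PCA, PCoA and RDA follow one convention: the largest-|loading|
element of each axis is made positive. Eigendecompositions are otherwise
sign-ambiguous, which breaks reproducibility across BLAS builds.

## Size spectrum

Length densities are computed on a log10 grid (histogram bin width 0.02
plus a kernel-smoothed curve; the Sheather–Jones bandwidth falls back to
Silverman's rule, floored at the bin width, when the selector fails on
sparse or degenerate samples). `detect_peaks()` finds local maxima with a
topographic-prominence filter; a peak's window is the contiguous region
above half its prominence. The four canonical windows (125–158, 252–316,
1018–1263, 7686–9689 bp) are available as explicit defaults via
`default_peak_windows()` so analyses can use the printed windows instead of
auto-detection.

Within-window enrichment regresses, across repeat types, the in-window
composition on the overall composition (unweighted OLS across types —
matching the presentation convention of the figures this mirrors; a
count-based mode exists) and flags types whose externally studentized
residual survives Bonferroni correction over the types in that one analysis.
The young-versus-rest comparison combines a 2×2 Pearson chi-square (no
continuity correction, with a Fisher fallback when an expected cell is
below 1) with the same per-type residual screen on counts.

## Model selection

Nine candidate models are swept: Linear `a+bx`, Inverse `a+b/x`,
Logarithmic `a+b ln x`, Quadratic `a+bx+cx²`, InverseAndLinear `a+b/x+cx`,
ConstantAndLogarithmic, InverseAndConstant, Exponential `a·e^{bx}` and
Power `a·x^b`. Since every linear form carries an intercept,
ConstantAndLogarithmic and InverseAndConstant coincide with Logarithmic and
Inverse; they are retained as named aliases so that the full nine-name
candidate set can be reported, and ties between aliases break
deterministically (BIC, then parameter count, then name). Linear-in-parameter
models are solved by OLS; the nonlinear pair by Levenberg–Marquardt from
log-linearised starting values (`ln y` on `x`, or on `ln x`, over positive-y
points); a non-converging fit is flagged and excluded from selection.

Goodness of fit is computed identically for all models from the residual
sum of squares: `R² = 1 − SSres/SStot`, `AIC = n ln(SSres/n) + 2k`,
`BIC = n ln(SSres/n) + k ln n`. The smallest AIC wins. `SSres` is floored
at machine epsilon times `SStot` so an exact fit yields a finite criterion
and still always ranks first. Confidence bands use error propagation through
the parameter Jacobian, `se(x) = √(J'ΣJ)`, with t-quantiles at `n − k`
degrees of freedom; for linear models this is exactly the classical OLS
mean-response interval, and the band is restricted to the observed x-range
(extrapolation is an error).

For recovery experiments the package's simulator draws data from a named
model plus Gaussian noise. The parameter sets used in the shipped recovery
tests (e.g. Exponential `a=0.5, b=0.45`, Power `a=0.8, b=2.6`, on
`x ∈ [1, 10]`, n = 50, signal-to-noise 10) were chosen once so the nine
forms are mutually identifiable on that domain — with weak curvature an
exponential is indistinguishable from a quadratic at this n, which is a
property of the models, not of the implementation. "Recovery" credits the
generating model, its alias, or a model nesting it (a nesting model with one
spurious parameter wins a fraction of AIC contests by construction).

## Population statistics

`weir_cockerham_fst()` implements the 1984 variance-component estimator on
biallelic presence/absence alleles with observed heterozygosity; per-site
`θ = a/(a+b+c)` (negative estimates preserved — clipping would bias
summaries), genome-wide summary as the ratio of summed components, the
weighted estimator of the standard VCF tooling. Sites monomorphic across
all groups are undefined; sites missing an entire group are skipped and
counted. The estimator is validated against a brute-force transcription of
the component formulas and against Balding–Nichols simulations where the
truth is the drift parameter F.

Group contrasts of per-individual proportions use the two-sided Wilcoxon
rank-sum test (exact enumeration when both groups are ≤ 10 and tie-free;
otherwise the normal approximation with tie and continuity correction).
Genotype–phenotype association is one-way fixed-effects ANOVA via `aov`,
dropping genotype classes with a single observation.

## Problem sizes and numerical choices

The shipped validation suite runs at desk scale, chosen so the full suite
completes in a few minutes: cohorts of 3000 SVs and 30 individuals for
classification and ecology; 10 000 SVs for the X-bias recovery runs, so that
each 1-Mb autosome carries roughly 20 rep-SVs above 8 kb and the
per-chromosome ratio statistic is not dominated by Poisson noise; 500 null
data sets × 99 permutations for the RDA calibration; 10⁴ draws for the
Grubbs type-I calibration; 10⁴ sites for the F_ST recovery. Degenerate
inputs are handled explicitly rather than by accident: zero-carrier SVs,
all-zero composition rows, rank-deficient matrices in DCA, constant vectors
in the Grubbs test, zero-length INS effective intervals, and exact fits in
OLS diagnostics all have documented behaviour (error, warning-plus-NA, or
defined value, as listed on each function's help page).

## Known limitations

* The simulator's repeat track is SV-anchored; analyses that depend on the
  marginal repeat landscape of a genome (e.g. repeat density per Mb) should
  not be calibrated against it.
* Single-linkage merging can chain distant breakpoints in dense regions;
  this mirrors the behaviour class of the upstream merging tool rather than
  improving on it.
* `rda()` supports a single categorical constraint, which is what the
  subspecies analyses need; multi-factor or continuous constraints are out
  of scope.
* Breakends, multi-allelic SV records and CRAM/BAM handling are out of
  scope; unknown `SVTYPE`s are counted and skipped at parse time.
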