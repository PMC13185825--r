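# repsv

Analysis of repeat-mediated structural variants (rep-SVs) in cohorts
spanning two subspecies — the setting of modern cattle pangenomics, where
long-read call sets from taurine (*Bos taurus taurus*) and indicine
(*B. t. indicus*) individuals are merged into a non-redundant pan-SV set and
the variants that overlap repetitive elements are profiled as a community.

`repsv` is aimed at population genomicists who have per-individual SV call
sets (VCF), a repeat annotation (RepeatMasker `.out` or BED) and sample
metadata, and who want a tested, reproducible implementation of the full
analysis chain:

* **Merging & filtering** — SURVIVOR-style multi-call-set merging
  (breakpoint distance ≤ 1000 bp on both ends, type-matched, support ≥ 2,
  lengths in [50 bp, 100 kbp]), missing-rate filtering (> 50% excluded),
  novelty by ≥ 50% reciprocal overlap, and pan-SV saturation curves.
* **Classification** — rep-SV status (≥ 1 bp repeat overlap and
  length < 100 kbp), dominant repeat type by summed overlap, evolutionary
  states from genotype presence patterns (shared / subspecies-private /
  specific = young), and exon/intron/intergenic context.
* **Chromosomal bias** — per-chromosome regression diagnostics (externally
  studentized residuals, Bonferroni outlier test, Cook's distance sweeps
  over SV size thresholds), X-versus-autosome density ratios
  ρ(t) = (n_X/L_X)/(Σn_A/ΣL_A), a closed-form two-sided Grubbs single-outlier
  test with Shapiro–Wilk precheck, and per-individual ratio PCA.
* **Size spectrum** — log-scale length densities, prominence-based peak
  detection (the canonical peaks sit near 140, 280, 1150 and 8400 bp), and
  repeat-type enrichment inside peak windows via studentized residuals of a
  proportion-on-proportion regression.
* **Community ecology** — Shannon H = −Σ pᵢ ln pᵢ, Pielou J = H/ln S,
  Bray–Curtis d = Σ|u−v|/Σ(u+v), PCoA, DCA gradient length (RDA/CCA
  decision), and redundancy analysis with seeded permutation inference.
* **Model selection** — nine candidate curves fit by OLS or
  Levenberg–Marquardt and ranked by RSS-based information criteria
  (AIC = n·ln(SSres/n) + 2k, BIC = n·ln(SSres/n) + k·ln n), with
  Jacobian/t confidence bands restricted to the observed x-range.
* **Population statistics** — Weir–Cockerham F_ST (per-site variance
  components a, b, c; genome-wide ratio of sums Σa/Σ(a+b+c)), Wilcoxon
  rank-sum contrasts, genotype–phenotype ANOVA, and 2×2 chi-square tests.

A first-class synthetic-cohort generator (`simulate_cohort()`) emulates the
statistical structure these analyses assume — sharing states, repeat-type
mixtures, length peaks, X bias of large rep-SVs, genotype missingness — with
complete ground truth, so every stage is validated end-to-end against known
answers and independent brute-force oracles.

## Worked example

```r
library(repsv)

## simulate a 30-individual, 3000-SV cohort with known truth
co  <- simulate_cohort(cohort_config(seed = 42))
ann <- annotate_cohort(co$callset, co$repeats, co$metadata, co$genes)

mean(ann$is_rep)          # 0.745  -- fraction of SVs touching a repeat
table(ann$state)
#> private_indicine  private_taurine           shared         specific
#>              474              435             1366              725

## X-vs-autosome density ratio at the 8-kb split (no bias planted here)
density_ratio_profile(ann, co$genome, c(50, 8000))
#>   threshold rep_ratio nonrep_ratio
#> 1        50 1.0492371     1.178209
#> 2      8000 0.7619048     2.035088

## community ecology of repeat-type composition
comp <- composition_matrix(ann, co$callset, co$metadata, "all")
dp   <- diversity_profile(comp)
mean(dp$shannon); mean(dp$pielou)   # 1.572, 0.808
rda(comp, co$metadata$subspecies, n_perm = 999, seed = 1)
#> <rda_result> constrained fraction 0.199, p = 0.006 (999 permutations)

## population differentiation between the subspecies
nh <- co$metadata$subspecies != "hybrid"
weir_cockerham_fst(co$callset$gt[, nh], co$metadata$subspecies[nh])$overall
#> 0.149

## model selection on simulated power-law data
d   <- simulate_regression_data("Power", c(0.8, 2.6), n = 50,
                                noise_sd = 2, seed = 7)
sel <- select_best(fit_all_models(d$x, d$y))
sel$best
#> <model_fit> Power: a = 0.8209, b = 2.589 | R^2 = 0.9995, AIC = 74.92, BIC = 78.75
```

The rep-SV fraction, state proportions and diversity values reflect the
generator's configured study conditions; the RDA constrained fraction and
F_ST are genuine subspecies signal created by the state-conditional carrier
frequencies; and the Power fit recovers the generating parameters
(a = 0.8, b = 2.6) within noise.

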