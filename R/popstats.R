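## Population differentiation and genotype-phenotype association on SV
## genotypes. F_ST follows the Weir & Cockerham (1984) variance-component
## estimator on biallelic presence/absence alleles, with the genome-wide
## summary as a ratio of summed components (the weighted estimator of the
## standard VCF tooling).

#' Weir-Cockerham F_ST
#'
#' Per-site variance components for `r` groups: with per-group sample sizes
#' `n_i` (non-missing diploid individuals), alternate-allele frequencies
#' `p_i` and observed heterozygote frequencies `h_i`,
#' \deqn{a = \frac{\bar n}{n_c}\left(s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right)}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right)}
#' \deqn{c = \bar h / 2}
#' and per-site `theta = a / (a + b + c)`. Sites monomorphic across all
#' groups are undefined (NA); negative estimates are preserved. The
#' genome-wide value is `sum(a) / sum(a + b + c)`.
#'
#' @param gt integer matrix, SVs x individuals, alt-allele counts 0/1/2 with
#'   NA for missing.
#' @param groups group label per individual; at least 2 groups with >= 1
#'   non-missing genotype per site (sites missing an entire group are
#'   skipped and counted in attribute `n_skipped`).
#' @return list `per_site` (data.frame `a`, `b`, `c`, `theta`),
#'   `overall` (ratio-of-sums estimate), `n_used`, `n_skipped`.
#' @export
weir_cockerham_fst <- function(gt, groups) {
  gt <- as.matrix(gt)
  groups <- droplevels(factor(groups))
  r <- nlevels(groups)
  if (r < 2) stop("need >= 2 groups")
  lev <- levels(groups)
  nsv <- nrow(gt)

  comp <- matrix(NA_real_, nsv, 3, dimnames = list(rownames(gt), c("a", "b", "c")))
  skipped <- logical(nsv)
  ## per-group per-site n, p, h
  n_i <- sapply(lev, function(g) rowSums(!is.na(gt[, groups == g, drop = FALSE])))
  p_i <- sapply(lev, function(g)
    rowSums(gt[, groups == g, drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(lev, function(g)
    rowSums(gt[, groups == g, drop = FALSE] == 1L, na.rm = TRUE)) / n_i
  if (nsv == 1) { n_i <- rbind(n_i); p_i <- rbind(p_i); h_i <- rbind(h_i) }

  skipped <- rowSums(n_i == 0) > 0
  ok <- which(!skipped)
  nbar <- rowMeans(n_i)
  nsum <- rowSums(n_i)
  nc <- (nsum - rowSums(n_i^2) / nsum) / (r - 1)
  pbar <- rowSums(n_i * p_i) / nsum
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / nsum

  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
        hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  mono <- pbar %in% c(0, 1) & hbar == 0
  use <- !skipped & !mono
  comp[use, "a"] <- a[use]; comp[use, "b"] <- b[use]; comp[use, "c"] <- cc[use]
  theta <- comp[, "a"] / (comp[, "a"] + comp[, "b"] + comp[, "c"])

  denom <- sum(comp[use, , drop = FALSE])
  overall <- if (is.finite(denom) && denom != 0)
    sum(comp[use, "a"]) / denom else NA_real_
  list(per_site = data.frame(comp, theta = theta),
       overall = overall, n_used = sum(use), n_skipped = sum(skipped))
}

#' Two-group contrast of per-individual proportions
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration when both groups have
#' at most 10 observations and the data are tie-free, otherwise the normal
#' approximation with tie correction. All values tied across groups gives
#' p = 1.
#'
#' @param values numeric vector (e.g. per-individual proportions of one
#'   repeat type).
#' @param groups two-level grouping.
#' @return list `statistic` (W), `p_value`, `method`.
#' @export
group_frequency_contrast <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all tied)"))
  want_exact <- length(x) <= 10 && length(y) <= 10
  has_ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = want_exact && !has_ties, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (want_exact && !has_ties) "exact" else "normal approximation")
}

#' One-way ANOVA of a phenotype on SV genotype classes
#'
#' Genotype classes with a single observation are dropped with a warning;
#' at least two classes with two observations each are required. A
#' zero-within-variance separation of class means yields an unbounded F and
#' p approaching 0.
#'
#' @param genotypes integer vector of alt-allele counts (0/1/2; NA dropped).
#' @param phenotype numeric phenotype values.
#' @return list `f_statistic`, `df`, `p_value`, `group_means`.
#' @export
genotype_anova <- function(genotypes, phenotype) {
  ok <- !is.na(genotypes) & !is.na(phenotype)
  g <- factor(genotypes[ok]); ph <- phenotype[ok]
  sizes <- table(g)
  if (any(sizes < 2)) {
    warning("dropping genotype class(es) with a single observation: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- g %in% names(sizes)[sizes >= 2]
    g <- droplevels(g[keep]); ph <- ph[keep]
  }
  if (nlevels(g) < 2) stop("need >= 2 genotype classes with >= 2 observations")
  fit <- stats::aov(ph ~ g)
  s <- summary(fit)[[1]]
  list(f_statistic = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = s[["Pr(>F)"]][1],
       group_means = tapply(ph, g, mean))
}

#' Pearson chi-square on a 2x2 table
#'
#' `X^2 = sum((O - E)^2 / E)` without continuity correction; a zero marginal
#' is an error.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list `statistic`, `df` (= 1), `p_value`.
#' @export
proportion_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero marginal")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Simulate Balding-Nichols differentiated genotypes
#'
#' Two subpopulations drift from a common ancestral frequency with
#' differentiation parameter F: ancestral `p ~ U(0.1, 0.9)`, subpopulation
#' frequencies `p_i ~ Beta(p (1-F)/F, (1-p)(1-F)/F)`, genotypes
#' `Binomial(2, p_i)`. Used to validate the F_ST estimator: the
#' ratio-of-sums estimate recovers F.
#'
#' @param n_sites number of sites.
#' @param n_per_group diploid individuals per group.
#' @param F differentiation parameter in (0, 1).
#' @param seed integer seed.
#' @return list `gt` (sites x individuals matrix), `groups`.
#' @export
simulate_balding_nichols <- function(n_sites, n_per_group = 50, F = 0.2,
                                     seed = 1) {
  if (F <= 0 || F >= 1) stop("F must lie in (0, 1)")
  set.seed(seed)
  p <- stats::runif(n_sites, 0.1, 0.9)
  shape <- (1 - F) / F
  p1 <- stats::rbeta(n_sites, p * shape, (1 - p) * shape)
  p2 <- stats::rbeta(n_sites, p * shape, (1 - p) * shape)
  g1 <- matrix(stats::rbinom(n_sites * n_per_group, 2, p1),
               n_sites, n_per_group)
  g2 <- matrix(stats::rbinom(n_sites * n_per_group, 2, p2),
               n_sites, n_per_group)
  list(gt = cbind(g1, g2),
       groups = rep(c("pop1", "pop2"), each = n_per_group))
}
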