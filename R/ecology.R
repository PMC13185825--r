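## Community-ecology profiling of repeat-type composition. Individuals are
## "sites", repeat types are "species", and the counts of carried rep-SVs
## form the community matrix. Alpha diversity and dissimilarity are delegated
## to vegan (the field-standard implementation); the constrained ordination
## is computed directly from its least-squares definition so that scores,
## eigenvalues and the permutation scheme are fully specified.

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over types with positive counts, natural log.
#'
#' @param counts non-negative count vector with positive total.
#' @return H in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Pielou's evenness J
#'
#' `J = H / ln(S)` where S is the number of types with positive count.
#' Undefined (NA, with a warning) when S <= 1.
#'
#' @param counts non-negative count vector.
#' @return J in `[0, 1]`, or NA.
#' @export
pielou <- function(counts) {
  S <- sum(counts > 0)
  if (S <= 1) {
    warning("richness <= 1: evenness undefined")
    return(NA_real_)
  }
  shannon(counts) / log(S)
}

#' Per-individual diversity profile
#'
#' @param mat composition matrix (individuals x types).
#' @return data.frame `individual`, `richness`, `shannon`, `pielou`.
#' @export
diversity_profile <- function(mat) {
  data.frame(
    individual = rownames(mat),
    richness = apply(mat, 1, function(r) sum(r > 0)),
    shannon = apply(mat, 1, shannon),
    pielou = apply(mat, 1, function(r) suppressWarnings(pielou(r))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)` on raw counts by default;
#' `relative = TRUE` normalises rows to proportions first.
#'
#' @param mat composition matrix (>= 2 rows, non-negative).
#' @param relative normalise rows first (default `FALSE`).
#' @return a `dist` object with values in `[0, 1]`.
#' @export
bray_curtis <- function(mat, relative = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 individuals")
  if (any(mat < 0)) stop("counts must be non-negative")
  zero <- rowSums(mat) == 0
  if (any(zero))
    stop("all-zero row(s): ",
         paste(rownames(mat)[zero], collapse = ", "))
  if (relative) mat <- mat / rowSums(mat)
  vegan::vegdist(mat, method = "bray")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling (double-centering + eigendecomposition) with the
#' same sign convention as [individual_ratio_pca()]. Negative eigenvalues are
#' reported but excluded from the variance fractions.
#'
#' @param d a `dist` or symmetric matrix with zero diagonal.
#' @return list `scores`, `eigenvalues`, `var_explained` (over positive
#'   eigenvalues).
#' @export
pcoa_on_distance <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  k <- nrow(m) - 1
  ## k = n-1 requested; axes with non-positive eigenvalues are dropped by
  ## cmdscale (with a chatty warning we silence)
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  eig <- mds$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  scores <- mds$points
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  list(scores = scores, eigenvalues = eig,
       var_explained = pmax(eig[seq_len(ncol(scores))], 0) / sum(eig[pos]))
}

#' DCA gradient length of axis 1
#'
#' Detrended correspondence analysis (detrending by segments, no nonlinear
#' rescaling) via [vegan::decorana]; the gradient length is the range of the
#' axis-1 site scores in SD units. Lengths below 3 recommend the linear
#' ordination (RDA), longer gradients recommend the unimodal one (CCA, not
#' implemented here).
#'
#' @param mat composition matrix (non-negative; all-zero rows/columns are
#'   dropped).
#' @return list `length`, `recommendation` (`"RDA"` or `"CCA"`). Degenerate
#'   matrices (rank < 2) return length 0 with a warning.
#' @export
gradient_length <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[rowSums(mat) > 0, colSums(mat) > 0, drop = FALSE]
  prof <- mat / rowSums(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2 || qr(prof)$rank < 2) {
    warning("composition matrix has rank < 2; gradient length set to 0")
    return(list(length = 0, recommendation = "RDA"))
  }
  len <- tryCatch({
    dca <- vegan::decorana(mat, iweigh = 0, iresc = 0)
    sc <- vegan::scores(dca, display = "sites", choices = 1)
    diff(range(sc))
  }, error = function(e) {
    warning("degenerate composition matrix (", conditionMessage(e),
            "); gradient length set to 0")
    0
  })
  if (!is.finite(len)) len <- 0
  list(length = len, recommendation = if (len < 3) "RDA" else "CCA")
}

## constrained-variance fraction of a column-centered response given a group
## index; the permutation statistic. rowsum-based, cheap enough to call
## thousands of times.
.rda_fraction <- function(Yc, groups) {
  ss_tot <- sum(Yc^2)
  gm <- rowsum(Yc, groups) / as.vector(table(groups))
  fitted <- gm[as.character(groups), , drop = FALSE]
  sum(fitted^2) / ss_tot
}

#' Redundancy analysis with a permutation test
#'
#' Constrained ordination of a composition matrix on a categorical
#' constraint. The response is column-centered (optionally
#' Hellinger-transformed first); the constraint is dummy-coded (drop-first);
#' fitted values come from multivariate least squares, and the constrained
#' axes are the singular vectors of the fitted matrix. The constrained
#' variance fraction is `trace(fitted' fitted) / trace(Yc' Yc)`. Significance
#' is assessed by freely permuting row identities:
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param response composition matrix (individuals x types).
#' @param constraint factor (or vector) of group labels, one per row;
#'   must have >= 2 levels present.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param hellinger apply the Hellinger transformation before centering
#'   (default `FALSE`).
#' @return list of class `rda_result`: `eigenvalues`, `site_scores`,
#'   `species_scores`, `constrained_fraction`, `axis_fractions` (summing to
#'   the constrained fraction), `p_value`, `n_perm`, `seed`.
#' @export
rda <- function(response, constraint, n_perm = 999, seed = 1,
                hellinger = FALSE) {
  Y <- as.matrix(response)
  groups <- droplevels(factor(constraint))
  if (nlevels(groups) < 2) stop("constraint needs >= 2 levels")
  if (length(groups) != nrow(Y)) stop("constraint length must match rows")
  if (hellinger) Y <- sqrt(Y / rowSums(Y))
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  gm <- rowsum(Yc, groups) / as.vector(table(groups))
  fitted <- gm[as.character(groups), , drop = FALSE]
  ss_tot <- sum(Yc^2)
  frac <- sum(fitted^2) / ss_tot

  n <- nrow(Y)
  sv <- svd(fitted)
  nz <- sv$d > sqrt(.Machine$double.eps) * max(sv$d, 1)
  d <- sv$d[nz]
  site <- sv$u[, nz, drop = FALSE] %*% diag(d, sum(nz))
  species <- sv$v[, nz, drop = FALSE]
  for (j in seq_len(ncol(species))) {
    i <- which.max(abs(species[, j]))
    if (species[i, j] < 0) {
      species[, j] <- -species[, j]
      site[, j] <- -site[, j]
    }
  }
  dimnames(site) <- list(rownames(Y), paste0("RDA", seq_len(ncol(site))))
  dimnames(species) <- list(colnames(Y), colnames(site))
  eig <- d^2 / (n - 1)

  set.seed(seed)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    f <- .rda_fraction(Yc[sample.int(n), , drop = FALSE], groups)
    if (f >= frac) perm_ge <- perm_ge + 1L
  }
  structure(list(
    eigenvalues = eig, site_scores = site, species_scores = species,
    constrained_fraction = frac,
    axis_fractions = d^2 / ss_tot,
    p_value = (1 + perm_ge) / (1 + n_perm),
    n_perm = n_perm, seed = seed
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> constrained fraction %.3f, p = %.4g (%d permutations)\n",
              x$constrained_fraction, x$p_value, x$n_perm))
  invisible(x)
}

#' Evenness-versus-content regression per group
#'
#' Fits, for each group of individuals, a straight line of Pielou's J on
#' repeat content (rep-SV count or summed bp), delegating to
#' [fit_model()] with the Linear model, and returns slope with its 95%
#' confidence interval.
#'
#' @param content per-individual repeat content (numeric).
#' @param evenness per-individual Pielou's J.
#' @param groups group labels (e.g. subspecies).
#' @param level confidence level (default 0.95).
#' @return data.frame per group: `group`, `n`, `slope`, `slope_lo`,
#'   `slope_hi`, `r_squared`; groups with fewer than 3 members are skipped.
#' @export
evenness_content_regression <- function(content, evenness, groups,
                                        level = 0.95) {
  out <- lapply(split(seq_along(content), groups), function(ix) {
    if (length(ix) < 3) return(NULL)
    ok <- is.finite(content[ix]) & is.finite(evenness[ix])
    if (sum(ok) < 3) return(NULL)
    f <- fit_model(content[ix][ok], evenness[ix][ok], "Linear")
    se <- sqrt(diag(f$vcov))[2]
    tq <- stats::qt(1 - (1 - level) / 2, df = f$n - f$k)
    data.frame(group = as.character(groups[ix[1]]), n = sum(ok),
               slope = unname(f$coefficients[2]),
               slope_lo = unname(f$coefficients[2] - tq * se),
               slope_hi = unname(f$coefficients[2] + tq * se),
               r_squared = f$r_squared, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
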