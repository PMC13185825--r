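## X-versus-autosome distribution diagnostics for rep-SVs: OLS outlier
## tests, Cook's-distance sweeps over SV size thresholds, density-ratio
## profiles, Grubbs single-outlier testing with a Shapiro-Wilk normality
## precheck, and per-individual ratio PCA.

#' Per-chromosome rep/nonrep SV counts
#'
#' @param annotations output of [annotate_cohort()].
#' @param genome a [genome_model()].
#' @param min_size count only SVs with `svlen >= min_size` bp (default 50).
#' @return data.frame `chrom`, `length`, `is_x`, `rep_count`, `nonrep_count`.
#' @export
chromosome_counts <- function(annotations, genome, min_size = 50) {
  unknown <- setdiff(unique(annotations$chrom), genome$chrom)
  if (length(unknown))
    stop("annotations contain chromosomes not in the genome: ",
         paste(unknown, collapse = ", "))
  a <- annotations[annotations$svlen >= min_size, , drop = FALSE]
  cnt <- function(rep) {
    tab <- table(factor(a$chrom[a$is_rep == rep], levels = genome$chrom))
    as.integer(tab)
  }
  data.frame(chrom = genome$chrom, length = genome$length, is_x = genome$is_x,
             rep_count = cnt(TRUE), nonrep_count = cnt(FALSE),
             stringsAsFactors = FALSE)
}

#' OLS regression with a Bonferroni outlier test
#'
#' Fits `y ~ x` by ordinary least squares and reports externally studentized
#' residuals; the outlier p-value is the Bonferroni-adjusted two-sided t tail
#' of the largest absolute studentized residual at `n - 3` degrees of
#' freedom (the test used by `car::outlierTest`).
#'
#' @param x,y numeric vectors (length >= 4), e.g. per-chromosome nonrep and
#'   rep counts.
#' @param names optional labels for the observations.
#' @return list with `slope`, `intercept`, `r_squared`, `rstudent`,
#'   `cooks_d`, `outlier` (label or index of the extreme point),
#'   `bonferroni_p`.
#' @export
regression_outlier_test <- function(x, y, names = NULL) {
  if (length(x) < 4) stop("need >= 4 observations")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  res <- residuals(fit)
  rs <- stats::rstudent(fit)
  ss_res0 <- sum(res^2); ss_tot0 <- sum((y - mean(y))^2)
  if (ss_res0 <= 1e-12 * ss_tot0) {
    ## numerically perfect fit: no outliers by definition
    rs[] <- 0
  } else {
    ## NaN arises when the deleted fit is exact: such a point is infinitely
    ## outlying relative to the exact remainder.
    rs[!is.finite(rs)] <- Inf
  }
  if (!is.null(names)) names(rs) <- names
  n <- length(x)
  i_max <- which.max(abs(rs))
  p <- min(1, n * 2 * stats::pt(-abs(rs[i_max]), df = n - 3))
  ss_res <- sum(res^2); ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot,
       rstudent = rs, cooks_d = stats::cooks.distance(fit),
       outlier = if (is.null(names)) i_max else names[i_max],
       bonferroni_p = unname(p))
}

#' Cook's-distance sweep over SV size thresholds
#'
#' For each size threshold, per-chromosome counts of rep- and nonrep-SVs at
#' least that long are regressed and each chromosome's Cook's distance is
#' recorded, alongside the Bonferroni outlier p, X/autosome density ratios,
#' and a Grubbs test (with Shapiro-Wilk precheck) on the per-chromosome
#' ratio of rep-SVs above versus below the threshold.
#'
#' Two regression modes mirror the two published readings of the analysis:
#' `"ratio"` (default) regresses the per-chromosome rep/nonrep count ratio on
#' chromosome length; `"count"` regresses rep counts on nonrep counts.
#'
#' @param annotations output of [annotate_cohort()].
#' @param genome a [genome_model()].
#' @param thresholds ascending vector of size thresholds in bp (default
#'   `c(50, 100, 200, 500, 1000, 2000, 4000, 8000, 16000)`).
#' @param mode `"ratio"` or `"count"`.
#' @return list of per-threshold diagnostics; thresholds leaving fewer than
#'   4 chromosomes with nonzero totals are skipped with a warning. Each
#'   element carries `threshold`, `cooks_d`, `rstudent`, `bonferroni_p`,
#'   `density_ratio_rep`, `density_ratio_nonrep`, `grubbs`, `shapiro_p`.
#' @export
cook_distance_sweep <- function(annotations, genome,
                                thresholds = c(50, 100, 200, 500, 1000,
                                               2000, 4000, 8000, 16000),
                                mode = c("ratio", "count")) {
  mode <- match.arg(mode)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  out <- list()
  for (th in thresholds) {
    cc <- chromosome_counts(annotations, genome, min_size = th)
    ok <- cc$rep_count + cc$nonrep_count > 0
    if (sum(ok) < 4) {
      warning("threshold ", th, " leaves < 4 chromosomes with SVs; skipped")
      next
    }
    cc2 <- cc[ok, , drop = FALSE]
    if (mode == "ratio") {
      yv <- cc2$rep_count / pmax(cc2$nonrep_count, 1)
      xv <- cc2$length
    } else {
      yv <- cc2$rep_count
      xv <- cc2$nonrep_count
    }
    reg <- tryCatch(regression_outlier_test(xv, yv, names = cc2$chrom),
                    error = function(e) NULL)
    dr <- density_ratio_profile(annotations, genome, th)
    ## large/small split statistic for the Grubbs test
    ann_rep <- annotations[annotations$is_rep, ]
    big <- table(factor(ann_rep$chrom[ann_rep$svlen > th], levels = cc2$chrom))
    small <- table(factor(ann_rep$chrom[ann_rep$svlen <= th], levels = cc2$chrom))
    ratio <- as.numeric(big) / pmax(as.numeric(small), 1)
    gr <- tryCatch(grubbs_single_outlier(stats::setNames(ratio, cc2$chrom)),
                   error = function(e) NULL)
    out[[as.character(th)]] <- list(
      threshold = th,
      cooks_d = if (!is.null(reg)) reg$cooks_d,
      rstudent = if (!is.null(reg)) reg$rstudent,
      bonferroni_p = if (!is.null(reg)) reg$bonferroni_p else NA_real_,
      density_ratio_rep = dr$rep_ratio,
      density_ratio_nonrep = dr$nonrep_ratio,
      grubbs = gr,
      shapiro_p = if (!is.null(gr)) gr$shapiro_p else NA_real_
    )
  }
  out
}

#' X-versus-autosome density-ratio profile
#'
#' At each threshold, the ratio compares SV density on the X with pooled
#' (length-weighted) autosomal density:
#' `(count_X / length_X) / (sum(count_autosome) / sum(length_autosome))`,
#' separately for rep- and nonrep-SVs of length at least the threshold. A
#' ratio of 1 means equal density; a zero autosomal count yields `NA`.
#'
#' @param annotations output of [annotate_cohort()].
#' @param genome a [genome_model()].
#' @param thresholds vector of minimum SV sizes in bp.
#' @return data.frame `threshold`, `rep_ratio`, `nonrep_ratio`.
#' @export
density_ratio_profile <- function(annotations, genome, thresholds) {
  xlen <- genome$length[genome$is_x]
  alen <- sum(genome$length[!genome$is_x])
  one <- function(th) {
    cc <- chromosome_counts(annotations, genome, min_size = th)
    ratio <- function(col) {
      xc <- cc[[col]][cc$is_x]
      ac <- sum(cc[[col]][!cc$is_x])
      if (ac == 0) return(NA_real_)
      (xc / xlen) / (ac / alen)
    }
    c(ratio("rep_count"), ratio("nonrep_count"))
  }
  m <- t(vapply(thresholds, one, numeric(2)))
  data.frame(threshold = thresholds, rep_ratio = m[, 1], nonrep_ratio = m[, 2])
}

#' Grubbs single-outlier test with normality precheck
#'
#' Two-sided test on the maximum absolute deviation:
#' `G = max |x_i - mean| / sd`. The p-value uses the closed form through the
#' t-distribution: with `u = n G^2 / (n-1)^2` and
#' `t = sqrt((n-2) u / (1-u))`, `p = min(1, 2 n P(T_{n-2} > t))`. A
#' Shapiro-Wilk p-value is reported alongside; a warning is logged when it
#' falls below 0.05 since the test assumes normality.
#'
#' @param values named numeric vector (length >= 3), e.g. a per-chromosome
#'   statistic.
#' @return list `statistic` (G), `p_value`, `outlier` (name or index of the
#'   most deviant value), `shapiro_p`.
#' @export
grubbs_single_outlier <- function(values) {
  if (length(values) < 3) stop("need >= 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  n <- length(values)
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  u <- n * G^2 / (n - 1)^2
  p <- if (u >= 1) 0 else {
    t_stat <- sqrt((n - 2) * u / (1 - u))
    min(1, 2 * n * stats::pt(t_stat, df = n - 2, lower.tail = FALSE))
  }
  sw <- stats::shapiro.test(values)$p.value
  if (sw < 0.05)
    warning(sprintf("Shapiro-Wilk p = %.3g: values deviate from normality; Grubbs test may be unreliable", sw))
  list(statistic = unname(G), p_value = unname(p),
       outlier = if (is.null(names(values))) i else names(values)[i],
       shapiro_p = sw)
}

#' PCA of per-individual feature tables
#'
#' Thin wrapper around [stats::prcomp] with a fixed sign convention: on each
#' axis the loading of largest magnitude is made positive, so scores are
#' reproducible across platforms.
#'
#' @param features numeric matrix or data.frame, individuals in rows.
#' @param scale. unit-scale columns (default `FALSE`); scaling a constant
#'   column is an error.
#' @return list `scores`, `loadings`, `var_explained` (fractions summing
#'   to 1), `sdev`.
#' @export
individual_ratio_pca <- function(features, scale. = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need >= 2 individuals")
  if (scale. && any(apply(features, 2, stats::sd) == 0))
    stop("constant feature with scaling on")
  pc <- stats::prcomp(features, center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' Per-individual X-linked size-ratio features
#'
#' For each individual, the ratio of X-chromosome rep-SVs longer than
#' `threshold` to those at most `threshold` bp (carried SVs only), the
#' feature analysed by [individual_ratio_pca()].
#'
#' @param annotations output of [annotate_cohort()].
#' @param callset the matching [sv_callset()].
#' @param genome a [genome_model()].
#' @param threshold size split in bp (default [LARGE_SV_THRESHOLD]).
#' @return named numeric vector of per-individual ratios (pseudo-count 1 in
#'   the denominator).
#' @export
x_size_ratio_features <- function(annotations, callset, genome,
                                  threshold = LARGE_SV_THRESHOLD) {
  xname <- genome$chrom[genome$is_x]
  on_x <- annotations$chrom == xname & annotations$is_rep
  pres <- presence_matrix(callset)
  pres[is.na(pres)] <- FALSE
  big <- colSums(pres[on_x & annotations$svlen > threshold, , drop = FALSE])
  small <- colSums(pres[on_x & annotations$svlen <= threshold, , drop = FALSE])
  big / pmax(small, 1)
}
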