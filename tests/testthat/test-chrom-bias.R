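test_that("chromosome counts respect size thresholds and partition totals", {
  co <- simulate_cohort(cohort_config(seed = 13, n_sv = 500))
  ann <- annotate_cohort(co$callset, co$repeats, co$metadata)
  cc <- chromosome_counts(ann, co$genome, min_size = 50)
  expect_equal(sum(cc$rep_count + cc$nonrep_count), nrow(ann))
  cc2 <- chromosome_counts(ann, co$genome, min_size = max(ann$svlen) + 1)
  expect_true(all(cc2$rep_count + cc2$nonrep_count == 0))
  bad <- ann; bad$chrom[1] <- "chrZZ"
  expect_error(chromosome_counts(bad, co$genome), "chrZZ")
})

test_that("outlier regression flags a constructed off-line point", {
  ## 10 near-collinear points + 1 displaced
  set.seed(12)
  x <- c(1:10, 6)
  y <- c(2 * (1:10) + rnorm(10, 0, 0.05), 40)
  r <- regression_outlier_test(x, y, names = c(paste0("c", 1:10), "out"))
  expect_equal(r$outlier, "out")
  expect_lt(r$bonferroni_p, 0.05)
  expect_equal(unname(which.max(abs(r$rstudent))), 11L)
  ## exact line: R^2 = 1, residuals all ~0
  r2 <- regression_outlier_test(1:10, 2 * (1:10))
  expect_equal(r2$r_squared, 1)
  expect_true(all(abs(r2$rstudent) < 1e-8))
  ## duplicated data leave the fit unchanged
  r3 <- regression_outlier_test(rep(x, 2), rep(y, 2))
  expect_equal(r3$slope, r$slope, tolerance = 1e-12)
  expect_error(regression_outlier_test(rep(1, 5), 1:5), "zero variance")
  ## agrees with the reference implementation of the Bonferroni outlier test
  skip_if_not_installed("car")
  ref <- car::outlierTest(lm(y ~ x), cutoff = Inf, n.max = 1)
  expect_equal(r$bonferroni_p, unname(ref$bonf.p), tolerance = 1e-10)
  expect_equal(unname(r$rstudent[11]), unname(ref$rstudent), tolerance = 1e-10)
})

test_that("diagnostics match the leave-one-out refit oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
    fit <- lm(y ~ x)
    orc <- loo_diagnostics(x, y)
    expect_equal(unname(rstudent(fit)), orc$rstudent, tolerance = 1e-10)
    expect_equal(unname(cooks.distance(fit)), orc$cooks, tolerance = 1e-10)
    ## and the packaged wrapper exposes the same numbers
    r <- regression_outlier_test(x, y)
    expect_equal(unname(r$cooks_d), orc$cooks, tolerance = 1e-10)
  }
})

test_that("an influential chromosome dominates the Cook sweep", {
  ## 5-point fixture with a hand-placed influential point
  x <- c(10, 20, 30, 40, 80)
  y <- c(21, 39, 61, 79, 250)
  r <- regression_outlier_test(x, y)
  expect_equal(unname(which.max(r$cooks_d)), 5L)
  expect_gt(max(r$cooks_d), 4 / 5)
  ## removing it changes the slope in the direction the residual predicts
  slope_full <- r$slope
  slope_wo <- coef(lm(y[-5] ~ x[-5]))[2]
  expect_true((slope_full - slope_wo) * sign(r$rstudent[5]) > 0)
})

test_that("density ratios are calibrated against generator truth", {
  co1 <- simulate_cohort(cohort_config(seed = 41, x_bias = 1))
  ann1 <- annotate_cohort(co1$callset, co1$repeats, co1$metadata)
  dr1 <- density_ratio_profile(ann1, co1$genome, c(50, 8000))
  expect_equal(dr1$rep_ratio[1], 1, tolerance = 0.25)
  co3 <- simulate_cohort(cohort_config(seed = 41, x_bias = 3))
  ann3 <- annotate_cohort(co3$callset, co3$repeats, co3$metadata)
  dr3 <- density_ratio_profile(ann3, co3$genome, c(50, 8000))
  expect_gt(dr3$rep_ratio[2], 2)                   # biased threshold recovers ~3
  expect_lt(abs(dr3$rep_ratio[1] - 1), abs(dr3$rep_ratio[2] - 1))
  ## zero X count -> ratio 0
  annx <- ann1[ann1$chrom != "chrX", ]
  dr0 <- density_ratio_profile(annx, co1$genome, 50)
  expect_equal(dr0$rep_ratio, 0)
})

test_that("density ratios are invariant to relabeling and length scaling", {
  co <- simulate_cohort(cohort_config(seed = 19, n_sv = 500))
  ann <- annotate_cohort(co$callset, co$repeats, co$metadata)
  dr <- density_ratio_profile(ann, co$genome, c(50, 1000))
  ## uniform scaling of all chromosome lengths cancels
  g2 <- co$genome; g2$length <- g2$length * 7
  expect_equal(density_ratio_profile(ann, g2, c(50, 1000)), dr)
  ## relabeling chromosomes (consistently) changes nothing
  map <- setNames(paste0("K", seq_len(nrow(co$genome))), co$genome$chrom)
  g3 <- co$genome; g3$chrom <- unname(map[g3$chrom])
  ann3 <- ann; ann3$chrom <- unname(map[ann3$chrom])
  dr3 <- density_ratio_profile(ann3, g3, c(50, 1000))
  expect_equal(dr3$rep_ratio, dr$rep_ratio)
})

test_that("Grubbs test matches its closed form and flags gross outliers", {
  v <- c(1, 1, 1, 1, 10)
  expect_warning(g <- grubbs_single_outlier(v), "normality")
  expect_equal(g$statistic, (10 - 2.8) / sd(v))    # G = max dev / sd
  expect_equal(g$outlier, 5L)
  expect_lt(g$p_value, 0.05)
  expect_error(grubbs_single_outlier(rep(2, 6)), "degenerate")
  ## closed form against a hand-derived value at n = 8
  x <- c(-1.2, -0.8, -0.3, 0.1, 0.4, 0.9, 1.1, 3.5)
  gg <- suppressWarnings(grubbs_single_outlier(x))
  n <- 8; G <- max(abs(x - mean(x))) / sd(x)
  u <- n * G^2 / (n - 1)^2
  tt <- sqrt((n - 2) * u / (1 - u))
  expect_equal(gg$p_value, min(1, 2 * n * pt(tt, n - 2, lower.tail = FALSE)))
})

test_that("ratio PCA separates simulated subspecies and fixes signs", {
  set.seed(3)
  f <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
  p <- individual_ratio_pca(f)
  expect_equal(sum(p$var_explained), 1)
  grp <- rep(1:2, each = 20)
  ## PC1 separates the groups (positive silhouette-like margin)
  m1 <- mean(p$scores[grp == 1, 1]); m2 <- mean(p$scores[grp == 2, 1])
  s <- sd(p$scores[, 1])
  expect_gt(abs(m1 - m2) / s, 1)
  ## largest loading on each axis is positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  ## one nonzero-variance direction -> PC1 explains everything
  one <- cbind(1:10, (1:10) * 2)
  p1 <- individual_ratio_pca(one)
  expect_equal(p1$var_explained[1], 1)
  expect_error(individual_ratio_pca(cbind(rep(1, 5), 1:5), scale. = TRUE),
               "constant")
})
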