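test_that("diversity indices match their defining formulas", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), 0.5 * log(2) + 2 * 0.25 * log(4))
  expect_equal(pielou(c(2, 1, 1)), shannon(c(2, 1, 1)) / log(3))
  expect_equal(pielou(c(7, 7, 7, 7, 7)), 1)        # uniform is perfectly even
  expect_warning(j <- pielou(c(1, 0)), "undefined")
  expect_true(is.na(j))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("Bray-Curtis follows the count-based formula", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 1), c(2, 0)))), 0.5)
  expect_equal(as.numeric(bray_curtis(rbind(c(3, 2), c(3, 2)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(5, 0), c(0, 9)))), 1)
  m <- rbind(a = c(1, 2), b = c(0, 0))
  expect_error(bray_curtis(m), "b")
})

test_that("diversity and dissimilarity agree with brute-force oracles", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rpois(6 * 5, lambda = sample(2:30, 1)), 6, 5)
    m[m < 0] <- 0
    m <- m + 1   # avoid all-zero rows
    for (r in seq_len(nrow(m))) {
      expect_equal(shannon(m[r, ]), shannon_oracle(m[r, ]), tolerance = 1e-12)
      expect_equal(pielou(m[r, ]), pielou_oracle(m[r, ]), tolerance = 1e-12)
    }
    d <- as.matrix(bray_curtis(m))
    for (a in 1:5) for (b in (a + 1):6)
      expect_equal(d[b, a], bray_oracle(m[a, ], m[b, ]), tolerance = 1e-12)
  }
})

test_that("PCoA reproduces PCA on Euclidean distances", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  p_ref <- prcomp(X, center = TRUE)
  pc <- pcoa_on_distance(dist(X))
  ## same variance profile and same scores up to sign
  expect_equal(pc$var_explained[1:3],
               p_ref$sdev[1:3]^2 / sum(p_ref$sdev^2), tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(abs(pc$scores[, j]), abs(p_ref$x[, j]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  ## collinear points load a single axis
  line <- cbind(1:8)
  pl <- pcoa_on_distance(dist(line))
  expect_equal(pl$var_explained[1], 1)
  expect_error(pcoa_on_distance(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("DCA gradient length drives the RDA/CCA recommendation", {
  ## near-identical rows: negligible gradient -> RDA
  m <- matrix(rep(c(30, 20, 10, 5), each = 8), 8) +
    matrix(rbinom(32, 2, 0.5), 8)
  gl <- gradient_length(m)
  expect_lt(gl$length, 3)
  expect_equal(gl$recommendation, "RDA")
  ## long single gradient with high species turnover -> CCA
  set.seed(5)
  n_site <- 30; n_sp <- 20
  opt <- seq(0, 10, length.out = n_sp)
  pos <- seq(0, 10, length.out = n_site)
  mu <- outer(pos, opt, function(a, b) 60 * exp(-(a - b)^2 / 0.8))
  comm <- matrix(rpois(length(mu), mu), n_site)
  comm <- comm[rowSums(comm) > 0, colSums(comm) > 0]
  gl2 <- gradient_length(comm)
  expect_gt(gl2$length, 3)
  expect_equal(gl2$recommendation, "CCA")
  ## against the reference implementation with the same settings
  ref <- vegan::decorana(comm, iweigh = 0, iresc = 0)
  ref_len <- diff(range(vegan::scores(ref, display = "sites", choices = 1)))
  expect_equal(gl2$length, ref_len, tolerance = 1e-10)
  ## invariant to row order
  perm <- sample(nrow(comm))
  expect_equal(gradient_length(comm[perm, ])$length, gl2$length,
               tolerance = 1e-8)
  ## degenerate matrix falls back to 0 with a warning
  expect_warning(gl0 <- gradient_length(matrix(c(5, 5, 5, 5), 2)), "rank < 2")
  expect_equal(gl0$length, 0)
})

test_that("RDA recovers exact group structure and matches vegan", {
  groups <- rep(c("a", "b", "c"), each = 4)
  gm <- rbind(c(10, 0, 5), c(0, 10, 5), c(5, 5, 10))
  Y_exact <- gm[match(groups, c("a", "b", "c")), ]
  r <- rda(Y_exact, groups, n_perm = 99, seed = 1)
  expect_equal(r$constrained_fraction, 1, tolerance = 1e-12)
  expect_equal(sum(r$axis_fractions), r$constrained_fraction, tolerance = 1e-12)
  ## noisy case: fraction matches the reference implementation
  set.seed(14)
  Y <- Y_exact + matrix(rnorm(36), 12, 3)
  r2 <- rda(Y, groups, n_perm = 99, seed = 1)
  vr <- vegan::rda(Y ~ g, data = data.frame(g = factor(groups)))
  expect_equal(r2$constrained_fraction,
               vr$CCA$tot.chi / vr$tot.chi, tolerance = 1e-10)
  expect_equal(sort(r2$eigenvalues, decreasing = TRUE), r2$eigenvalues)
  ## binary constraint -> exactly one constrained axis
  rb <- rda(Y, rep(c("x", "y"), 6), n_perm = 49, seed = 2)
  expect_equal(length(rb$eigenvalues), 1)
  expect_error(rda(Y, rep("only", 12)), "levels")
})

test_that("RDA permutation p is reproducible and sensitive to real signal", {
  set.seed(33)
  groups <- rep(c("t", "i"), each = 8)
  Y <- matrix(rpois(16 * 5, 20), 16, 5)
  Y[groups == "t", 1] <- Y[groups == "t", 1] + 25    # strong group effect
  r1 <- rda(Y, groups, n_perm = 199, seed = 5)
  r2 <- rda(Y, groups, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
})

test_that("evenness-content regression delegates to the Linear model fit", {
  set.seed(10)
  content <- rep(seq(100, 400, length.out = 10), 2)
  groups <- rep(c("taurine", "indicine"), each = 10)
  evenness <- ifelse(groups == "taurine",
                     0.95 - 0.0008 * content, 0.85 + 0 * content) +
    rnorm(20, 0, 0.005)
  fits <- evenness_content_regression(content, evenness, groups)
  tau <- fits[fits$group == "taurine", ]
  expect_lt(tau$slope, 0)
  expect_lt(tau$slope_hi, 0)                       # CI excludes zero
  ## identical numbers as a direct Linear fit
  direct <- fit_model(content[groups == "taurine"],
                      evenness[groups == "taurine"], "Linear")
  expect_equal(tau$slope, unname(direct$coefficients[2]))
  ## groups below 3 members are skipped
  f2 <- evenness_content_regression(content[1:4], evenness[1:4],
                                    c("a", "a", "a", "b"))
  expect_equal(f2$group, "a")
})
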