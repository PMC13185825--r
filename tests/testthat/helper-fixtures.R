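## Shared fixture builders and brute-force oracles. Every oracle here is a
## direct transcription of the defining formula, independent of the package's
## implementation path.

make_callset <- function(chrom, pos, end, svtype, svlen, gt = NULL,
                         samples = character(), id = NULL,
                         source = "fixture") {
  n <- length(pos)
  if (is.null(id)) id <- sprintf("fx_%03d", seq_len(n))
  sv_callset(
    data.frame(id = id, chrom = chrom, pos = pos, end = end,
               svtype = svtype, svlen = svlen, stringsAsFactors = FALSE),
    gt, samples = samples, source = source
  )
}

## metadata for a small cohort
make_meta <- function(n_t = 2, n_i = 2, n_h = 0) {
  n <- n_t + n_i + n_h
  data.frame(
    individual = sprintf("ind_%02d", seq_len(n)),
    subspecies = c(rep("taurine", n_t), rep("indicine", n_i),
                   rep("hybrid", n_h)),
    stringsAsFactors = FALSE
  )
}

## ---- brute-force diversity oracles (definitional) ----
shannon_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}
pielou_oracle <- function(counts) {
  S <- sum(counts > 0)
  if (S <= 1) return(NA_real_)
  shannon_oracle(counts) / log(S)
}
bray_oracle <- function(u, v) sum(abs(u - v)) / sum(u + v)

## ---- leave-one-out regression diagnostics oracle ----
## externally studentized residual and Cook's distance for y ~ x by literal
## refitting without observation i.
loo_diagnostics <- function(x, y) {
  n <- length(x)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  p <- 2
  s2 <- sum(residuals(fit)^2) / (n - p)
  rstud <- cooks <- numeric(n)
  for (i in seq_len(n)) {
    fi <- lm(y[-i] ~ x[-i])
    pred_i <- coef(fi)[1] + coef(fi)[2] * x[i]
    s2_i <- sum(residuals(fi)^2) / (n - 1 - p)
    X_i <- cbind(1, x[-i])
    h_loo <- c(cbind(1, x[i]) %*% solve(crossprod(X_i)) %*% t(cbind(1, x[i])))
    rstud[i] <- (y[i] - pred_i) / sqrt(s2_i * (1 + h_loo))
    yhat_i <- coef(fi)[1] + coef(fi)[2] * x
    cooks[i] <- sum((yhat - yhat_i)^2) / (p * s2)
  }
  list(rstudent = rstud, cooks = cooks)
}

## ---- brute-force interval overlap oracle ----
## all-pairs overlap bp between SV effective intervals and repeat intervals,
## returning per-SV total and dominant type (lexicographic tie-break).
overlap_oracle <- function(eff, repeats) {
  n <- nrow(eff)
  rep_type <- rep(NA_character_, n)
  total <- dominant_bp <- numeric(n)
  for (i in seq_len(n)) {
    bp <- c()
    for (j in seq_len(nrow(repeats))) {
      if (eff$chrom[i] != repeats$chrom[j]) next
      ov <- min(eff$end[i], repeats$end[j]) - max(eff$start[i], repeats$start[j])
      if (ov > 0) {
        t <- repeats$rep_type[j]
        bp[t] <- if (is.null(bp[t]) || is.na(bp[t])) ov else bp[t] + ov
      }
    }
    if (length(bp)) {
      bp <- bp[order(names(bp))]
      total[i] <- sum(bp)
      k <- which(bp == max(bp))[1]
      rep_type[i] <- names(bp)[k]
      dominant_bp[i] <- bp[k]
    }
  }
  list(total = total, rep_type = rep_type, dominant_bp = dominant_bp)
}
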