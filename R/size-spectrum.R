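## SV length spectra: log-scale densities, modal-peak detection with
## prominence-based windows, and repeat-type enrichment within peak windows
## via a proportion-on-proportion regression with studentized residuals.

#' Canonical size-peak windows
#'
#' The four modal peaks of the repeat-mediated SV length distribution
#' (~140, ~280, ~1150 and ~8400 bp) with their windows; the first two are
#' dominated by Bov-A2, the last two by LTR/ERVK.
#' @return data.frame `center`, `lo`, `hi`.
#' @export
default_peak_windows <- function() {
  data.frame(center = c(140, 280, 1150, 8400),
             lo = c(125, 252, 1018, 7686),
             hi = c(158, 316, 1263, 9689))
}

#' Log-scale length density
#'
#' Histogram on a fixed log10(length) grid plus a kernel-smoothed density,
#' per group. Histogram densities integrate to 1 over the log10 axis.
#'
#' @param annotations annotation table with `svlen` (and the grouping
#'   columns).
#' @param group_by optional column name(s) to stratify by (e.g. `"svtype"`,
#'   `"is_rep"`); NULL pools everything.
#' @param binwidth bin width on the log10 axis (default 0.02).
#' @return list of class `length_density`, one element per group:
#'   `lengths`, `hist` (data.frame `log10_mid`, `density`), `smooth`
#'   (data.frame `log10` grid and `density`). Empty groups are dropped with
#'   a warning.
#' @export
length_density <- function(annotations, group_by = NULL, binwidth = 0.02) {
  if (any(annotations$svlen < 50)) stop("lengths must be >= 50 bp")
  groups <- if (is.null(group_by)) list(all = annotations)
            else split(annotations, annotations[group_by], drop = TRUE)
  groups <- Filter(nrow, groups)
  if (!length(groups)) {
    warning("no SVs to profile")
    return(structure(list(), class = "length_density"))
  }
  out <- lapply(groups, function(g) {
    lg <- log10(g$svlen)
    brk <- seq(floor(min(lg) / binwidth) * binwidth,
               ceiling(max(lg) / binwidth) * binwidth + binwidth, by = binwidth)
    h <- graphics::hist(lg, breaks = brk, plot = FALSE)
    bw <- tryCatch(stats::bw.SJ(lg, method = "ste"), error = function(e) NULL)
    if (is.null(bw) || !is.finite(bw) || bw <= 0)
      bw <- max(stats::bw.nrd0(lg), binwidth)
    sm <- stats::density(lg, bw = bw, n = 512)
    list(lengths = g$svlen,
         hist = data.frame(log10_mid = h$mids, density = h$density),
         smooth = data.frame(log10 = sm$x, density = sm$y))
  })
  structure(out, class = "length_density")
}

## local maxima of y (strict rise then fall; plateau peaks take the first
## index), with topographic prominence.
local_peaks <- function(y) {
  n <- length(y)
  d <- diff(y)
  up <- c(FALSE, d > 0)
  down <- c(d < 0, FALSE)
  idx <- which(up & down)
  if (!length(idx)) return(data.frame(idx = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- if (i < n) y[(i + 1):n] else numeric()
    base_side <- function(side) {
      if (!length(side)) return(min(y))
      higher <- which(side > h)
      if (length(higher)) {
        ## nearest higher terrain bounds the key col
        if (identical(side, left)) min(side[(max(higher)):(i - 1)])
        else min(side[1:min(higher)])
      } else min(side)
    }
    h - max(base_side(left), base_side(right))
  }, numeric(1))
  data.frame(idx = idx, prominence = prom)
}

#' Detect peaks in a length density
#'
#' Local maxima of the kernel-smoothed log-scale density with topographic
#' prominence at least `min_prominence`; each peak's window is the contiguous
#' region above half its prominence.
#'
#' @param dens one group element of [length_density()] (a list with
#'   `smooth` and `lengths`), or a whole `length_density` of one group.
#' @param min_prominence minimum prominence on the density scale
#'   (default 0.05; 0 reports every local maximum).
#' @return data.frame of peaks sorted by center: `center`, `lo`, `hi` (bp),
#'   `n` (SVs inside the window), `prominence`.
#' @export
detect_peaks <- function(dens, min_prominence = 0.05) {
  if (inherits(dens, "length_density")) {
    if (length(dens) != 1) stop("pass a single group, or subset the density")
    dens <- dens[[1]]
  }
  x <- dens$smooth$log10; y <- dens$smooth$density
  pk <- local_peaks(y)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(pk)) {
    return(data.frame(center = numeric(), lo = numeric(), hi = numeric(),
                      n = integer(), prominence = numeric()))
  }
  res <- lapply(seq_len(nrow(pk)), function(r) {
    i <- pk$idx[r]
    cut_level <- y[i] - pk$prominence[r] / 2
    lo_i <- i; while (lo_i > 1 && y[lo_i - 1] >= cut_level) lo_i <- lo_i - 1
    hi_i <- i; while (hi_i < length(y) && y[hi_i + 1] >= cut_level) hi_i <- hi_i + 1
    lo <- 10^x[lo_i]; hi <- 10^x[hi_i]
    data.frame(center = 10^x[i], lo = lo, hi = hi,
               n = if (!is.null(dens$lengths))
                 sum(dens$lengths >= lo & dens$lengths <= hi) else NA_integer_,
               prominence = pk$prominence[r])
  })
  out <- do.call(rbind, res)
  out[order(out$center), , drop = FALSE]
}

## shared core of the proportion/count regression residual screen:
## regress y on x across repeat types, flag types whose externally
## studentized residual survives Bonferroni correction over types.
type_residual_screen <- function(x, y, types, alpha = 0.05) {
  m <- length(types)
  fit <- stats::lm(y ~ x)
  rs <- stats::rstudent(fit)
  p_adj <- pmin(1, m * 2 * stats::pt(-abs(rs), df = m - 3))
  data.frame(rep_type = types, overall = x, subset = y,
             rstudent = rs, bonferroni_p = p_adj,
             flagged = p_adj < alpha, stringsAsFactors = FALSE)
}

#' Repeat-type enrichment within a size window
#'
#' Compares the repeat-type composition of rep-SVs inside a size window to
#' the overall rep-SV composition: one point per type, in-window proportion
#' regressed on overall proportion by unweighted OLS; types whose externally
#' studentized residual has Bonferroni-adjusted two-sided p < 0.05 are
#' flagged as over- or under-represented.
#'
#' @param annotations output of [annotate_cohort()].
#' @param window numeric `c(lo, hi)` in bp (inclusive).
#' @param mode `"proportion"` (default) or `"count"` for the regression
#'   axes.
#' @return data.frame per repeat type: `overall`, `subset`, `rstudent`,
#'   `bonferroni_p`, `flagged`; attribute `low_power` is `TRUE` (with a
#'   warning) when the window holds fewer than 10 SVs.
#' @export
peak_type_enrichment <- function(annotations, window,
                                 mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  a <- annotations[annotations$is_rep, , drop = FALSE]
  types <- sort(unique(a$rep_type))
  if (length(types) < 3) stop("need >= 3 repeat types")
  inw <- a$svlen >= window[1] & a$svlen <= window[2]
  n_in <- sum(inw)
  low_power <- n_in < 10
  if (low_power)
    warning("window holds only ", n_in, " SVs; enrichment is low-powered")
  tab_all <- table(factor(a$rep_type, levels = types))
  tab_in <- table(factor(a$rep_type[inw], levels = types))
  if (mode == "proportion") {
    x <- as.numeric(tab_all) / sum(tab_all)
    y <- if (n_in) as.numeric(tab_in) / sum(tab_in) else rep(0, length(types))
  } else {
    x <- as.numeric(tab_all)
    y <- as.numeric(tab_in)
  }
  out <- type_residual_screen(x, y, types)
  attr(out, "low_power") <- low_power
  out
}

#' Young versus remaining SVs: composition tests
#'
#' Two complementary tests of whether young SVs (singletons, i.e. state
#' `specific`) differ from the rest: (1) a 2x2 Pearson chi-square (no Yates
#' correction) of rep/nonrep status against young/other, falling back to
#' Fisher's exact test when any expected cell is below 1; (2) a per-type
#' regression residual screen of young rep-SV counts on remaining rep-SV
#' counts across repeat types, as in [peak_type_enrichment()].
#'
#' @param annotations output of [annotate_cohort()] with states assigned.
#' @return list: `table` (the 2x2 table), `chisq` (`statistic`, `p_value`,
#'   `method`), `per_type` (residual screen data.frame).
#' @export
compare_young_vs_rest <- function(annotations) {
  tab <- table(rep = factor(annotations$is_rep, c(TRUE, FALSE),
                            c("rep", "nonrep")),
               young = factor(annotations$is_young, c(TRUE, FALSE),
                              c("young", "other")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    ft <- stats::fisher.test(tab)
    message("expected cell < 1; using Fisher's exact test")
    chisq <- list(statistic = NA_real_, p_value = ft$p.value,
                  method = "fisher")
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    chisq <- list(statistic = unname(ct$statistic),
                  p_value = ct$p.value, method = "pearson")
  }
  a <- annotations[annotations$is_rep, , drop = FALSE]
  types <- sort(unique(a$rep_type))
  per_type <- if (length(types) >= 3) {
    young <- table(factor(a$rep_type[a$is_young], levels = types))
    rest <- table(factor(a$rep_type[!a$is_young], levels = types))
    type_residual_screen(as.numeric(rest), as.numeric(young), types)
  } else NULL
  list(table = tab, chisq = chisq, per_type = per_type)
}
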