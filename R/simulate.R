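## Synthetic cohorts with known ground truth.
##
## The simulator emulates the statistical structure the downstream analyses
## assume: two subspecies plus hybrids, per-SV sharing states, a repeat-type
## mixture, an SV size mixture with discrete peaks (~140/~280/~1150/~8400 bp),
## optional X-chromosome enrichment of large rep-SVs, and genotype
## missingness. The repeat track is generated jointly with the SVs: every
## truth rep-SV receives a co-placed repeat interval of its type inside its
## effective interval, decoy repeats are scattered away from all SVs, and
## nonrep-SVs are guaranteed repeat-free.

#' Cohort simulation configuration
#'
#' Defaults encode the structure observed in real two-subspecies cattle
#' cohorts: roughly three quarters of SVs touch a repeat; the repeat-type
#' mixture is led by bovine SINEs (Bov-A2, Bov-tA), LINE/L1, LINE/RTE-BovB
#' and LTR/ERVK; the length law is a broad log-normal background with four
#' discrete peaks near 140, 280, 1150 and 8400 bp whose windows
#' (125-158, 252-316, 1018-1263, 7686-9689 bp) are dominated by Bov-A2 and
#' LTR/ERVK respectively.
#'
#' @param n_taurine,n_indicine,n_hybrid individual counts (>= 2 per
#'   subspecies whenever the matching private-state weight is positive).
#' @param n_sv number of SVs to emit.
#' @param rep_fraction probability that an SV is repeat-mediated.
#' @param rep_types named weights of the repeat-type mixture (normalised).
#' @param state_proportions named probabilities of
#'   `(shared, private_taurine, private_indicine, specific)`; must sum to 1.
#' @param size_background list `(weight, meanlog, sdlog)` of the log-normal
#'   background length law (truncated to `[50, 99999]`).
#' @param size_peaks data.frame of peak components with columns `center`,
#'   `lo`, `hi`, `weight`, `rep_type`; peak lengths are drawn uniformly on
#'   `[lo, hi]`. Background and peak weights must sum to 1.
#' @param peak_dominance probability that a rep-SV drawn from a peak carries
#'   the peak's dominant repeat type (otherwise the global mixture is used).
#' @param svtype_weights named weights over INS/DEL/DUP/INV.
#' @param x_bias multiplier on the X chromosome's placement weight for
#'   rep-SVs longer than `x_bias_threshold` bp (1 = no bias).
#' @param x_bias_threshold size threshold for the X bias (default
#'   [LARGE_SV_THRESHOLD]).
#' @param missing_rate per-genotype missingness probability; masks are
#'   redrawn when they would alter the SV's recomputed state.
#' @param beta_shared,beta_private shape pairs of the Beta laws generating
#'   per-subspecies carrier frequencies conditional on the state.
#' @param decoy_repeats_per_mb density of decoy repeat intervals (placed
#'   away from every SV) per Mb of genome.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_taurine = 13, n_indicine = 13, n_hybrid = 4,
                          n_sv = 3000,
                          rep_fraction = 0.75,
                          rep_types = c("Bov-A2" = 0.28, "Bov-tA" = 0.12,
                                        "LINE/L1" = 0.20, "LINE/RTE-BovB" = 0.10,
                                        "LTR/ERVK" = 0.15, "Satellite" = 0.08,
                                        "Simple_repeat" = 0.07),
                          state_proportions = c(shared = 0.45,
                                                private_taurine = 0.15,
                                                private_indicine = 0.15,
                                                specific = 0.25),
                          size_background = list(weight = 0.48,
                                                 meanlog = log(300), sdlog = 1.3),
                          size_peaks = data.frame(
                            center = c(140, 280, 1150, 8400),
                            lo = c(125, 252, 1018, 7686),
                            hi = c(158, 316, 1263, 9689),
                            weight = c(0.20, 0.12, 0.10, 0.10),
                            rep_type = c("Bov-A2", "Bov-A2",
                                         "LTR/ERVK", "LTR/ERVK"),
                            stringsAsFactors = FALSE),
                          peak_dominance = 0.8,
                          svtype_weights = c(INS = 0.44, DEL = 0.44,
                                             DUP = 0.07, INV = 0.05),
                          x_bias = 1, x_bias_threshold = LARGE_SV_THRESHOLD,
                          missing_rate = 0.02,
                          beta_shared = c(2, 2), beta_private = c(1.5, 2.5),
                          decoy_repeats_per_mb = 10,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(rep_fraction, state_proportions, missing_rate, peak_dominance)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(state_proportions) - 1) > 1e-8)
    stop("state_proportions must sum to 1")
  if (abs(size_background$weight + sum(size_peaks$weight) - 1) > 1e-8)
    stop("size mixture weights must sum to 1")
  if (state_proportions["private_taurine"] > 0 && n_taurine < 2)
    stop("private_taurine weight > 0 requires n_taurine >= 2")
  if (state_proportions["private_indicine"] > 0 && n_indicine < 2)
    stop("private_indicine weight > 0 requires n_indicine >= 2")
  if (x_bias <= 0) stop("x_bias must be > 0")
  cfg$rep_types <- rep_types / sum(rep_types)
  cfg$svtype_weights <- svtype_weights / sum(svtype_weights)
  class(cfg) <- "cohort_config"
  cfg
}

## non-overlapping placement of n intervals of given spans on [0, L):
## distribute the free space as uniform gaps (order statistics of a uniform
## sample), guaranteeing >= 1 bp separation between consecutive intervals.
place_disjoint <- function(spans, L) {
  n <- length(spans)
  if (!n) return(numeric(0))
  free <- L - sum(spans) - n
  if (free <= 0) stop("chromosome too small for requested SV load")
  gaps <- diff(c(0, sort(stats::runif(n, 0, free))))
  starts <- cumsum(gaps + 1) - 1 + cumsum(c(0, spans[-n]))
  floor(starts)
}

## draw presence patterns consistent with a state, by vectorised rejection:
## rows violating the state's carrier pattern are redrawn; after max_iter the
## pattern is minimally repaired (documented fallback).
draw_presence <- function(state, n_sv, sub, cfg) {
  n_ind <- length(sub)
  t_idx <- which(sub == "taurine"); i_idx <- which(sub == "indicine")
  h_idx <- which(sub == "hybrid")
  P <- matrix(FALSE, n_sv, n_ind)
  if (!n_sv) return(P)
  if (state == "specific") {
    P[cbind(seq_len(n_sv), sample.int(n_ind, n_sv, replace = TRUE))] <- TRUE
    return(P)
  }
  draw_rows <- function(rows) {
    m <- length(rows)
    if (state == "shared") {
      qt <- stats::rbeta(m, cfg$beta_shared[1], cfg$beta_shared[2])
      qi <- stats::rbeta(m, cfg$beta_shared[1], cfg$beta_shared[2])
    } else if (state == "private_taurine") {
      qt <- stats::rbeta(m, cfg$beta_private[1], cfg$beta_private[2])
      qi <- rep(0, m)
    } else {
      qt <- rep(0, m)
      qi <- stats::rbeta(m, cfg$beta_private[1], cfg$beta_private[2])
    }
    qh <- (qt + qi) / 2
    P[rows, t_idx] <- stats::runif(m * length(t_idx)) < qt
    P[rows, i_idx] <- stats::runif(m * length(i_idx)) < qi
    P[rows, h_idx] <- stats::runif(m * length(h_idx)) < qh
    P
  }
  ok_rows <- function(P) {
    nt <- rowSums(P[, t_idx, drop = FALSE])
    ni <- rowSums(P[, i_idx, drop = FALSE])
    ntot <- rowSums(P)
    switch(state,
      shared = nt >= 1 & ni >= 1,
      private_taurine = nt >= 2 & ni == 0 & ntot >= 2,
      private_indicine = ni >= 2 & nt == 0 & ntot >= 2)
  }
  todo <- seq_len(n_sv)
  for (iter in 1:50) {
    P <- draw_rows(todo)
    todo <- which(!ok_rows(P))
    if (!length(todo)) break
  }
  if (length(todo)) {   # repair the stragglers deterministically
    for (r in todo) {
      if (state == "shared") {
        P[r, sample(t_idx, 1)] <- TRUE
        P[r, sample(i_idx, 1)] <- TRUE
      } else if (state == "private_taurine") {
        P[r, i_idx] <- FALSE
        P[r, sample(t_idx, 2)] <- TRUE
      } else {
        P[r, t_idx] <- FALSE
        P[r, sample(i_idx, 2)] <- TRUE
      }
    }
  }
  P
}

#' Simulate a two-subspecies SV cohort with known truth
#'
#' @param config a [cohort_config()].
#' @param genome a [genome_model()] (default [default_genome()]).
#' @return A list of class `sv_cohort`:
#'   \describe{
#'     \item{callset}{multi-sample [sv_callset()] of all SVs.}
#'     \item{individual_callsets}{list of per-individual call sets holding
#'       only the SVs that individual carries.}
#'     \item{repeats}{the jointly generated [repeat_track()].}
#'     \item{genes}{a scattered [gene_track()].}
#'     \item{metadata}{data.frame `individual`, `subspecies`, `breed`, `sex`.}
#'     \item{truth}{per-SV truth: `id`, `state`, `rep_type` (NA for
#'       nonrep-SVs), `is_rep`, `on_x`, `size_class`, `size_component`.}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config(), genome = default_genome()) {
  cfg <- config
  set.seed(cfg$seed)
  n_ind <- cfg$n_taurine + cfg$n_indicine + cfg$n_hybrid
  if (n_ind < 2) stop("need at least 2 individuals")
  sub <- c(rep("taurine", cfg$n_taurine), rep("indicine", cfg$n_indicine),
           rep("hybrid", cfg$n_hybrid))
  ids <- sprintf("ind_%02d", seq_len(n_ind))
  metadata <- data.frame(
    individual = ids, subspecies = sub,
    breed = paste0(substr(sub, 1, 3), "_breed_",
                   stats::ave(seq_len(n_ind), sub, FUN = seq_along) %% 3 + 1),
    sex = sample(c("F", "M"), n_ind, replace = TRUE),
    stringsAsFactors = FALSE
  )

  n <- cfg$n_sv
  ## --- truth draws -------------------------------------------------------
  state <- sample(names(cfg$state_proportions), n, replace = TRUE,
                  prob = cfg$state_proportions)
  is_rep <- stats::runif(n) < cfg$rep_fraction
  svtype <- sample(names(cfg$svtype_weights), n, replace = TRUE,
                   prob = cfg$svtype_weights)

  comp_w <- c(background = cfg$size_background$weight, cfg$size_peaks$weight)
  comp <- sample.int(length(comp_w), n, replace = TRUE, prob = comp_w)
  svlen <- numeric(n)
  bg <- comp == 1
  svlen[bg] <- pmin(pmax(round(stats::rlnorm(sum(bg), cfg$size_background$meanlog,
                                             cfg$size_background$sdlog)), 50), 99999)
  for (p in seq_len(nrow(cfg$size_peaks))) {
    sel <- comp == p + 1
    svlen[sel] <- round(stats::runif(sum(sel), cfg$size_peaks$lo[p],
                                     cfg$size_peaks$hi[p]))
  }

  rep_type <- rep(NA_character_, n)
  rep_type[is_rep] <- sample(names(cfg$rep_types), sum(is_rep), replace = TRUE,
                             prob = cfg$rep_types)
  for (p in seq_len(nrow(cfg$size_peaks))) {
    sel <- is_rep & comp == p + 1 & stats::runif(n) < cfg$peak_dominance
    rep_type[sel] <- cfg$size_peaks$rep_type[p]
  }

  ## --- chromosome placement ---------------------------------------------
  w <- matrix(rep(genome$length, each = n), n, nrow(genome))
  biased <- is_rep & svlen > cfg$x_bias_threshold
  w[biased, genome$is_x] <- w[biased, genome$is_x] * cfg$x_bias
  w <- w / rowSums(w)
  cum <- t(apply(w, 1, cumsum))
  u <- stats::runif(n)
  chrom_idx <- rowSums(u > cum) + 1L
  chrom <- genome$chrom[chrom_idx]

  span <- svlen   # effective-interval width for every type
  start0 <- numeric(n)   # 0-based
  for (ci in seq_len(nrow(genome))) {
    sel <- which(chrom_idx == ci)
    if (!length(sel)) next
    ord <- sel[order(stats::runif(length(sel)))]
    starts <- place_disjoint(span[ord], genome$length[ci])
    start0[ord] <- starts
  }
  pos <- start0 + 1
  end <- ifelse(svtype == "INS", pos, pos + svlen - 1)

  ## --- joint repeat track ------------------------------------------------
  ## co-placed repeat inside each rep-SV's effective interval
  rep_len <- pmax(1, round(svlen * stats::runif(n, 0.3, 1)))
  off_max <- svlen - rep_len
  rep_start <- start0 + floor(stats::runif(n) * (off_max + 1))
  co <- data.frame(chrom = chrom[is_rep], start = rep_start[is_rep],
                   end = (rep_start + rep_len)[is_rep],
                   rep_type = rep_type[is_rep], stringsAsFactors = FALSE)
  ## decoy repeats away from every SV interval
  n_decoy <- round(sum(genome$length) / 1e6 * cfg$decoy_repeats_per_mb)
  decoy <- NULL
  if (n_decoy > 0) {
    sv_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1,
                                                            start0 + pmax(svlen, 1)))
    d_chrom_i <- sample.int(nrow(genome), n_decoy * 2, replace = TRUE,
                            prob = genome$length)
    d_len <- pmin(pmax(round(stats::rlnorm(n_decoy * 2, log(250), 1)), 30), 20000)
    d_start <- floor(stats::runif(n_decoy * 2) *
                       (genome$length[d_chrom_i] - d_len - 1))
    d_gr <- GenomicRanges::GRanges(genome$chrom[d_chrom_i],
                                   IRanges::IRanges(d_start + 1, d_start + d_len))
    free <- GenomicRanges::countOverlaps(d_gr, sv_gr) == 0
    keep <- which(free)[seq_len(min(n_decoy, sum(free)))]
    if (length(keep))
      decoy <- data.frame(chrom = genome$chrom[d_chrom_i[keep]],
                          start = d_start[keep],
                          end = d_start[keep] + d_len[keep],
                          rep_type = sample(names(cfg$rep_types), length(keep),
                                            replace = TRUE, prob = cfg$rep_types),
                          stringsAsFactors = FALSE)
  }
  rt <- rbind(co, decoy)
  rt <- rt[order(rt$chrom, rt$start), ]
  repeats <- repeat_track(rt$chrom, rt$start, rt$end, rt$rep_type)

  ## --- genotypes ----------------------------------------------------------
  pres <- matrix(FALSE, n, n_ind)
  for (st in unique(state)) {
    rows <- which(state == st)
    pres[rows, ] <- draw_presence(st, length(rows), sub, cfg)
  }
  gt <- matrix(0L, n, n_ind)
  gt[pres] <- 1L + (stats::runif(sum(pres)) < 0.3)

  if (cfg$missing_rate > 0) {
    recount <- function(P) {
      nt <- rowSums(P[, sub == "taurine", drop = FALSE])
      ni <- rowSums(P[, sub == "indicine", drop = FALSE])
      ntot <- rowSums(P)
      s <- rep("unassigned", nrow(P))
      s[nt >= 2 & ni == 0] <- "private_taurine"
      s[ni >= 2 & nt == 0] <- "private_indicine"
      s[nt >= 1 & ni >= 1] <- "shared"
      s[ntot == 1] <- "specific"
      s
    }
    for (try in 1:20) {
      mask <- matrix(stats::runif(n * n_ind) < cfg$missing_rate, n, n_ind)
      P2 <- pres & !mask
      ok <- recount(P2) == state & rowMeans(mask) <= 0.5
      if (try == 1) {
        final_mask <- mask & ok
      } else {
        final_mask[todo, ] <- mask[todo, ] & ok[todo]
      }
      todo <- which(!ok)
      if (!length(todo)) break
    }
    ## rows never satisfying the check keep full genotypes (no masking)
    gt[final_mask] <- NA_integer_
  }

  sv_ids <- sprintf("sv_%05d", seq_len(n))
  records <- data.frame(id = sv_ids, chrom = chrom, pos = pos, end = end,
                        svtype = svtype, svlen = svlen, stringsAsFactors = FALSE)
  callset <- sv_callset(records, gt, samples = ids, source = "simulated")

  size_class <- cut(svlen, c(50, 200, 500, Inf), right = FALSE,
                    labels = c("small", "medium", "large"))
  truth <- data.frame(
    id = sv_ids, state = state, rep_type = rep_type, is_rep = is_rep,
    on_x = chrom == genome$chrom[genome$is_x],
    size_class = as.character(size_class),
    size_component = c("background", sprintf("peak_%d", cfg$size_peaks$center))[comp],
    stringsAsFactors = FALSE
  )
  truth <- truth[match(callset$records$id, truth$id), ]
  rownames(truth) <- NULL

  indiv <- lapply(seq_len(n_ind), function(i) {
    carry <- !is.na(callset$gt[, i]) & callset$gt[, i] > 0
    sv_callset(callset$records[carry, , drop = FALSE],
               callset$gt[carry, i, drop = FALSE],
               samples = ids[i], source = ids[i])
  })
  names(indiv) <- ids

  ## --- gene track ---------------------------------------------------------
  genes <- local({
    per_chrom <- 8
    rows <- list()
    gi <- 0
    for (ci in seq_len(nrow(genome))) {
      gstart <- sort(sample.int(genome$length[ci] - 30000, per_chrom))
      for (s in gstart) {
        gi <- gi + 1
        glen <- sample(5000:25000, 1)
        gid <- sprintf("gene_%03d", gi)
        ne <- sample(2:4, 1)
        estart <- sort(sample(seq(s, s + glen - 400, by = 200), ne))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = genome$chrom[ci],
          start = c(s, estart), end = c(s + glen, estart + 300),
          kind = c("gene", rep("exon", ne)), gene_id = gid,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    gene_track(d$chrom, d$start, d$end, d$kind, d$gene_id, d$strand)
  })

  structure(list(callset = callset, individual_callsets = indiv,
                 repeats = repeats, genes = genes, metadata = metadata,
                 truth = truth, config = cfg, genome = genome),
            class = "sv_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF 4.2 per individual, the repeat track in both RepeatMasker
#' `.out` and 6-column BED form, the gene track as GFF3, and metadata/truth
#' as TSV.
#'
#' @param cohort an `sv_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$individual_callsets))
    write_sv_vcf(cohort$individual_callsets[[nm]],
                 file.path(dir, paste0(nm, ".vcf")), genome = cohort$genome)
  write_sv_vcf(cohort$callset, file.path(dir, "cohort.vcf"),
               genome = cohort$genome)
  write_repeat_annotation(cohort$repeats, file.path(dir, "repeats.bed"), "bed")
  write_repeat_annotation(cohort$repeats, file.path(dir, "repeats.out"), "rmout")
  write_gene_gff3(cohort$genes, file.path(dir, "genes.gff3"))
  utils::write.table(cohort$metadata, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate (x, y) data from one of the nine candidate models
#'
#' @param model_name one of the nine model names (see [model_specs()]).
#' @param params named or positional numeric parameters of the model.
#' @param n number of points (used with `x_range` when `x` is NULL).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param x optional explicit x values.
#' @param x_range range for equally spaced x (default `c(1, 10)`).
#' @return data.frame with columns `x`, `y`.
#' @export
simulate_regression_data <- function(model_name, params, n = 50,
                                     noise_sd = 0, seed = 1, x = NULL,
                                     x_range = c(1, 10)) {
  spec <- model_specs()[[model_name]]
  if (is.null(spec)) stop("unknown model: ", model_name)
  if (is.null(x)) x <- seq(x_range[1], x_range[2], length.out = n)
  if (spec$positive_x && any(x <= 0))
    stop(model_name, " requires x > 0; offending indices: ",
         paste(utils::head(which(x <= 0)), collapse = ", "))
  set.seed(seed)
  y <- spec$predict(unname(params), x) + stats::rnorm(length(x), 0, noise_sd)
  data.frame(x = x, y = y)
}

#' Simulate a composition matrix
#'
#' Multinomial repeat-type counts per individual, either uniform over types
#' or dominated by one type with a given expected share.
#'
#' @param n_individuals,n_types dimensions (`n_types >= 2`).
#' @param structure `"uniform"` or `list(type = <index or name>, share = s)`
#'   with `s` strictly inside (0, 1).
#' @param total expected total count per individual.
#' @param seed integer seed.
#' @return integer matrix individuals x types.
#' @export
simulate_composition <- function(n_individuals, n_types,
                                 structure = "uniform", total = 1000,
                                 seed = 1) {
  if (n_types < 2) stop("n_types must be >= 2")
  types <- sprintf("type_%02d", seq_len(n_types))
  probs <- rep(1 / n_types, n_types)
  if (is.list(structure)) {
    s <- structure$share
    if (is.null(s) || s <= 0 || s >= 1)
      stop("dominated share must lie strictly in (0, 1)")
    t_idx <- if (is.character(structure$type)) match(structure$type, types)
             else as.integer(structure$type)
    probs <- rep((1 - s) / (n_types - 1), n_types)
    probs[t_idx] <- s
  } else if (!identical(structure, "uniform")) {
    stop("structure must be 'uniform' or list(type=, share=)")
  }
  set.seed(seed)
  m <- t(stats::rmultinom(n_individuals, total, probs))
  dimnames(m) <- list(sprintf("ind_%02d", seq_len(n_individuals)), types)
  m
}
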