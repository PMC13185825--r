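## rep-SV classification and evolutionary-state stratification.
##
## An SV is a rep-SV when its effective interval overlaps at least one
## annotated repetitive element by >= 1 bp and its length is < 100 kbp.
## States are defined on genotype presence patterns: shared (>= 1 taurine and
## >= 1 indicine carrier), subspecies-private (>= 2 carriers in one
## subspecies, none in the other), specific/young (exactly one carrier).

REP_SV_MAX_LEN <- 100000

#' Effective genomic interval of an SV
#'
#' Returns 0-based half-open intervals. DEL/DUP/INV span `[pos-1, end)`;
#' for INS the effective end is the start plus the insertion length, i.e.
#' `[pos-1, pos-1+svlen)`.
#'
#' @param records data.frame with `pos`, `end`, `svtype`, `svlen` (e.g.
#'   `callset$records`).
#' @return data.frame with columns `start`, `end` (0-based half-open). INS
#'   records with `svlen = 0` yield an empty interval and are flagged in the
#'   logical attribute `degenerate`.
#' @export
effective_interval <- function(records) {
  if (any(records$svtype == "INS" & is.na(records$svlen)))
    stop("INS record(s) with missing svlen")
  ins <- records$svtype == "INS"
  start <- records$pos - 1
  end <- ifelse(ins, records$pos - 1 + records$svlen, records$end)
  out <- data.frame(start = start, end = end)
  attr(out, "degenerate") <- ins & records$svlen == 0
  out
}

#' Classify SVs by repeat overlap
#'
#' For each SV, overlaps with the repeat track are summed per repeat type on
#' the SV's effective interval. An SV is a rep-SV when the total overlap is at
#' least 1 bp and its length is below 100 kbp. The dominant repeat type is
#' the one with the largest summed overlap; exact ties go to the
#' lexicographically smaller label.
#'
#' @param callset an [sv_callset()] (or a records data.frame).
#' @param repeats a [repeat_track()].
#' @return data.frame aligned with the records: `id`, `is_rep`, `rep_type`
#'   (NA for nonrep-SVs), `overlap_bp` (bp overlapped by the dominant type),
#'   and a list-column `all_overlaps` of named per-type bp vectors.
#' @export
classify_rep_sv <- function(callset, repeats) {
  records <- if (inherits(callset, "sv_callset")) callset$records else callset
  eff <- effective_interval(records)
  n <- nrow(records)
  width <- eff$end - eff$start
  svgr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(start = eff$start + 1,
                                                  width = pmax(width, 0)))
  rpgr <- track_granges(repeats)
  hits <- GenomicRanges::findOverlaps(svgr, rpgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(svgr[qh], rpgr[sh]))
  typ <- repeats$rep_type[sh]

  all_overlaps <- vector("list", n)
  rep_type <- rep(NA_character_, n)
  overlap_bp <- rep(0, n)
  if (length(qh)) {
    bp <- rowsum(ov, group = paste(qh, typ, sep = "\r"))
    key <- strsplit(rownames(bp), "\r", fixed = TRUE)
    svi <- as.integer(vapply(key, `[[`, character(1), 1))
    tlab <- vapply(key, `[[`, character(1), 2)
    for (grp in split(seq_along(svi), svi)) {
      i <- svi[grp[1]]
      v <- stats::setNames(bp[grp, 1], tlab[grp])
      v <- v[order(names(v))]
      all_overlaps[[i]] <- v
      best <- which(v == max(v))[1]   # names sorted => lexicographic tie-break
      rep_type[i] <- names(v)[best]
      overlap_bp[i] <- v[best]
    }
  }
  total <- vapply(all_overlaps, function(v) if (is.null(v)) 0 else sum(v), numeric(1))
  is_rep <- total >= 1 & records$svlen < REP_SV_MAX_LEN
  rep_type[!is_rep] <- NA_character_
  overlap_bp[!is_rep] <- 0
  out <- data.frame(id = records$id, is_rep = is_rep, rep_type = rep_type,
                    overlap_bp = overlap_bp, stringsAsFactors = FALSE)
  out$all_overlaps <- all_overlaps
  out
}

#' Assign evolutionary states from genotype presence patterns
#'
#' Carriers are individuals with a present genotype (allele count > 0;
#' missing genotypes are not carriers). With `n_t` taurine and `n_i` indicine
#' carriers and `n_tot` carriers overall (hybrids included):
#' exactly one carrier overall gives `specific`; otherwise `n_t >= 1` and
#' `n_i >= 1` gives `shared`; `n_t >= 2` with `n_i = 0` gives
#' `private_taurine` (and vice versa); anything else is `unassigned`.
#' Hybrid individuals never decide shared/private status — they only count
#' toward the overall carrier total.
#'
#' @param callset an [sv_callset()] with genotypes.
#' @param metadata data.frame with columns `individual` and `subspecies`
#'   (values `taurine`, `indicine`, `hybrid`) covering all samples.
#' @return character vector of states, one per record.
#' @export
assign_state <- function(callset, metadata) {
  sub <- metadata$subspecies[match(callset$samples, metadata$individual)]
  if (anyNA(sub)) stop("metadata does not cover all samples")
  pres <- presence_matrix(callset)
  pres[is.na(pres)] <- FALSE
  n_t <- rowSums(pres[, sub == "taurine", drop = FALSE])
  n_i <- rowSums(pres[, sub == "indicine", drop = FALSE])
  n_tot <- rowSums(pres)
  if (any(n_tot == 0))
    stop("SV(s) with zero carriers (should have been filtered): ",
         paste(utils::head(callset$records$id[n_tot == 0]), collapse = ", "))
  state <- rep("unassigned", length(n_tot))
  state[n_t >= 2 & n_i == 0] <- "private_taurine"
  state[n_i >= 2 & n_t == 0] <- "private_indicine"
  state[n_t >= 1 & n_i >= 1] <- "shared"
  state[n_tot == 1] <- "specific"
  state
}

#' Annotate genomic context of SVs
#'
#' Priority order: an SV overlapping any exon is `exon`; otherwise overlap
#' with any gene body gives `intron`; otherwise `intergenic`.
#'
#' @param callset an [sv_callset()] (or records data.frame).
#' @param genes a [gene_track()].
#' @return character vector of contexts.
#' @export
annotate_context <- function(callset, genes) {
  records <- if (inherits(callset, "sv_callset")) callset$records else callset
  eff <- effective_interval(records)
  svgr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(start = eff$start + 1,
                                                  width = pmax(eff$end - eff$start, 0)))
  mk <- function(kind) {
    g <- genes[genes$kind == kind, ]
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1, g$end))
  }
  ctx <- rep("intergenic", nrow(records))
  in_gene <- GenomicRanges::countOverlaps(svgr, mk("gene")) > 0
  in_exon <- GenomicRanges::countOverlaps(svgr, mk("exon")) > 0
  ctx[in_gene] <- "intron"
  ctx[in_exon] <- "exon"
  ctx
}

#' Annotate a cohort call set
#'
#' Convenience wrapper combining [classify_rep_sv()], [assign_state()] and
#' [annotate_context()] into one annotation table, the input of all
#' downstream analyses.
#'
#' @param callset a genotyped [sv_callset()].
#' @param repeats a [repeat_track()].
#' @param metadata sample metadata (see [assign_state()]).
#' @param genes optional [gene_track()]; without it `context` is NA.
#' @return data.frame with one row per SV: coordinates, type, length,
#'   `is_rep`, `rep_type`, `overlap_bp`, `all_overlaps`, `state`, `is_young`
#'   (specific SVs, i.e. singletons, are the young SVs), `context`.
#' @export
annotate_cohort <- function(callset, repeats, metadata, genes = NULL) {
  cls <- classify_rep_sv(callset, repeats)
  state <- assign_state(callset, metadata)
  ann <- cbind(callset$records[c("id", "chrom", "pos", "end", "svtype", "svlen")],
               cls[c("is_rep", "rep_type", "overlap_bp")])
  ann$all_overlaps <- cls$all_overlaps
  ann$state <- state
  ann$is_young <- state == "specific"
  ann$context <- if (is.null(genes)) NA_character_ else annotate_context(callset, genes)
  ann
}

#' Individuals-by-repeat-type composition matrix
#'
#' Cell (i, t) counts the rep-SVs of dominant repeat type t (optionally
#' restricted to one evolutionary state) carried by individual i. With
#' `count_mode = "all-overlaps"` an SV contributes once to every repeat type
#' it overlaps rather than only to its dominant type.
#'
#' @param annotations output of [annotate_cohort()].
#' @param callset the matching [sv_callset()] (genotype source).
#' @param metadata sample metadata; rows of the result follow
#'   `metadata$individual` order.
#' @param state_filter one of `"all"`, `"shared"`, `"private"`, `"specific"`
#'   (`"private"` covers both subspecies-private states; the exact state
#'   labels `"private_taurine"`/`"private_indicine"` are also accepted).
#' @param count_mode `"dominant"` (default) or `"all-overlaps"`.
#' @return integer matrix individuals x repeat types (columns sorted). An
#'   empty selection yields a 0-column matrix with a warning.
#' @export
composition_matrix <- function(annotations, callset, metadata,
                               state_filter = "all",
                               count_mode = c("dominant", "all-overlaps")) {
  count_mode <- match.arg(count_mode)
  keep <- annotations$is_rep
  keep <- keep & switch(state_filter,
    all = TRUE,
    private = annotations$state %in% c("private_taurine", "private_indicine"),
    annotations$state == state_filter)
  inds <- metadata$individual
  if (!any(keep)) {
    warning("empty selection: no rep-SVs match state_filter '", state_filter, "'")
    return(matrix(0L, length(inds), 0, dimnames = list(inds, NULL)))
  }
  ann <- annotations[keep, , drop = FALSE]
  pres <- presence_matrix(callset)[match(ann$id, callset$records$id),
                                   match(inds, callset$samples), drop = FALSE]
  pres[is.na(pres)] <- FALSE
  if (count_mode == "dominant") {
    types <- sort(unique(ann$rep_type))
    m <- vapply(types, function(t)
      colSums(pres[ann$rep_type == t, , drop = FALSE]), numeric(length(inds)))
  } else {
    types <- sort(unique(unlist(lapply(ann$all_overlaps, names))))
    m <- vapply(types, function(t) {
      has <- vapply(ann$all_overlaps, function(v) !is.null(v) && t %in% names(v),
                    logical(1))
      colSums(pres[has, , drop = FALSE])
    }, numeric(length(inds)))
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = length(inds),
                                   dimnames = list(inds, types))
  storage.mode(m) <- "integer"
  rownames(m) <- inds
  m
}

#' Size-class proportions of SVs
#'
#' Classes are half-open: small `[50, 200)`, medium `[200, 500)`, large
#' `[500, Inf)` bp.
#'
#' @param annotations annotation table (or any data.frame with `svlen`).
#' @return named numeric vector of proportions summing to 1.
#' @export
summarize_size_classes <- function(annotations) {
  len <- annotations$svlen
  if (any(len < 50))
    stop("svlen < 50 present; upstream length filter violated")
  cls <- cut(len, c(50, 200, 500, Inf), right = FALSE,
             labels = c("small", "medium", "large"))
  prop.table(table(cls))
}
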