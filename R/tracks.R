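## Repeat and gene annotation tracks. Internal coordinates are 0-based
## half-open everywhere; BED is native, RepeatMasker .out and GFF3 (1-based
## inclusive) are converted at the boundary.

#' Construct a repeat track
#'
#' @param chrom,start,end vectors describing repeat intervals, 0-based
#'   half-open.
#' @param rep_type hierarchical repeat label, either `"class/family"`
#'   (e.g. `"LINE/L1"`, `"LTR/ERVK"`) or a single token (`"Bov-A2"`,
#'   `"Satellite"`).
#' @return An object of class `repeat_track` (a data.frame).
#' @export
repeat_track <- function(chrom, start, end, rep_type) {
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("inverted or empty repeat interval at row %d", bad))
  }
  if (any(start < 0)) stop("negative repeat coordinates")
  if (any(!nzchar(rep_type))) stop("rep_type must be non-empty")
  tr <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), rep_type = as.character(rep_type),
                   stringsAsFactors = FALSE)
  class(tr) <- c("repeat_track", "data.frame")
  tr
}

track_granges <- function(tr) {
  GenomicRanges::GRanges(tr$chrom,
                         IRanges::IRanges(start = tr$start + 1, end = tr$end))
}

#' Read a repeat annotation
#'
#' Two dialects are supported: 4+ column BED (`chrom start end name`, 0-based
#' half-open, `name` taken as the repeat type) and RepeatMasker `.out`
#' (whitespace table with a 3-line header; `begin`/`end` are 1-based inclusive
#' and the class/family column supplies the repeat type).
#'
#' @param path annotation file.
#' @param dialect `"bed"` or `"rmout"`.
#' @return A [repeat_track()] with 0-based half-open coordinates.
#' @export
read_repeat_annotation <- function(path, dialect = c("bed", "rmout")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("BED repeat annotation needs >= 4 columns")
    bad <- which(d[[2]] >= d[[3]] | d[[2]] < 0)
    if (length(bad))
      stop(sprintf("invalid interval in %s at line %d", path, bad[1]))
    repeat_track(d[[1]], d[[2]], d[[3]], d[[4]])
  } else {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3, length(lines)))]   # banner + blank
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 11)) stop("malformed RepeatMasker .out line: ",
                           which(nf < 11)[1] + 3)
    getf <- function(i) vapply(fields, `[[`, character(1), i)
    begin <- as.numeric(getf(6)); endc <- as.numeric(getf(7))
    bad <- which(begin > endc | begin < 1)
    if (length(bad))
      stop(sprintf("invalid interval in %s at line %d", path, bad[1] + 3))
    repeat_track(getf(5), begin - 1, endc, getf(11))
  }
}

#' Write a repeat track
#'
#' @param tr a [repeat_track()].
#' @param path output file.
#' @param dialect `"bed"` (6-column: name = repeat type, score 0, strand `+`)
#'   or `"rmout"` (RepeatMasker-style layout with a 3-line header).
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(tr, path, dialect = c("bed", "rmout")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    d <- data.frame(tr$chrom, as.integer(tr$start), as.integer(tr$end),
                    tr$rep_type, 0L, "+")
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    hdr <- c(
      "   SW   perc perc perc  query     position in query              matching repeat",
      "score   div. del. ins.  sequence  begin end       (left)  repeat  class/family",
      ""
    )
    body <- sprintf("%5d %6.1f %4.1f %4.1f  %s %9d %9d (%d) + %s %s %d %d (%d) %d",
                    1000L, 1.0, 0.0, 0.0, tr$chrom,
                    as.integer(tr$start) + 1L, as.integer(tr$end), 0L,
                    "rep", tr$rep_type, 1L,
                    as.integer(tr$end - tr$start), 0L, seq_len(nrow(tr)))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Construct a gene track
#'
#' @param chrom,start,end 0-based half-open intervals.
#' @param kind `"gene"` or `"exon"`.
#' @param gene_id gene identifier; exons carry their parent gene's id.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_track` (a data.frame). Exon intervals
#'   must fall within their gene's interval.
#' @export
gene_track <- function(chrom, start, end, kind, gene_id, strand = "+") {
  tr <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), kind = as.character(kind),
                   gene_id = as.character(gene_id),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(!tr$kind %in% c("gene", "exon"))) stop("kind must be gene or exon")
  if (any(tr$start >= tr$end)) stop("empty or inverted gene intervals")
  g <- tr[tr$kind == "gene", ]
  e <- tr[tr$kind == "exon", ]
  if (nrow(e)) {
    m <- match(e$gene_id, g$gene_id)
    if (anyNA(m)) stop("exon without parent gene: ", e$gene_id[which(is.na(m))[1]])
    if (any(e$start < g$start[m] | e$end > g$end[m]))
      stop("exon interval outside its gene")
  }
  class(tr) <- c("gene_track", "data.frame")
  tr
}

#' Read a gene track from GFF3
#'
#' Only `gene` and `exon` features are retained; exon parents are resolved
#' through their `Parent`/`ID` attributes (transcript-less GFF3 with exons
#' pointing directly at genes, as written by [write_gene_gff3()]).
#'
#' @param path GFF3 file.
#' @return A [gene_track()].
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "exon")]
  kind <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  gene_id <- ifelse(kind == "gene", id, parent)
  gene_track(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
             kind, gene_id, as.character(GenomicRanges::strand(gr)))
}

#' Write a gene track as GFF3
#'
#' @param tr a [gene_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(tr, path) {
  gr <- GenomicRanges::GRanges(
    tr$chrom, IRanges::IRanges(tr$start + 1, tr$end),
    strand = tr$strand, type = tr$kind,
    source = "repsv"
  )
  is_gene <- tr$kind == "gene"
  gr$ID <- ifelse(is_gene, tr$gene_id,
                  sprintf("%s.exon%d", tr$gene_id, seq_len(nrow(tr))))
  parent <- ifelse(is_gene, NA_character_, tr$gene_id)
  gr$Parent <- IRanges::CharacterList(lapply(parent, function(p)
    if (is.na(p)) character() else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
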