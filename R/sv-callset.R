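## SV call sets: a records table plus an alternate-allele-count genotype
## matrix. Internal coordinates keep the VCF convention in `pos`/`end`
## (1-based, inclusive); interval arithmetic converts at the point of use via
## effective_interval().

SV_TYPES <- c("INS", "DEL", "DUP", "INV")

#' Construct an SV call set
#'
#' @param records data.frame with columns `id`, `chrom`, `pos`, `end`,
#'   `svtype`, `svlen`. `pos`/`end` are 1-based inclusive (VCF convention);
#'   for INS the stored `end` equals `pos` and the effective interval is
#'   computed downstream. `svlen` is the absolute SV length in bp.
#' @param gt integer matrix (records x individuals) of alternate-allele
#'   counts: 0 = absent, 1/2 = present, `NA` = missing. May have zero columns
#'   for an ungenotyped set.
#' @param samples character vector of individual labels (matrix columns).
#' @param source provenance tag for the call set (e.g. the caller name).
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(records, gt = NULL, samples = character(), source = "unknown") {
  need <- c("id", "chrom", "pos", "end", "svtype", "svlen")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- records[need]
  records$id <- as.character(records$id)
  records$chrom <- as.character(records$chrom)
  records$svtype <- as.character(records$svtype)
  records$pos <- as.numeric(records$pos)
  records$end <- as.numeric(records$end)
  records$svlen <- as.numeric(records$svlen)
  if (any(!records$svtype %in% SV_TYPES))
    stop("unknown svtype values: ",
         paste(unique(setdiff(records$svtype, SV_TYPES)), collapse = ", "))
  if (any(records$svlen < 0)) stop("svlen must be >= 0")
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  o <- order(records$chrom, records$pos, records$end, records$id)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(gt)) {
    gt <- matrix(NA_integer_, nrow(records), length(samples))
  } else {
    gt <- as.matrix(gt)[o, , drop = FALSE]
    storage.mode(gt) <- "integer"
  }
  if (ncol(gt) != length(samples))
    stop("gt columns must match samples")
  dimnames(gt) <- list(records$id, samples)
  structure(
    list(records = records, gt = gt, samples = samples, source = source),
    class = "sv_callset"
  )
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> %d SVs, %d individuals, source '%s'\n",
              nrow(x$records), length(x$samples), x$source))
  print(utils::head(x$records, 5))
  invisible(x)
}

#' Number of records in a call set
#' @param x an `sv_callset`.
#' @export
n_svs <- function(x) nrow(x$records)

## Subset rows of a callset by logical/integer index, keeping gt in step.
subset_callset <- function(x, keep) {
  sv_callset(x$records[keep, , drop = FALSE],
             x$gt[keep, , drop = FALSE],
             samples = x$samples, source = x$source)
}

## Presence matrix: TRUE present, FALSE absent, NA missing.
presence_matrix <- function(x) x$gt > 0L

## ---- VCF ----

gt_to_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g >= 2L] <- "1/1"
  out
}

gt_from_string <- function(s) {
  ## any allele >= 1 => present; "." anywhere => missing
  out <- rep(NA_integer_, length(s))
  miss <- is.na(s) | grepl("\\.", s)
  alleles <- strsplit(s[!miss], "[/|]")
  out[!miss] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
  out
}

#' Write an SV call set as VCF 4.2
#'
#' Symbolic alternate alleles (`<DEL>` etc.) are used; `SVLEN` is written
#' signed (negative for DEL, following common caller output) and `END` is
#' written for every record (for INS it equals `POS`).
#'
#' @param x an `sv_callset`.
#' @param path output file.
#' @param genome optional [genome_model()] used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path, genome = NULL) {
  r <- x$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=repsv",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(x$samples)) c("FORMAT", x$samples)),
          collapse = "\t")
  )
  svlen_signed <- ifelse(r$svtype == "DEL", -r$svlen, r$svlen)
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d",
                  r$svtype, as.integer(svlen_signed), as.integer(r$end))
  body <- cbind(r$chrom, as.integer(r$pos), r$id, "N",
                sprintf("<%s>", r$svtype), ".", "PASS", info)
  if (length(x$samples)) {
    gts <- apply(x$gt, 2, gt_to_string)
    if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1)
    body <- cbind(body, "GT", gts)
  }
  lines <- c(hdr, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an SV call set from a VCF
#'
#' Parses `SVTYPE`, `SVLEN`, `END` from INFO and `GT` from the sample columns.
#' `svlen` is stored as an absolute value. Records whose `SVTYPE` is not one
#' of INS/DEL/DUP/INV (e.g. BND) are skipped and counted, as are records
#' lacking both `SVLEN` and `END`; the skip counts are attached as attributes
#' `n_skipped_type` / `n_skipped_len` and reported in a warning.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param source provenance tag to attach (defaults to the file name).
#' @return An [sv_callset()].
#' @export
read_sv_vcf <- function(path, source = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  id <- vcfR::getID(v)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  endv <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))

  bad_type <- is.na(svtype) | !svtype %in% SV_TYPES
  bad_len <- is.na(svlen) & is.na(endv)
  keep <- !bad_type & !bad_len
  n_skipped_type <- sum(bad_type)
  n_skipped_len <- sum(bad_len & !bad_type)
  if (n_skipped_type + n_skipped_len > 0)
    warning(sprintf("%s: skipped %d record(s) with unsupported SVTYPE and %d lacking both SVLEN and END",
                    basename(path), n_skipped_type, n_skipped_len))

  chrom <- chrom[keep]; pos <- pos[keep]; id <- id[keep]
  svtype <- svtype[keep]; svlen <- svlen[keep]; endv <- endv[keep]
  len <- ifelse(is.na(svlen), endv - pos + 1, abs(svlen))
  end <- ifelse(svtype == "INS", pos, ifelse(is.na(endv), pos + len - 1, endv))
  id[is.na(id) | id == "."] <- sprintf("sv_%06d", which(keep)[is.na(id) | id == "."])

  samples <- colnames(v@gt)[-1]
  if (length(samples)) {
    gts <- vcfR::extract.gt(v, "GT")
    gts <- gts[keep, , drop = FALSE]
    gt <- apply(gts, 2, gt_from_string)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep))
  } else {
    gt <- matrix(NA_integer_, sum(keep), 0)
    samples <- character()
  }
  cs <- sv_callset(
    data.frame(id = id, chrom = chrom, pos = pos, end = end,
               svtype = svtype, svlen = round(len), stringsAsFactors = FALSE),
    gt, samples = samples, source = source
  )
  attr(cs, "n_skipped_type") <- n_skipped_type
  attr(cs, "n_skipped_len") <- n_skipped_len
  cs
}
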