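#' Define a genome model
#'
#' A genome model is the ordered set of chromosomes the cohort lives on, with
#' one chromosome designated as the X. Chromosomes named `"Y"` or `"chrY"` are
#' rejected: the analyses in this package exclude the Y chromosome throughout.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp; names
#'   are chromosome identifiers.
#' @param x_name name of the X chromosome; must appear in `chromosomes`.
#' @return An object of class `genome_model`: a data.frame with columns
#'   `chrom`, `length`, `is_x`.
#' @examples
#' genome_model(c(chr1 = 2e6, chr2 = 2e6, chrX = 1.5e6), x_name = "chrX")
#' @export
genome_model <- function(chromosomes, x_name) {
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("`chromosomes` must be a named vector of lengths")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(names(chromosomes)))
    stop("duplicated chromosome names")
  if (any(names(chromosomes) %in% c("Y", "chrY")))
    stop("the Y chromosome is excluded from all analyses; remove it")
  if (!x_name %in% names(chromosomes))
    stop("`x_name` not among chromosome names")
  if (sum(names(chromosomes) == x_name) != 1)
    stop("exactly one X chromosome required")
  if (length(chromosomes) - 1L < 2L)
    stop("at least two autosomes required")
  g <- data.frame(
    chrom  = names(chromosomes),
    length = as.numeric(chromosomes),
    is_x   = names(chromosomes) == x_name,
    stringsAsFactors = FALSE
  )
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Default desk-scale genome
#'
#' 29 autosomes of 1 Mb plus an X of 1.5 Mb, mimicking the karyotype structure
#' of the bovine reference (29 autosomes + X) at a size where simulated
#' cohorts run in seconds.
#'
#' @return A [genome_model()].
#' @export
default_genome <- function() {
  lens <- c(stats::setNames(rep(1e6, 29), paste0("chr", 1:29)), chrX = 1.5e6)
  genome_model(lens, x_name = "chrX")
}
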