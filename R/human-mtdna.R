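## The paper-scale worked example: the human mitochondrial genome
## (NC_001807), distributed as a plain FASTA with the seqinr package, and
## its cox1 CDS (positions 5905-7446 of that accession's annotation).

#' Human mitochondrial genome (NC_001807)
#'
#' Loads the complete human mtDNA sequence shipped with the seqinr package
#' (accession NC_001807.4, 16709 bp). Requires seqinr to be installed; no
#' download is performed.
#'
#' @return the genome as a single uppercase character string.
#' @export
humanMitogenome <- function() {
  path <- system.file("sequences", "humanMito.fasta", package = "seqinr")
  if (!nzchar(path))
    stop("the seqinr package (which ships the NC_001807 FASTA) is not ",
         "installed")
  as.character(Biostrings::readDNAStringSet(path)[[1]])
}

#' Human cox1 CDS from NC_001807
#'
#' The cytochrome c oxidase subunit I coding sequence, positions 5905-7446
#' of NC_001807 (1542 nt, 514 codons including the terminal stop).
#'
#' @return list with \code{cds} (character string), \code{genomeStart}
#'   (5905) and \code{genomeEnd} (7446), for mapping results back to
#'   genome coordinates.
#' @export
humanCox1 <- function() {
  g <- humanMitogenome()
  list(cds = substr(g, 5905L, 7446L), genomeStart = 5905L,
       genomeEnd = 7446L)
}
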