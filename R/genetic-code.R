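#' @import methods
#' @importFrom stats sd setNames rnorm rpois runif t.test pt complete.cases
#' @importFrom utils combn read.delim head tail
NULL

.FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

## NCBI translation tables shipped as built-ins; ids follow the NCBI numbering.
.BUILTIN_CODES <- c(
  "1" = "standard",
  "2" = "vertebrate mitochondrial",
  "3" = "yeast mitochondrial",
  "4" = "mold/protozoan mitochondrial",
  "5" = "invertebrate mitochondrial"
)

#' Genetic code table
#'
#' A 64-codon translation table with its start-codon set. Stop codons are the
#' codons mapped to \code{"*"}. The \code{agrAsStop} flag records whether the
#' code reassigns the AGA/AGG (AGR) arginine codons to stops, as the
#' vertebrate mitochondrial code (NCBI table 2) does; this reassignment is
#' what punctuates vertebrate gau frames with extra stops.
#'
#' @slot codeId short identifier (NCBI table number for built-ins).
#' @slot table named character of length 64 mapping DNA codons to one-letter
#'   amino acids, with \code{"*"} for stops.
#' @slot starts character vector of initiation codons.
#' @export
setClass("GeneticCode",
  representation(codeId = "character", table = "character", starts = "character")
)

setValidity("GeneticCode", function(object) {
  msg <- character(0)
  if (length(object@table) != 64L)
    msg <- c(msg, "codon table must map exactly 64 codons")
  expected <- sort(as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0)))
  if (!identical(sort(names(object@table)), expected))
    msg <- c(msg, "codon table names must be the 64 DNA codons")
  if (!all(object@starts %in% names(object@table)))
    msg <- c(msg, "start codons must be codons of the table")
  if (length(msg)) msg else TRUE
})

#' Construct a genetic code
#'
#' Built-in tables are keyed to NCBI translation-table numbers: 1 (standard),
#' 2 (vertebrate mitochondrial), 3 (yeast mitochondrial), 4 (mold/protozoan
#' mitochondrial) and 5 (invertebrate mitochondrial). Tables and start codons
#' are taken from \code{Biostrings::GENETIC_CODE_TABLE}.
#'
#' @param codeId NCBI table number as character or integer (one of 1,2,3,4,5).
#' @return a \code{\linkS4class{GeneticCode}}.
#' @examples
#' vert <- geneticCode(2)
#' agrAsStop(vert)
#' @export
geneticCode <- function(codeId = "1") {
  codeId <- as.character(codeId)
  if (!codeId %in% names(.BUILTIN_CODES))
    stop("unknown built-in code id '", codeId, "'; available: ",
         paste(names(.BUILTIN_CODES), collapse = ", "))
  tbl <- Biostrings::getGeneticCode(codeId, full.search = FALSE)
  starts <- attr(tbl, "alt_init_codons")
  ## the canonical ATG initiator is implicit in Biostrings' attribute
  starts <- sort(unique(c("ATG", as.character(starts))))
  tab <- setNames(as.character(tbl), names(tbl))
  new("GeneticCode", codeId = codeId, table = tab, starts = starts)
}

#' Read a genetic code from a TSV file
#'
#' Expects columns \code{codon}, \code{aa} and \code{is_start} (0/1); all 64
#' codons must be present, stops encoded as \code{"*"} in \code{aa}.
#'
#' @param path path to the TSV file.
#' @param codeId identifier to record on the returned object.
#' @return a \code{\linkS4class{GeneticCode}}.
#' @export
readGeneticCodeTSV <- function(path, codeId = "custom") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "aa", "is_start")
  if (!all(need %in% names(df)))
    stop("code TSV needs columns: ", paste(need, collapse = ", "))
  tab <- setNames(toupper(df$aa), toupper(df$codon))
  new("GeneticCode", codeId = codeId, table = tab,
      starts = toupper(df$codon[df$is_start == 1]))
}

#' @describeIn geneticCode identifier of a code
#' @param code a \code{GeneticCode}.
#' @export
codeId <- function(code) code@codeId

#' @describeIn geneticCode the 64-codon lookup table
#' @export
codonTable <- function(code) code@table

#' @describeIn geneticCode initiation codons
#' @export
startCodons <- function(code) code@starts

#' @describeIn geneticCode codons translating to \code{"*"}
#' @export
stopCodons <- function(code) names(code@table)[code@table == "*"]

#' @describeIn geneticCode TRUE when AGA and AGG are stops (vertebrate mt)
#' @export
agrAsStop <- function(code) all(c("AGA", "AGG") %in% stopCodons(code))

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode '", object@codeId, "'",
      if (object@codeId %in% names(.BUILTIN_CODES))
        paste0(" (", .BUILTIN_CODES[object@codeId], ")"),
      "\n  stops:  ", paste(stopCodons(object), collapse = " "),
      "\n  starts: ", paste(object@starts, collapse = " "),
      "\n  AGR as stop: ", agrAsStop(object), "\n", sep = "")
})

## ---- sequence utilities ----------------------------------------------------

.normalizeSeq <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "RNAString"))
    seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string or DNA/RNAString")
  s <- chartr("u", "T", chartr("U", "T", toupper(seq)))
  if (!nzchar(s)) stop("empty sequence")
  s
}

#' Reverse complement
#'
#' @param seq nucleotide string (DNA or RNA; U is normalised to T).
#' @return reverse-complemented DNA string; ambiguity codes follow IUPAC.
#' @export
revComp <- function(seq) {
  s <- .normalizeSeq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.splitCodons <- function(s, offset = 0L) {
  n <- nchar(s)
  starts <- seq.int(1L + offset, by = 3L, length.out = (n - offset) %/% 3L)
  if (!length(starts)) return(character(0))
  substring(s, starts, starts + 2L)
}

.translateCodons <- function(codons, code) {
  aa <- unname(code@table[codons])
  aa[is.na(aa)] <- "X"   # codons with N or other ambiguity codes
  aa
}

## ---- frame-aware translation ----------------------------------------------

#' Single-frame translation
#'
#' Translation of one of the six reading frames. Minus frames translate the
#' reverse complement with offsets 0..2. Codons containing ambiguity codes
#' give \code{"X"}; stop codons are rendered \code{"*"} and translation runs
#' through them (no truncation).
#'
#' @slot frameLabel one of \code{"+1","+2","+3","-1","-2","-3"}.
#' @slot protein amino-acid string.
#' @slot ntOffset 0-based offset of the first translated base on the labelled
#'   strand.
#' @slot codeId id of the code used.
#' @export
setClass("FrameTranslation",
  representation(frameLabel = "character", protein = "character",
                 ntOffset = "integer", codeId = "character"))

setMethod("show", "FrameTranslation", function(object) {
  p <- object@protein
  cat("FrameTranslation frame ", object@frameLabel, " (code ", object@codeId,
      ", ", nchar(p), " aa)\n  ",
      if (nchar(p) > 60) paste0(substr(p, 1, 60), "...") else p, "\n", sep = "")
})

#' @describeIn translateFrame protein string of a FrameTranslation
#' @param x a \code{FrameTranslation}.
#' @export
frameProtein <- function(x) x@protein

#' @describeIn translateFrame frame label of a FrameTranslation
#' @export
frameLabel <- function(x) x@frameLabel

.checkFrame <- function(frame) {
  if (is.numeric(frame))
    frame <- sprintf("%+d", frame)
  frame <- as.character(frame)
  if (!frame %in% .FRAME_LABELS)
    stop("unknown frame label '", frame, "'")
  frame
}

#' Translate one reading frame
#'
#' @param seq nucleotide string (A,C,G,T,U,N; U normalised to T).
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param frame frame label \code{"+1".."-3"} (or integer \code{1..3},
#'   \code{-1..-3}).
#' @return a \code{\linkS4class{FrameTranslation}}.
#' @examples
#' translateFrame("ATGTTTTAA", geneticCode(1), "+1")  # "MF*"
#' @export
translateFrame <- function(seq, code, frame = "+1") {
  frame <- .checkFrame(frame)
  s <- .normalizeSeq(seq)
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  offset <- as.integer(substr(frame, 2, 2)) - 1L
  strand_seq <- if (substr(frame, 1, 1) == "-") revComp(s) else s
  aa <- .translateCodons(.splitCodons(strand_seq, offset), code)
  new("FrameTranslation", frameLabel = frame,
      protein = paste(aa, collapse = ""), ntOffset = offset,
      codeId = code@codeId)
}

#' Six-frame translation
#'
#' @inheritParams translateFrame
#' @return named list of six \code{FrameTranslation}s
#'   (\code{"+1","+2","+3","-1","-2","-3"}).
#' @export
sixFrameTranslate <- function(seq, code) {
  setNames(lapply(.FRAME_LABELS, function(f) translateFrame(seq, code, f)),
           .FRAME_LABELS)
}

## ---- the -2 frame codon geometry ------------------------------------------

#' Antisense (-2 frame) codon overlapping two sense codons
#'
#' The gau frame sits on the complementary strand so that third codon
#' positions of the sense gene and of gau pair with each other. The antisense
#' codon paired with sense codon \code{k} takes its first two bases from the
#' complement of positions 2 and 1 of sense codon \code{k + 1} and its third
#' base from the complement of position 3 of codon \code{k}.
#'
#' @param seq sense-strand nucleotide string (length a multiple of 3 at least
#'   two codons long).
#' @param k 1-based sense codon index; the adjacent codon \code{k + 1} must
#'   exist.
#' @return three-letter antisense codon string.
#' @examples
#' minus2Codon("TTCGGA", 1)  # "CCG"
#' @export
minus2Codon <- function(seq, k) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  nCodons <- n %/% 3L
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k >= nCodons)
    stop("codon index k out of range: need 1 <= k < ", nCodons,
         " (the adjacent sense codon is required)")
  bases <- substring(s, c(3L * k + 2L, 3L * k + 1L, 3L * k),
                        c(3L * k + 2L, 3L * k + 1L, 3L * k))
  comp <- .COMP[bases]
  comp[is.na(comp)] <- "N"
  paste(comp, collapse = "")
}

#' Stop positions within a window of a frame translation
#'
#' @param ft a \code{\linkS4class{FrameTranslation}}.
#' @param startCodon 1-based first codon of the window within the translation.
#' @param nCodons window length in codons.
#' @return integer vector of 1-based stop positions relative to the window
#'   start (empty when the window is stop-free).
#' @export
countStops <- function(ft, startCodon, nCodons) {
  stopifnot(is(ft, "FrameTranslation"))
  L <- nchar(ft@protein)
  startCodon <- as.integer(startCodon); nCodons <- as.integer(nCodons)
  if (startCodon < 1L || nCodons < 1L || startCodon + nCodons - 1L > L)
    stop("window [", startCodon, ", ", startCodon + nCodons - 1L,
         "] out of translation bounds (1..", L, ")")
  win <- substr(ft@protein, startCodon, startCodon + nCodons - 1L)
  which(strsplit(win, "")[[1]] == "*")
}
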