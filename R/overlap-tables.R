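## Pairwise six-frame conservation tables and per-column amino-acid family
## profiles for aligned Gau proteins.

#' Amino-acid similarity scheme
#'
#' A partition of amino acids into groups whose members count as
#' "functionally similar". Groups must be pairwise disjoint.
#'
#' Built-ins: \code{"table3"} holds the families observed to interchange in
#' Gau columns (F/L/I/M/V, K/N, Q/H); \code{"physicochemical"} (the default
#' elsewhere) is a broader disjoint partition by side-chain class.
#'
#' @slot name scheme name.
#' @slot groups list of character vectors of one-letter amino acids.
#' @export
setClass("SimilarityScheme",
  representation(name = "character", groups = "list"))

setValidity("SimilarityScheme", function(object) {
  msg <- character(0)
  all_aa <- unlist(object@groups)
  if (any(duplicated(all_aa)))
    msg <- c(msg, "similarity groups must be pairwise disjoint")
  if (!all(all_aa %in% names(.KD)))
    msg <- c(msg, "groups may only contain standard amino acids")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimilarityScheme", function(object) {
  cat("SimilarityScheme '", object@name, "': ",
      paste(vapply(object@groups, paste, "", collapse = ""),
            collapse = " | "), "\n", sep = "")
})

#' Construct or look up a similarity scheme
#'
#' @param name \code{"physicochemical"}, \code{"table3"}, or a custom name
#'   when \code{groups} is supplied.
#' @param groups optional list of disjoint character vectors.
#' @return a \code{\linkS4class{SimilarityScheme}}.
#' @export
similarityScheme <- function(name = "physicochemical", groups = NULL) {
  if (is.null(groups)) {
    groups <- switch(name,
      physicochemical = list(c("G", "A", "V", "L", "I", "M"),
                             c("F", "Y", "W"), c("S", "T"), c("N", "Q"),
                             c("D", "E"), c("K", "R", "H")),
      table3 = list(c("F", "L", "I", "M", "V"), c("K", "N"), c("Q", "H")),
      stop("unknown built-in scheme '", name, "'"))
  }
  new("SimilarityScheme", name = name, groups = lapply(groups, toupper))
}

.groupIndex <- function(scheme) {
  idx <- integer(0)
  for (i in seq_along(scheme@groups))
    idx[scheme@groups[[i]]] <- i
  idx
}

#' Are two residues identical or in the same similarity group?
#'
#' @param scheme a \code{\linkS4class{SimilarityScheme}}.
#' @param a,b one-letter amino acids (vectorised).
#' @return logical vector.
#' @export
residuesSimilar <- function(scheme, a, b) {
  idx <- .groupIndex(scheme)
  ga <- idx[a]; gb <- idx[b]
  (a == b) | (!is.na(ga) & !is.na(gb) & ga == gb)
}

#' Pairwise global nucleotide alignment
#'
#' Needleman-Wunsch global alignment with affine gaps: the cost of a
#' length-L gap is \code{gapOpen + L * gapExt}. Backed by
#' \code{Biostrings::pairwiseAlignment}.
#'
#' @slot idA,idB sequence identifiers.
#' @slot alignedA,alignedB equal-length aligned strings with \code{"-"} gaps.
#' @slot score optimal alignment score.
#' @slot params scoring parameters used.
#' @export
setClass("PairAlignment",
  representation(idA = "character", idB = "character",
                 alignedA = "character", alignedB = "character",
                 score = "numeric", params = "list"))

setValidity("PairAlignment", function(object) {
  msg <- character(0)
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned strings must have equal length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairAlignment", function(object) {
  cat("PairAlignment ", object@idA, " vs ", object@idB,
      " (score ", object@score, ", ", nchar(object@alignedA),
      " columns)\n", sep = "")
})

#' @describeIn globalAlignNt aligned string of the first sequence
#' @param aln a \code{PairAlignment}.
#' @export
alignedA <- function(aln) aln@alignedA

#' @describeIn globalAlignNt aligned string of the second sequence
#' @export
alignedB <- function(aln) aln@alignedB

#' Globally align two nucleotide sequences
#'
#' @param seqA,seqB nucleotide strings.
#' @param match,mismatch,gapOpen,gapExt scoring parameters (defaults
#'   +1/-1/5/2; gap penalties are positive costs).
#' @param idA,idB identifiers recorded on the alignment.
#' @return a \code{\linkS4class{PairAlignment}}.
#' @export
globalAlignNt <- function(seqA, seqB, match = 1, mismatch = -1,
                          gapOpen = 5, gapExt = 2,
                          idA = "seqA", idB = "seqB") {
  a <- .normalizeSeq(seqA); b <- .normalizeSeq(seqB)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExt)
  new("PairAlignment", idA = idA, idB = idB,
      alignedA = as.character(Biostrings::alignedPattern(pa)),
      alignedB = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa),
      params = list(match = match, mismatch = mismatch,
                    gapOpen = gapOpen, gapExt = gapExt))
}

#' Build a PairAlignment from pre-aligned sequences
#'
#' Accepts an externally computed alignment (e.g. the output of another
#' alignment tool) so downstream tables can be reproduced exactly.
#'
#' @param alignedA,alignedB equal-length aligned strings with \code{"-"}.
#' @param idA,idB identifiers.
#' @return a \code{\linkS4class{PairAlignment}} (score \code{NA}).
#' @export
pairAlignmentFromAligned <- function(alignedA, alignedB,
                                     idA = "seqA", idB = "seqB") {
  new("PairAlignment", idA = idA, idB = idB,
      alignedA = toupper(alignedA), alignedB = toupper(alignedB),
      score = NA_real_, params = list())
}

#' Partition an alignment into regions defined on the first sequence
#'
#' @param aln a \code{\linkS4class{PairAlignment}}.
#' @param breakpoints data.frame (or matrix) with columns \code{start},
#'   \code{end}: contiguous 1-based inclusive ranges on the ungapped first
#'   sequence, jointly covering it.
#' @return data.frame with columns \code{region}, \code{start}, \code{end}
#'   (on seqA) and \code{aln_start}, \code{aln_end} (alignment columns).
#'   Gap columns belong to the region of the preceding seqA position.
#' @export
partitionRegions <- function(aln, breakpoints) {
  bp <- as.data.frame(breakpoints)
  if (!all(c("start", "end") %in% names(bp)))
    stop("breakpoints need columns start, end")
  bp <- bp[order(bp$start), , drop = FALSE]
  lenA <- sum(strsplit(aln@alignedA, "")[[1]] != "-")
  if (bp$start[1] != 1L || bp$end[nrow(bp)] != lenA ||
      (nrow(bp) > 1 && any(bp$start[-1] != bp$end[-nrow(bp)] + 1L)))
    stop("breakpoints must be contiguous, non-overlapping and cover 1..",
         lenA, " on the first sequence")
  chA <- strsplit(aln@alignedA, "")[[1]]
  cumA <- cumsum(chA != "-")
  ## leading gap columns (cumA == 0) are assigned to the first region
  posA <- pmax(cumA, 1L)
  regOfPos <- rep(seq_len(nrow(bp)), bp$end - bp$start + 1L)
  regionPerCol <- regOfPos[posA]
  out <- data.frame(region = seq_len(nrow(bp)), start = bp$start,
                    end = bp$end, aln_start = NA_integer_,
                    aln_end = NA_integer_)
  for (r in seq_len(nrow(bp))) {
    cols <- which(regionPerCol == r)
    if (length(cols)) {
      out$aln_start[r] <- min(cols); out$aln_end[r] <- max(cols)
    }
  }
  out
}

## translate paired, gap-free region strings in one frame and tally
.frameCellStats <- function(sA, sB, frame, codeA, codeB, scheme) {
  offset <- as.integer(substr(frame, 2, 2)) - 1L
  if (startsWith(frame, "-")) {
    sA <- revComp(sA); sB <- revComp(sB)
  }
  aaA <- .translateCodons(.splitCodons(sA, offset), codeA)
  aaB <- .translateCodons(.splitCodons(sB, offset), codeB)
  n <- length(aaA)
  if (!n)
    return(c(pct_identical_aa = NA_real_,
             pct_identical_or_similar_aa = NA_real_,
             pct_stop_a = NA_real_, pct_stop_b = NA_real_))
  ident <- aaA == aaB
  sim <- ident | residuesSimilar(scheme, aaA, aaB)
  c(pct_identical_aa = 100 * mean(ident),
    pct_identical_or_similar_aa = 100 * mean(sim),
    pct_stop_a = 100 * mean(aaA == "*"),
    pct_stop_b = 100 * mean(aaB == "*"))
}

#' Six-frame conservation table over alignment regions
#'
#' For each region of the alignment and each of the six reading frames,
#' tallies amino-acid identity, identity-or-similarity under a scheme, and
#' per-sequence stop-codon fractions, each sequence translated under its own
#' genetic code. Columns with a gap in either sequence are removed before
#' codon extraction (gapped columns are counted as indel events); regions
#' should be codon-aligned on the first sequence (frame anchoring follows
#' the first sequence's coordinates).
#'
#' @param aln a \code{\linkS4class{PairAlignment}}.
#' @param codeA,codeB genetic codes for the two sequences.
#' @param scheme a \code{\linkS4class{SimilarityScheme}}.
#' @param breakpoints region ranges on the first sequence (see
#'   \code{\link{partitionRegions}}); default a single region covering all.
#' @return data.frame, one row per region x frame, with columns
#'   \code{region}, \code{frame}, \code{region_start}, \code{region_end},
#'   \code{pct_identical_nt}, \code{pct_identical_aa},
#'   \code{pct_identical_or_similar_aa}, \code{gap_indel_count},
#'   \code{pct_stop_a}, \code{pct_stop_b}.
#' @export
frameComparisonTable <- function(aln, codeA, codeB,
                                 scheme = similarityScheme(),
                                 breakpoints = NULL) {
  chA <- strsplit(aln@alignedA, "")[[1]]
  chB <- strsplit(aln@alignedB, "")[[1]]
  lenA <- sum(chA != "-")
  if (is.null(breakpoints))
    breakpoints <- data.frame(start = 1L, end = lenA)
  parts <- partitionRegions(aln, breakpoints)
  rows <- NULL
  for (r in seq_len(nrow(parts))) {
    cols <- parts$aln_start[r]:parts$aln_end[r]
    gA <- chA[cols] == "-"; gB <- chB[cols] == "-"
    keep <- !(gA | gB)
    if (sum(keep) < 3L)
      stop("region ", r, " shorter than one codon after removing gaps")
    sA <- paste(chA[cols][keep], collapse = "")
    sB <- paste(chB[cols][keep], collapse = "")
    pctNt <- 100 * mean(chA[cols][keep] == chB[cols][keep])
    gapRuns <- rle(gA | gB)
    nIndel <- sum(gapRuns$values)
    for (f in .FRAME_LABELS) {
      st <- .frameCellStats(sA, sB, f, codeA, codeB, scheme)
      rows <- rbind(rows, data.frame(
        region = r, frame = f,
        region_start = parts$start[r], region_end = parts$end[r],
        pct_identical_nt = pctNt,
        pct_identical_aa = st[["pct_identical_aa"]],
        pct_identical_or_similar_aa = st[["pct_identical_or_similar_aa"]],
        gap_indel_count = nIndel,
        pct_stop_a = st[["pct_stop_a"]],
        pct_stop_b = st[["pct_stop_b"]],
        stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Per-column residue profiles of a protein MSA
#'
#' Tallies residues per column and flags columns where at least two distinct
#' residues interchange entirely within one similarity group (the pattern of
#' the Gau alignment columns such as "I (10) M (3)").
#'
#' @param msa character vector of equal-length aligned protein strings (or
#'   an \code{AAStringSet}).
#' @param scheme a \code{\linkS4class{SimilarityScheme}}.
#' @return data.frame with columns \code{column}, \code{profile} (residues
#'   with counts, most frequent first, e.g. \code{"I (10) M (3)"}),
#'   \code{n_distinct}, \code{same_family} (TRUE when >= 2 distinct residues
#'   all fall in one scheme group).
#' @export
columnFamilyProfile <- function(msa, scheme = similarityScheme("table3")) {
  if (is(msa, "AAStringSet")) msa <- as.character(msa)
  if (!is.character(msa) || length(msa) < 1L)
    stop("msa must be a character vector of aligned proteins")
  L <- unique(nchar(msa))
  if (length(L) != 1L) stop("ragged MSA: aligned sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  idx <- .groupIndex(scheme)
  out <- lapply(seq_len(L), function(j) {
    col <- mat[, j]
    col <- col[!col %in% c("-", ".")]
    tab <- sort(table(col), decreasing = TRUE)
    resid <- names(tab)
    sameFam <- length(resid) >= 2L && all(resid %in% names(idx)) &&
      length(unique(idx[resid])) == 1L
    data.frame(column = j,
               profile = paste(sprintf("%s (%d)", resid, as.integer(tab)),
                               collapse = " "),
               n_distinct = length(resid), same_family = sameFam,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
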