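## Locating the gau region: the antisense ORF on the complementary strand of
## cox1, anchored by the conserved GSPPP pentapeptide (anchor glycine at
## residue 2 of the 101-codon region).

#' The located gau region
#'
#' The 101-codon antisense ORF: one codon upstream of the anchor glycine
#' (candidate start, residue 1) through codon 101 (candidate stop). All
#' coordinates are 1-based inclusive on the parent sense strand (GenBank
#' convention); the region itself reads on the complementary strand.
#'
#' @slot parentId identifier of the parent sequence.
#' @slot strand always \code{"-"}.
#' @slot startNt,endNt 1-based inclusive span on the parent (303 nt).
#' @slot codons the 101 codons, read 5' to 3' on the antisense strand.
#' @slot anchorCodonIndex residue index of the anchor glycine (2).
#' @slot protein 101-character translation (stops as \code{"*"}).
#' @slot stopPositions 1-based codon indices translating to a stop.
#' @slot agrCount number of AGA + AGG codons among the 101.
#' @slot codeId genetic code used for translation.
#' @export
setClass("GauRegion",
  representation(parentId = "character", strand = "character",
                 startNt = "integer", endNt = "integer",
                 codons = "character", anchorCodonIndex = "integer",
                 protein = "character", stopPositions = "integer",
                 agrCount = "integer", codeId = "character"))

setValidity("GauRegion", function(object) {
  msg <- character(0)
  if (length(object@codons) != 101L)
    msg <- c(msg, "a gau region has exactly 101 codons")
  if (object@endNt - object@startNt + 1L != 303L)
    msg <- c(msg, "nucleotide span must be 303 nt")
  if (nchar(object@protein) != length(object@codons))
    msg <- c(msg, "protein length must equal codon count")
  if (!identical(object@strand, "-"))
    msg <- c(msg, "gau lies on the antisense strand")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GauRegion", function(object) {
  cat("GauRegion on '", object@parentId, "' (", object@strand, ") ",
      object@startNt, "-", object@endNt, " (code ", object@codeId, ")\n",
      "  protein: ", object@protein, "\n",
      "  stops:   ", if (length(object@stopPositions))
        paste(object@stopPositions, collapse = " ") else "none",
      "\n  AGR codons: ", object@agrCount, "\n", sep = "")
})

#' @describeIn extractGauRegion the 101 codons of a region
#' @export
gauCodons <- function(region) region@codons

#' @describeIn extractGauRegion the 101-residue protein of a region
#' @export
gauProtein <- function(region) region@protein

#' @describeIn extractGauRegion stop codon indices of a region
#' @export
stopPositions <- function(region) region@stopPositions

#' Locate an amino-acid motif in all six frames
#'
#' Exact-match search of the translated motif (default the gau anchor
#' pentapeptide GSPPP) across the six reading frames.
#'
#' @param seq nucleotide string.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param motif uppercase amino-acid string, non-empty.
#' @return data.frame with columns \code{frame} and \code{codon_index}
#'   (1-based residue position of the motif start within that frame's
#'   translation), sorted by frame then position; zero rows when absent.
#' @export
findAnchor <- function(seq, code, motif = "GSPPP") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty amino-acid string")
  motif <- toupper(motif)
  six <- sixFrameTranslate(seq, code)
  hits <- lapply(.FRAME_LABELS, function(f) {
    m <- gregexpr(motif, six[[f]]@protein, fixed = TRUE)[[1]]
    pos <- m[m > 0]
    if (!length(pos)) return(NULL)
    data.frame(frame = f, codon_index = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(frame = character(0), codon_index = integer(0),
                      stringsAsFactors = FALSE)
  out
}

## Pick the primary anchor among several hits: prefer minus-frame hits (the
## gau geometry), then the 5'-most on the antisense strand.
.primaryAnchor <- function(hits, preferFrame = "-2") {
  if (!nrow(hits)) return(NULL)
  minus <- hits[startsWith(hits$frame, "-"), , drop = FALSE]
  pool <- if (nrow(minus)) minus else hits
  pref <- pool[pool$frame == preferFrame, , drop = FALSE]
  pool <- if (nrow(pref)) pref else pool
  pool[order(match(pool$frame, .FRAME_LABELS), pool$codon_index), ][1, ]
}

#' Extract the 101-codon gau region around a GSPPP anchor
#'
#' The region is fixed as [anchor - 1 codon, anchor + 99 codons]: residue 1
#' is the candidate start, the anchor glycine sits at residue 2 (the
#' antigen peptide of the paper spans residues 2-15) and residue 101 is the
#' candidate stop. Coordinates are reported on the parent sense strand.
#'
#' @param seq nucleotide string containing cox1 (a CDS or a whole genome).
#' @param code a \code{\linkS4class{GeneticCode}} used to translate the
#'   region (e.g. vertebrate mt, AGR as stops, for vertebrate mtDNA).
#' @param anchor a one-row data.frame as returned by \code{\link{findAnchor}}
#'   (minus frame required), or \code{NULL} to search for \code{motif} and
#'   use the primary hit.
#' @param motif anchor motif used when \code{anchor} is \code{NULL}.
#' @param parentId identifier recorded on the region.
#' @param parentStart 1-based position of \code{seq}'s first base on a larger
#'   parent sequence, used to report parent coordinates (default 1).
#' @return a \code{\linkS4class{GauRegion}}.
#' @examples
#' g <- makeOverlapCds(seed = 1)
#' extractGauRegion(g$cds, geneticCode(5))
#' @export
extractGauRegion <- function(seq, code, anchor = NULL, motif = "GSPPP",
                             parentId = "seq", parentStart = 1L) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  if (is.null(anchor)) {
    hits <- findAnchor(s, code, motif)
    anchor <- .primaryAnchor(hits)
    if (is.null(anchor))
      stop("anchor motif '", motif, "' not found in any frame")
  }
  frame <- as.character(anchor$frame[1])
  a <- as.integer(anchor$codon_index[1])
  if (!startsWith(frame, "-"))
    stop("gau lies on the antisense strand; anchor must be in a minus frame")
  offset <- as.integer(substr(frame, 2, 2)) - 1L
  rc <- revComp(s)
  ## residue r of this frame occupies rc positions offset + 3(r-1)+1 .. offset + 3r
  rcStart <- offset + 3L * (a - 2L) + 1L
  rcEnd <- offset + 3L * (a + 99L)
  if (rcStart < 1L)
    stop("insufficient flanking sequence upstream of the anchor ",
         "(5' side of gau): need one codon before the anchor glycine")
  if (rcEnd > n)
    stop("insufficient flanking sequence downstream of the anchor ",
         "(3' side of gau): need 99 codons after the anchor glycine")
  regionRc <- substr(rc, rcStart, rcEnd)
  codons <- .splitCodons(regionRc)
  aa <- .translateCodons(codons, code)
  startNt <- n + 1L - rcEnd + (as.integer(parentStart) - 1L)
  endNt <- n + 1L - rcStart + (as.integer(parentStart) - 1L)
  new("GauRegion", parentId = as.character(parentId), strand = "-",
      startNt = startNt, endNt = endNt, codons = codons,
      anchorCodonIndex = 2L, protein = paste(aa, collapse = ""),
      stopPositions = which(aa == "*"), agrCount = countAgr(codons),
      codeId = code@codeId)
}

#' Candidate initiation codons of a gau region
#'
#' Mitochondrial genes frequently initiate at non-AUG codons; AUU/AUC/AUA
#' (normally isoleucine) and GUG are documented initiators. The candidate
#' start of the region is its first codon.
#'
#' @param region a \code{\linkS4class{GauRegion}}.
#' @param startSet codons accepted as initiators.
#' @return data.frame with columns \code{codon_index}, \code{codon}; zero
#'   rows when the first codon is not in the start set.
#' @export
candidateStarts <- function(region,
                            startSet = c("ATG", "ATA", "ATT", "ATC", "GTG")) {
  stopifnot(is(region, "GauRegion"))
  first <- region@codons[1L]
  if (first %in% toupper(startSet))
    data.frame(codon_index = 1L, codon = first, stringsAsFactors = FALSE)
  else
    data.frame(codon_index = integer(0), codon = character(0),
               stringsAsFactors = FALSE)
}

## Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Sliding-window hydropathy profile
#'
#' @slot window odd window width (residues).
#' @slot values per-position window means of Kyte-Doolittle scores.
#' @export
setClass("HydropathyProfile",
  representation(window = "integer", values = "numeric"))

setMethod("show", "HydropathyProfile", function(object) {
  cat("HydropathyProfile window ", object@window, ", ",
      length(object@values), " positions, range [",
      round(min(object@values, na.rm = TRUE), 2), ", ",
      round(max(object@values, na.rm = TRUE), 2), "]\n", sep = "")
})

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window arithmetic mean of per-residue Kyte-Doolittle scores.
#' Stop symbols (\code{"*"}) and unknown residues are excluded from each
#' window's mean (a window of only excluded positions yields \code{NA}).
#'
#' @param protein amino-acid string.
#' @param window odd window width, default 9.
#' @return a \code{\linkS4class{HydropathyProfile}} with
#'   \code{length(protein) - window + 1} values.
#' @export
hydropathyProfile <- function(protein, window = 9L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  res <- strsplit(toupper(protein), "")[[1]]
  L <- length(res)
  if (L < window) stop("protein shorter than window")
  kd <- unname(.KD[res])     # NA for '*' and unknowns -> excluded
  vals <- vapply(seq_len(L - window + 1L), function(i) {
    w <- kd[i:(i + window - 1L)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  new("HydropathyProfile", window = window, values = vals)
}

#' @describeIn hydropathyProfile numeric profile values
#' @param x a \code{HydropathyProfile}.
#' @export
profileValues <- function(x) x@values

## merge qualifying fixed-width windows into maximal intervals
.mergeWindows <- function(starts, width) {
  if (!length(starts)) return(NULL)
  ends <- starts + width - 1L
  out <- NULL
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1L) cur_e <- max(cur_e, ends[i])
    else { out <- rbind(out, c(cur_s, cur_e)); cur_s <- starts[i]; cur_e <- ends[i] }
  }
  rbind(out, c(cur_s, cur_e))
}

#' Charged and hydrophobic domains of a protein
#'
#' Reports maximal runs of windows exceeding the configured thresholds,
#' ordered 5' to 3'. The mid-protein architecture of Gau proteins is a
#' positively charged domain followed by a strongly hydrophobic one; the
#' thresholds below operationalise that pattern. Charge counts K,R as +1 and
#' D,E as -1 (H neutral).
#'
#' @param protein amino-acid string.
#' @param chargeWindow,minNetCharge window length (>= 10) and net-charge
#'   threshold (>= +3) for positive domains.
#' @param hydroWindow,minMeanKd window length (>= 15) and mean
#'   Kyte-Doolittle threshold (>= 1.5) for hydrophobic domains.
#' @return data.frame with columns \code{type} (\code{"positive"} or
#'   \code{"hydrophobic"}), \code{start}, \code{end}; zero rows when nothing
#'   exceeds the thresholds.
#' @export
chargeHydrophobicDomains <- function(protein, chargeWindow = 10L,
                                     minNetCharge = 3, hydroWindow = 15L,
                                     minMeanKd = 1.5) {
  res <- strsplit(toupper(protein), "")[[1]]
  L <- length(res)
  if (!L) stop("empty protein")
  charge <- ifelse(res %in% c("K", "R"), 1, ifelse(res %in% c("D", "E"), -1, 0))
  kd <- unname(.KD[res]); kd[is.na(kd)] <- 0
  rows <- NULL
  if (L >= chargeWindow) {
    cs <- c(0, cumsum(charge))
    net <- cs[(chargeWindow + 1L):(L + 1L)] - cs[1:(L - chargeWindow + 1L)]
    m <- .mergeWindows(which(net >= minNetCharge), chargeWindow)
    if (!is.null(m))
      rows <- rbind(rows, data.frame(type = "positive", start = m[, 1],
                                     end = m[, 2]))
  }
  if (L >= hydroWindow) {
    ck <- c(0, cumsum(kd))
    mn <- (ck[(hydroWindow + 1L):(L + 1L)] - ck[1:(L - hydroWindow + 1L)]) /
      hydroWindow
    m <- .mergeWindows(which(mn >= minMeanKd), hydroWindow)
    if (!is.null(m))
      rows <- rbind(rows, data.frame(type = "hydrophobic", start = m[, 1],
                                     end = m[, 2]))
  }
  if (is.null(rows))
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  rows <- rows[order(rows$start, rows$type), ]
  rownames(rows) <- NULL
  rows
}
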