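## Sense-protein-preserving synonymous-codon shuffle null model.
##
## Codons of the sense CDS are independently redrawn from their synonymous
## family according to the usage frequencies of the gene itself, leaving the
## sense protein bit-identical; the effect on the antisense gau frame
## (altered fractions, residue changes, stop counts) is the statistic.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

.cdsCodons <- function(cds) {
  s <- .normalizeSeq(cds)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length must be a multiple of 3")
  .splitCodons(s)
}

## synonymous families of a code (six-fold Leu/Ser families are single
## families: reassignment may cross codon blocks)
.codeFamilies <- function(code) {
  split(names(code@table), unname(code@table))
}

#' Within-family synonymous codon usage of a CDS
#'
#' Relative frequencies of synonymous codons within each amino-acid family,
#' tallied from the CDS itself. Unobserved codons get frequency 0; amino
#' acids absent from the CDS get an all-zero family.
#'
#' @param cds coding sequence (length a multiple of 3).
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @return named list (one element per amino acid, \code{"*"} included) of
#'   named numeric vectors summing to 1 (or all zero when unobserved).
#' @export
codonUsage <- function(cds, code) {
  codons <- .cdsCodons(cds)
  fams <- .codeFamilies(code)
  lapply(fams, function(cs) {
    cnt <- table(factor(codons, levels = cs))
    tot <- sum(cnt)
    if (tot == 0) setNames(rep(0, length(cs)), cs)
    else setNames(as.numeric(cnt) / tot, cs)
  })
}

#' Synonymous shuffle of a CDS
#'
#' Every codon except the terminal stop is independently redrawn from its
#' synonymous family under \code{usage}; stop codons are never reassigned.
#' The sense-frame protein of the output is identical to the input by
#' construction. Deterministic given \code{seed}.
#'
#' @param cds coding sequence.
#' @param code a \code{\linkS4class{GeneticCode}}.
#' @param usage a codon-usage list as from \code{\link{codonUsage}}
#'   (default: usage of \code{cds} itself, as in the original analysis).
#' @param seed integer seed.
#' @return shuffled CDS string.
#' @export
shuffleSynonymous <- function(cds, code, usage = NULL, seed = 1L) {
  codons <- .cdsCodons(cds)
  n <- length(codons)
  aa <- .translateCodons(codons, code)
  if (any(aa[-n] == "*"))
    warning("CDS contains internal stop codons; they are left unchanged")
  if (is.null(usage)) usage <- codonUsage(cds, code)
  new <- codons
  .withSeed(seed, {
    for (a in sort(unique(aa[-n]))) {       # fixed order for determinism
      if (a == "*" || a == "X") next
      if (is.null(usage[[a]]))
        stop("usage has no family for observed amino acid '", a, "'")
      f <- usage[[a]]
      f <- f[f > 0]
      if (!length(f))
        stop("usage family for '", a, "' has no positive frequencies")
      idx <- which(aa == a & seq_len(n) < n)
      if (length(f) == 1L) { new[idx] <- names(f); next }
      new[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    }
  })
  out <- paste(new, collapse = "")
  stopifnot(identical(.translateCodons(new, code), aa))
  out
}

## sense codon indices whose span intersects [a, b]
.senseCodonsOverlapping <- function(n, a, b) {
  k <- seq_len(n %/% 3L)
  which(3L * k >= a & 3L * k - 2L <= b)
}

.gauCodonsOfSpan <- function(cds, a, b) {
  .splitCodons(revComp(substr(cds, a, b)))
}

#' Per-replicate shuffle metrics
#'
#' Compares a shuffled CDS with the original over the whole gene and over
#' the gau-complementary subregion. The sense protein must be preserved
#' (asserted). Fractions are percentages:
#' \itemize{
#'   \item \code{frac_altered_gene}: codons changed over the CDS (terminal
#'     stop excluded from the denominator);
#'   \item \code{frac_altered_gau}: codons changed among sense codons
#'     overlapping the gau span;
#'   \item \code{frac_gau_aa_unchanged}: of the 101 gau residues, those
#'     identical to the natural translation;
#'   \item \code{frac_altered_to_aa_change}: changed gau residues per
#'     altered sense codon in the gau span (the ratio the original
#'     analysis reports as "altered codons resulting in changes");
#'   \item \code{gau_stop_count}: stops among the shuffled gau codons;
#'   \item \code{pct_ident_or_sim_vs_reference}: identical-or-similar
#'     fraction of the shuffled gau protein against a reference Gau
#'     protein (NA when no reference is given).
#' }
#'
#' @param original,shuffled the natural and shuffled CDS.
#' @param gau a \code{\linkS4class{GauRegion}} located on \code{original}
#'   (coordinates within the CDS).
#' @param code sense-frame genetic code.
#' @param gauCode code used to translate the gau frame (default vertebrate
#'   mt, AGR as stops, matching the stop bookkeeping of the original
#'   analysis).
#' @param reference optional reference Gau protein (string).
#' @param scheme similarity scheme for the reference comparison.
#' @param seed seed recorded in the output row.
#' @return one-row data.frame of the metrics above.
#' @export
replicateMetrics <- function(original, shuffled, gau, code,
                             gauCode = geneticCode(2), reference = NULL,
                             scheme = similarityScheme(), seed = NA_integer_) {
  stopifnot(is(gau, "GauRegion"))
  orig <- .normalizeSeq(original); shuf <- .normalizeSeq(shuffled)
  if (nchar(orig) != nchar(shuf))
    stop("original and shuffled CDS differ in length")
  a <- gau@startNt; b <- gau@endNt
  if (a < 1L || b > nchar(orig))
    stop("gau region does not lie within the CDS span")
  codO <- .cdsCodons(orig); codS <- .cdsCodons(shuf)
  n <- length(codO)
  if (!identical(.translateCodons(codO, code), .translateCodons(codS, code)))
    stop("sense protein not preserved by the shuffle")
  altered <- codS != codO
  fracGene <- 100 * mean(altered[-n])
  inGau <- .senseCodonsOverlapping(nchar(orig), a, b)
  fracGau <- 100 * mean(altered[inGau])
  gauO <- .translateCodons(.gauCodonsOfSpan(orig, a, b), gauCode)
  gauS <- .translateCodons(.gauCodonsOfSpan(shuf, a, b), gauCode)
  unchanged <- 100 * mean(gauS == gauO)
  nAlteredGau <- sum(altered[inGau])
  changedRes <- sum(gauS != gauO)
  toChange <- if (nAlteredGau > 0) 100 * changedRes / nAlteredGau else 0
  stopCount <- sum(gauS == "*")
  simRef <- NA_real_
  if (!is.null(reference))
    simRef <- .pctIdentOrSimilar(paste(gauS, collapse = ""), reference, scheme)
  data.frame(seed = seed, frac_altered_gene = fracGene,
             frac_altered_gau = fracGau, frac_gau_aa_unchanged = unchanged,
             frac_altered_to_aa_change = toChange,
             gau_stop_count = stopCount,
             pct_ident_or_sim_vs_reference = simRef)
}

## global protein alignment -> % identical-or-similar over gapless columns
.pctIdentOrSimilar <- function(protein, reference, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4)
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- x != "-" & y != "-"
  100 * mean(x[keep] == y[keep] | residuesSimilar(scheme, x[keep], y[keep]))
}

#' Exhaustively enumerate stop-creating gau positions
#'
#' Each gau codon draws its first two bases from one sense codon and its
#' third base from the preceding one. For every gau codon the synonymous
#' families of both parent sense codons are enumerated jointly (stop codons
#' are never reassigned, matching the shuffle), and the gau codon indices
#' where some synonymous sense configuration yields a stop are collected.
#' Indices that are not stops in the natural sequence are the
#' "stop-creating" set; together with the natural stop indices they bound
#' the stop count of any shuffle replicate from above. Deterministic.
#'
#' @param cds the natural coding sequence.
#' @param code sense-frame code defining synonymy.
#' @param gau a \code{\linkS4class{GauRegion}} located on \code{cds}.
#' @param gauCode code used to read the gau frame (default vertebrate mt).
#' @return sorted integer vector of gau codon indices (1..101) where a
#'   synonymous sense change creates a stop; attributes \code{"natural"}
#'   (natural stop indices) and \code{"possible"} (all indices that can
#'   hold a stop under some synonymous configuration).
#' @export
enumerateStopSites <- function(cds, code, gau, gauCode = geneticCode(2)) {
  stopifnot(is(gau, "GauRegion"))
  s <- .normalizeSeq(cds)
  a <- gau@startNt; b <- gau@endNt
  if (a < 1L || b > nchar(s)) stop("gau region does not lie within the CDS")
  if (b %% 3L != 2L || a %% 3L != 0L)
    stop("gau span is not in the -2 frame of the CDS codon grid")
  codons <- .cdsCodons(s)
  n <- length(codons)
  aa <- .translateCodons(codons, code)
  fams <- .codeFamilies(code)
  natural <- which(.translateCodons(.gauCodonsOfSpan(s, a, b), gauCode) == "*")
  nGau <- (b - a + 1L) %/% 3L
  variants <- function(k) {
    if (k < 1L || k > n || aa[k] %in% c("*", "X")) return(codons[k])
    fams[[aa[k]]]
  }
  possible <- integer(0)
  for (j in seq_len(nGau)) {
    p3 <- b - 3L * j + 1L            # sense position pairing gau base 3
    k1 <- p3 %/% 3L                  # codon providing base 3 (its 3rd nt)
    k2 <- k1 + 1L                    # codon providing bases 1 and 2
    isStop <- FALSE
    for (c1 in variants(k1)) {
      for (c2 in variants(k2)) {
        g <- paste0(.COMP[substr(c2, 2, 2)], .COMP[substr(c2, 1, 1)],
                    .COMP[substr(c1, 3, 3)])
        if (!is.na(gauCode@table[g]) && gauCode@table[[g]] == "*") {
          isStop <- TRUE
          break
        }
      }
      if (isStop) break
    }
    if (isStop) possible <- c(possible, j)
  }
  out <- sort(setdiff(possible, natural))
  attr(out, "natural") <- natural
  attr(out, "possible") <- sort(possible)
  out
}

#' Summarise shuffle replicates
#'
#' Means and standard deviations of every replicate metric, the two-tailed
#' paired t test between the gene-wide and gau-region altered fractions,
#' and (when a reference similarity is supplied) the two-tailed one-sample
#' t test of replicate similarity against the natural value.
#'
#' @param reps data.frame of rows from \code{\link{replicateMetrics}}.
#' @param naturalStopCount stop count of the natural gau frame.
#' @param naturalSimilarity natural-sequence similarity to the reference
#'   (percent), for the one-sample test.
#' @return list with elements \code{n_reps}, \code{means}, \code{sds},
#'   \code{paired_t}, \code{paired_p}, \code{one_sample_t},
#'   \code{one_sample_p}, \code{natural_gau_stop_count}, \code{degenerate}.
#' @export
summarizeReplicates <- function(reps, naturalStopCount = NA_integer_,
                                naturalSimilarity = NA_real_) {
  if (nrow(reps) < 2L) stop("need at least 2 replicates for t statistics")
  metricCols <- setdiff(names(reps), "seed")
  means <- vapply(reps[metricCols], mean, numeric(1))
  sds <- vapply(reps[metricCols], sd, numeric(1))
  d <- reps$frac_altered_gau - reps$frac_altered_gene
  degenerate <- isTRUE(all.equal(sd(d), 0)) || all(d == d[1])
  if (degenerate) {
    pt_ <- NA_real_; tt <- NA_real_
  } else {
    ht <- t.test(reps$frac_altered_gau, reps$frac_altered_gene, paired = TRUE)
    tt <- unname(ht$statistic); pt_ <- ht$p.value
  }
  os_t <- NA_real_; os_p <- NA_real_
  simv <- reps$pct_ident_or_sim_vs_reference
  if (!is.na(naturalSimilarity) && all(!is.na(simv)) && sd(simv) > 0) {
    ho <- t.test(simv, mu = naturalSimilarity)
    os_t <- unname(ho$statistic); os_p <- ho$p.value
  }
  list(n_reps = nrow(reps), means = means, sds = sds,
       paired_t = tt, paired_p = pt_,
       one_sample_t = os_t, one_sample_p = os_p,
       natural_gau_stop_count = naturalStopCount,
       degenerate = degenerate)
}

#' Run the full shuffle study on a CDS
#'
#' Locates the gau region (unless given), computes the CDS's own codon
#' usage, draws \code{nReps} independent shuffles with counter-based seeds
#' (\code{seed + replicate index}), and summarises.
#'
#' @param cds coding sequence of the sense gene (cox1).
#' @param code sense-frame genetic code.
#' @param gau optional pre-located \code{\linkS4class{GauRegion}}.
#' @param nReps number of replicates (default 20, as in the original
#'   design).
#' @param seed master seed.
#' @param gauCode code for translating the gau frame.
#' @param reference optional reference Gau protein for the similarity
#'   metric.
#' @param scheme similarity scheme for the reference comparison.
#' @return list with \code{replicates} (data.frame), \code{summary} (from
#'   \code{\link{summarizeReplicates}}) and \code{natural} (list with
#'   \code{stop_count}, \code{agr_count}, \code{similarity}).
#' @export
runShuffleStudy <- function(cds, code, gau = NULL, nReps = 20L, seed = 1L,
                            gauCode = geneticCode(2), reference = NULL,
                            scheme = similarityScheme()) {
  s <- .normalizeSeq(cds)
  if (is.null(gau))
    gau <- extractGauRegion(s, gauCode, parentId = "cds")
  usage <- codonUsage(s, code)
  reps <- do.call(rbind, lapply(seq_len(nReps), function(i) {
    shuf <- shuffleSynonymous(s, code, usage, seed = seed + i)
    replicateMetrics(s, shuf, gau, code, gauCode = gauCode,
                     reference = reference, scheme = scheme, seed = seed + i)
  }))
  natAA <- .translateCodons(.gauCodonsOfSpan(s, gau@startNt, gau@endNt),
                            gauCode)
  natSim <- if (!is.null(reference))
    .pctIdentOrSimilar(paste(natAA, collapse = ""), reference, scheme)
  else NA_real_
  natural <- list(stop_count = sum(natAA == "*"),
                  agr_count = gau@agrCount, similarity = natSim)
  list(replicates = reps,
       summary = summarizeReplicates(reps, natural$stop_count, natSim),
       natural = natural, gau = gau)
}
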