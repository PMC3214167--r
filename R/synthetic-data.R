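## Deterministic generators for sequences and tables with planted truth:
## cox1-like CDS carrying a GSPPP-anchored antisense ORF, divergent homolog
## pairs, contrast datasets with a known AGR effect, and genome sets with
## planted stop deciles. Every generator is reproducible from its seed and
## its planted features are recovered exactly by the analysis functions.

.randCodons <- function(k, pool) {
  if (k <= 0L) return(character(0))
  sample(pool, k, replace = TRUE)
}

## pools for one code: free = non-stop, non-AGR codons; stop pool excludes
## AGR so planted stop and AGR counts stay independent
.codonPools <- function(code) {
  stops <- stopCodons(code)
  agr <- c("AGA", "AGG")
  list(free = setdiff(names(code@table), c(stops, agr)),
       stops = setdiff(stops, agr),
       agr = agr,
       fams = .codeFamilies(code))
}

## draw one codon for gau position j given its constraint
.drawGauCodon <- function(kind, value, pools) {
  switch(kind,
    codon = value,
    stop = sample(pools$stops, 1L),
    agr = sample(pools$agr, 1L),
    aa = {
      cand <- setdiff(pools$fams[[value]], c(pools$agr, pools$fams[["*"]]))
      if (!length(cand)) stop("no usable codon for amino acid ", value)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    },
    free = sample(pools$free, 1L))
}

## Build a gau-frame codon vector under positional constraints.
## constraints: list(kind=..., value=...) per position, kinds as above.
.buildGauCodons <- function(constraints, pools) {
  vapply(constraints, function(ct) .drawGauCodon(ct$kind, ct$value, pools),
         character(1))
}

## can position j of the constraint list be redrawn (not a rigid codon)?
.flexible <- function(constraints, j) constraints[[j]]$kind != "codon"

#' Generate a cox1-like CDS with a planted antisense gau region
#'
#' Builds a sense CDS whose \code{-2} frame carries a 101-codon region with
#' the anchor pentapeptide GSPPP at residues 2-6, a chosen candidate start
#' codon at residue 1, planted stop codons, a planted AGR codon count, and
#' a terminal TAA at residue 101; the sense frame itself is stop-free up to
#' its terminal stop. Deterministic given \code{seed};
#' \code{\link{extractGauRegion}} recovers every planted property exactly
#' (under the generation code; under an AGR-as-stop code the planted AGR
#' codons additionally read as stops).
#'
#' @param stopPositions gau codon indices in 7..100 to plant stops (TAA/TAG)
#'   at; residue 101 is handled by \code{terminalStop}.
#' @param agrCount number of AGR codons to plant (positions drawn from the
#'   free residues), or \code{NULL} with explicit \code{agrPositions}.
#' @param agrPositions explicit gau codon indices for AGR codons.
#' @param upstreamCodons,downstreamCodons sense codons flanking the region.
#' @param codeId genetic code for generation (default 5, invertebrate mt,
#'   under which AGR codons are serine, not stops).
#' @param startCodon codon planted at gau residue 1.
#' @param terminalStop plant TAA at gau residue 101 (default TRUE).
#' @param seed integer seed.
#' @return list with \code{cds}, \code{gauStart}, \code{gauEnd} (1-based on
#'   the CDS), \code{codons}, \code{protein}, \code{stopPositions} (as seen
#'   under the generation code, terminal included), \code{agrPositions},
#'   \code{anchorResidue} (2), \code{codeId}, \code{seed}.
#' @export
makeOverlapCds <- function(stopPositions = integer(0), agrCount = NULL,
                           agrPositions = NULL, upstreamCodons = 25L,
                           downstreamCodons = 25L, codeId = "5",
                           startCodon = "ATA", terminalStop = TRUE,
                           seed = 1L) {
  R <- 101L
  code <- geneticCode(codeId)
  pools <- .codonPools(code)
  stopPositions <- sort(unique(as.integer(stopPositions)))
  if (length(stopPositions) && (min(stopPositions) < 7L ||
                                max(stopPositions) > 100L))
    stop("planted stop positions must lie in 7..100")
  reserved <- c(1:6, stopPositions, if (terminalStop) R)
  .withSeed(seed, {
    if (is.null(agrPositions) && !is.null(agrCount)) {
      freePos <- setdiff(7:100, stopPositions)
      if (agrCount > length(freePos))
        stop("infeasible spec: AGR target exceeds available region positions")
      agrPositions <- sort(sample(freePos, agrCount))
    }
    agrPositions <- sort(unique(as.integer(agrPositions)))
    if (any(agrPositions %in% reserved))
      stop("AGR positions collide with anchor/start/stop positions")
    constraints <- lapply(seq_len(R), function(j) {
      if (j == 1L) list(kind = "codon", value = toupper(startCodon))
      else if (j <= 6L)
        list(kind = "aa", value = c("G", "S", "P", "P", "P")[j - 1L])
      else if (j %in% stopPositions) list(kind = "stop", value = NULL)
      else if (terminalStop && j == R) list(kind = "codon", value = "TAA")
      else if (j %in% agrPositions) list(kind = "agr", value = NULL)
      else list(kind = "free", value = NULL)
    })
    u <- as.integer(upstreamCodons); d <- as.integer(downstreamCodons)
    senseStops <- stopCodons(code)
    for (attempt in 1:60) {
      gau <- .buildGauCodons(constraints, pools)
      gauNt <- paste(gau, collapse = "")
      flank5 <- c(.randCodons(u, pools$free),
                  paste(sample(.BASES, 2, replace = TRUE), collapse = ""))
      flank3 <- c(paste(sample(.BASES, 1), collapse = ""),
                  .randCodons(d, pools$free),
                  sample(pools$stops, 1L))
      cds <- paste0(paste(flank5, collapse = ""), revComp(gauNt),
                    paste(flank3, collapse = ""))
      a <- 3L * u + 3L
      b <- 3L * u + 2L + 3L * R
      ## repair sense-frame stops by redrawing flexible gau codons/flanks
      ok <- FALSE
      for (iter in 1:200) {
        codons <- .cdsCodons(cds)
        n <- length(codons)
        bad <- which(codons %in% senseStops)
        bad <- bad[bad < n]
        if (!length(bad)) { ok <- TRUE; break }
        k <- bad[1]
        inRegion <- 3L * k >= a && 3L * k - 2L <= b
        if (inRegion) {
          ps <- (3L * k - 2L):(3L * k)
          ps <- ps[ps >= a & ps <= b]
          js <- unique(ceiling((b - ps + 1L) / 3L))
          js <- js[js >= 1L & js <= R]
          js <- js[vapply(js, function(j) .flexible(constraints, j), TRUE)]
          if (!length(js)) break              # rigid collision: rebuild
          for (j in js) {
            ct <- constraints[[j]]
            gau[j] <- .drawGauCodon(ct$kind, ct$value, pools)
          }
          gauNt <- paste(gau, collapse = "")
          cds <- paste0(paste(flank5, collapse = ""), revComp(gauNt),
                        paste(flank3, collapse = ""))
        } else if (3L * k < a) {
          flank5[k] <- sample(pools$free, 1L)   # codon k of the 5' flank
          cds <- paste0(paste(flank5, collapse = ""), revComp(gauNt),
                        paste(flank3, collapse = ""))
        } else {
          idx <- k - (u + R + 1L)               # codon index within flank3
          flank3[idx + 1L] <- sample(pools$free, 1L)
          cds <- paste0(paste(flank5, collapse = ""), revComp(gauNt),
                        paste(flank3, collapse = ""))
        }
      }
      if (!ok) next
      ## the anchor must be unique across the six frames
      hits <- findAnchor(cds, code)
      if (nrow(hits) == 1L && hits$frame == "-2") {
        aaGau <- .translateCodons(gau, code)
        return(list(cds = cds, gauStart = a, gauEnd = b, codons = gau,
                    protein = paste(aaGau, collapse = ""),
                    stopPositions = which(aaGau == "*"),
                    agrPositions = agrPositions,
                    anchorResidue = 2L, codeId = codeId, seed = seed))
      }
    }
    stop("could not realise the requested overlap spec; ",
         "it may be infeasible")
  })
}

#' Generate a divergent homologous CDS pair at a target identity
#'
#' Takes a planted overlap CDS and mutates a fixed number of positions
#' (outside the 15-nt anchor span, so both sequences retain GSPPP) to reach
#' the requested gap-free positional identity.
#'
#' @param identity target nucleotide identity in [0.3, 1].
#' @param seed integer seed.
#' @param ... passed to \code{\link{makeOverlapCds}} for the base sequence.
#' @return list with \code{seqA} (the base CDS), \code{seqB} (mutant),
#'   \code{identity} (realised), \code{base} (the generator truth of seqA).
#' @export
makeDivergentPair <- function(identity = 0.8, seed = 1L, ...) {
  if (identity < 0.3 || identity > 1)
    stop("identity must be within [0.3, 1]")
  base <- makeOverlapCds(seed = seed, ...)
  s <- base$cds
  n <- nchar(s)
  b <- base$gauEnd
  anchorSpan <- (b - 17L):(b - 3L)    # sense span of gau codons 2..6
  m <- round((1 - identity) * n)
  seqB <- s
  .withSeed(seed + 104729L, {
    pos <- sample(setdiff(seq_len(n), anchorSpan), m)
    for (p in pos) {
      cur <- substr(seqB, p, p)
      substr(seqB, p, p) <- sample(setdiff(.BASES, cur), 1L)
    }
  })
  realized <- mean(strsplit(s, "")[[1]] == strsplit(seqB, "")[[1]])
  list(seqA = s, seqB = seqB, identity = realized, base = base)
}

#' Generate a contrast dataset with a known AGR effect
#'
#' Emulates the comparative design: monophyletic groups each containing
#' tRNA-possessing and tRNA-lacking taxa whose AGR counts are drawn from
#' \code{round(Normal(mu + delta, sigma))} and \code{round(Normal(mu,
#' sigma))} respectively, clipped at 0. Defaults mirror the published
#' design: 13 groups (7 gains, 6 losses), baseline count 12 (primate gau
#' stop counts span 8-17), divergence times on a 1-60 My scale.
#'
#' @param nGroups number of groups (>= 2).
#' @param delta true AGR-count effect of tRNA presence.
#' @param sigma count noise SD (>= 0).
#' @param mu baseline AGR count.
#' @param times divergence times (My), one per group; default uniform on
#'   [1, 60].
#' @param nGains number of groups labelled "gain" (the rest "loss").
#' @param maxGroupSize taxa per side drawn uniformly from 1..maxGroupSize.
#' @param seed integer seed.
#' @return data.frame with columns \code{taxon}, \code{group_id},
#'   \code{trna_present}, \code{agr_count}, \code{divergence_time_my},
#'   \code{scenario}.
#' @export
makeContrastDataset <- function(nGroups = 13L, delta = 1, sigma = 2,
                                mu = 12, times = NULL, nGains = 7L,
                                maxGroupSize = 3L, seed = 1L) {
  if (nGroups < 2L) stop("need at least 2 groups")
  if (sigma < 0) stop("sigma must be >= 0")
  .withSeed(seed, {
    if (is.null(times))
      times <- round(sort(runif(nGroups, 1, 60)), 1)
    scenario <- c(rep("gain", nGains), rep("loss", nGroups - nGains))
    rows <- lapply(seq_len(nGroups), function(g) {
      nW <- sample.int(maxGroupSize, 1L)
      nWo <- sample.int(maxGroupSize, 1L)
      w <- pmax(0, round(rnorm(nW, mu + delta, sigma)))
      wo <- pmax(0, round(rnorm(nWo, mu, sigma)))
      data.frame(
        taxon = c(sprintf("g%02d_with_%d", g, seq_len(nW)),
                  sprintf("g%02d_without_%d", g, seq_len(nWo))),
        group_id = sprintf("%02d", g),
        trna_present = c(rep(1L, nW), rep(0L, nWo)),
        agr_count = c(w, wo),
        divergence_time_my = times[g],
        scenario = scenario[g], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a genome set with planted stop deciles
#'
#' Each anchored genome embeds, on its complementary strand, a 300-codon
#' frame around a GSPPP anchor (window i upstream, window ii from the
#' glycine, window iii beyond), with stops planted at known positions and
#' none elsewhere; a configurable fraction of genomes lack the anchor. The
#' returned truth table lists, per genome and window, exactly what
#' \code{\link{scanRecord}} and \code{\link{aggregateScan}} should report.
#'
#' @param n number of genomes.
#' @param meanStops Poisson mean of planted stops per 100-codon window.
#' @param anchorFreeFraction fraction of genomes generated without the
#'   anchor motif.
#' @param phyla phylum labels recycled over genomes.
#' @param flankNt random flank length on each side.
#' @param codeId genetic code id used for generation and scanning.
#' @param seed integer seed.
#' @return list with \code{sequences} (named character vector),
#'   \code{phyla} (named), \code{truth} (data.frame: \code{id},
#'   \code{phylum}, \code{window}, \code{n_stops}, \code{decile} (last for
#'   window i, first for ii/iii; NA when stop-free), \code{no_stop},
#'   \code{anchor} logical).
#' @export
makeGenomeSet <- function(n = 20L, meanStops = 2, anchorFreeFraction = 0,
                          phyla = c("Arthropoda", "Chordata", "Mollusca"),
                          flankNt = 120L, codeId = "5", seed = 1L) {
  code <- geneticCode(codeId)
  pools <- .codonPools(code)
  phyla <- rep_len(phyla, n)
  .withSeed(seed, {
    seqs <- character(n); truth <- NULL
    ids <- sprintf("genome_%03d", seq_len(n))
    hasAnchor <- runif(n) >= anchorFreeFraction
    for (g in seq_len(n)) {
      if (!hasAnchor[g]) {
        repeat {
          gen <- paste(sample(.BASES, 3L * 220L + 2L * flankNt,
                              replace = TRUE), collapse = "")
          if (nrow(findAnchor(gen, code)) == 0L) break
        }
        seqs[g] <- gen
        truth <- rbind(truth, data.frame(
          id = ids[g], phylum = phyla[g], window = .WINDOWS,
          n_stops = NA_integer_, decile = NA_integer_, no_stop = NA,
          anchor = FALSE, stringsAsFactors = FALSE))
        next
      }
      ## planted stops per window (window ii spares the GSPPP residues 1..5)
      planted <- list(
        i = sort(sample(1:100, min(rpois(1, meanStops), 100))),
        ii = sort(sample(6:100, min(rpois(1, meanStops), 95))),
        iii = sort(sample(1:100, min(rpois(1, meanStops), 100))))
      constraints <- lapply(1:300, function(j) {
        if (j >= 101L && j <= 105L)
          list(kind = "aa", value = c("G", "S", "P", "P", "P")[j - 100L])
        else if (j <= 100L && j %in% planted$i) list(kind = "stop")
        else if (j > 100L && j <= 200L && (j - 100L) %in% planted$ii)
          list(kind = "stop")
        else if (j > 200L && (j - 200L) %in% planted$iii)
          list(kind = "stop")
        else list(kind = "free")
      })
      repeat {
        gau <- .buildGauCodons(constraints, pools)
        gen <- paste0(
          paste(sample(.BASES, flankNt, replace = TRUE), collapse = ""),
          revComp(paste(gau, collapse = "")),
          paste(sample(.BASES, flankNt, replace = TRUE), collapse = ""))
        hits <- findAnchor(gen, code)
        if (nrow(hits) == 1L) break
      }
      seqs[g] <- gen
      truth <- rbind(truth, data.frame(
        id = ids[g], phylum = phyla[g], window = .WINDOWS,
        n_stops = vapply(.WINDOWS, function(w) length(planted[[w]]), 1L),
        decile = vapply(.WINDOWS, function(w) {
          p <- planted[[w]]
          if (!length(p)) NA_integer_
          else if (w == "i") .decile(max(p)) else .decile(min(p))
        }, 1L),
        no_stop = vapply(.WINDOWS, function(w) !length(planted[[w]]), TRUE),
        anchor = TRUE, stringsAsFactors = FALSE))
    }
    names(seqs) <- ids; names(phyla) <- ids
    list(sequences = seqs, phyla = phyla, truth = truth)
  })
}
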