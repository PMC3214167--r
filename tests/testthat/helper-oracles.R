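## Independent oracles and fixture builders used across the suite.

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

## random stop-free CDS (sense frame) with terminal stop, under a code
randomCleanCds <- function(nCodons, code, terminal = TRUE) {
  pool <- setdiff(names(codonTable(code)), stopCodons(code))
  body <- sample(pool, nCodons - as.integer(terminal), replace = TRUE)
  paste(c(body, if (terminal) sample(stopCodons(code), 1)), collapse = "")
}

## translation oracle: Biostrings' translator, frame handled here
oracleTranslate <- function(seq, codeId, frame) {
  s <- chartr("U", "T", toupper(seq))
  if (startsWith(frame, "-"))
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  off <- as.integer(substr(frame, 2, 2)) - 1L
  len <- (nchar(s) - off) %/% 3L
  sub <- substr(s, off + 1L, off + 3L * len)
  as.character(Biostrings::translate(
    Biostrings::DNAString(sub),
    genetic.code = Biostrings::getGeneticCode(codeId),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

## affine-gap global alignment score by explicit Gotoh DP
## (gap of length L costs open + L * ext, as in the implementation)
gotohScore <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## brute-force Fitch: minimum changes over all internal labelings
bruteFitchScore <- function(tree, tipStates) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  st <- as.integer(tipStates[tree$tip.label])
  nInt <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nInt - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(nInt)])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

## lexicographic permutation enumerator (independent of the package's)
lexPerms <- function(n) {
  out <- matrix(0L, factorial(n), n)
  p <- seq_len(n)
  for (r in seq_len(nrow(out))) {
    out[r, ] <- p
    ## next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
  }
  out
}

## build a 300-codon anchored frame with chosen window stops, as a genome
plantedGenome <- function(stopsI = integer(0), stopsII = integer(0),
                          stopsIII = integer(0), flankNt = 90, seed = 42) {
  set.seed(seed)
  code <- geneticCode(5)
  pool <- setdiff(names(codonTable(code)),
                  c(stopCodons(code), "AGA", "AGG"))
  gau <- sample(pool, 300, replace = TRUE)
  gau[101:105] <- c("GGA", "TCA", "CCA", "CCT", "CCG")  # GSPPP
  gau[stopsI] <- "TAA"
  gau[100 + stopsII] <- "TAA"
  gau[200 + stopsIII] <- "TAA"
  paste0(randomDna(flankNt),
         revComp(paste(gau, collapse = "")),
         randomDna(flankNt))
}
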