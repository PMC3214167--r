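code2 <- geneticCode(2)
code5 <- geneticCode(5)

test_that("codonUsage computes within-family frequencies from the gene", {
  u <- codonUsage(strrep("TTT", 10), geneticCode(1))
  expect_equal(u[["F"]][["TTT"]], 1)
  expect_equal(u[["F"]][["TTC"]], 0)
  ## frequencies within each observed family sum to 1
  set.seed(2)
  cds <- randomCleanCds(200, code2)
  u2 <- codonUsage(cds, code2)
  sums <- vapply(u2, sum, numeric(1))
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
  ## counts agree with a naive tally
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  nLeu <- sum(codons %in% names(codonTable(code2))[codonTable(code2) == "L"])
  leu <- u2[["L"]] * nLeu
  tallied <- table(factor(codons[codons %in% names(leu)], levels = names(leu)))
  expect_equal(unname(round(leu)), as.vector(tallied))
  expect_error(codonUsage("ATGA", code2), "multiple of 3")
})

test_that("shuffling preserves the sense protein and is seed-deterministic", {
  set.seed(4)
  for (rep in 1:25) {
    cds <- randomCleanCds(40, code2)
    shuf <- shuffleSynonymous(cds, code2, seed = rep)
    expect_identical(frameProtein(translateFrame(shuf, code2, "+1")),
                     frameProtein(translateFrame(cds, code2, "+1")))
  }
  cds <- randomCleanCds(60, code2)
  expect_identical(shuffleSynonymous(cds, code2, seed = 99),
                   shuffleSynonymous(cds, code2, seed = 99))
  ## single-member families can never change
  mono <- "ATGTGGATGTGGTAA"          # M W M W * under the standard code
  expect_identical(shuffleSynonymous(mono, geneticCode(1), seed = 1), mono)
})

test_that("altered fraction converges to 1 - sum(p^2) for a known family", {
  ## Phe family planted at 90% TTT / 10% TTC: expected altered = 0.18
  set.seed(12)
  n <- 1e5
  codons <- sample(c("TTT", "TTC"), n, replace = TRUE, prob = c(0.9, 0.1))
  cds <- paste(c(codons, "TAA"), collapse = "")
  usage <- list(F = c(TTT = 0.9, TTC = 0.1))
  usage <- c(usage, codonUsage(cds, geneticCode(1))[setdiff(
    names(codonUsage(cds, geneticCode(1))), "F")])
  shuf <- shuffleSynonymous(cds, geneticCode(1), usage = usage, seed = 77)
  newCod <- substring(shuf, seq(1, nchar(shuf) - 2, 3), seq(3, nchar(shuf), 3))
  altered <- mean(newCod[seq_len(n)] != codons)
  expected <- 1 - (0.9^2 + 0.1^2)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(altered - expected), 3 * se)
})

test_that("replicateMetrics is exact on degenerate and hand-built cases", {
  g <- makeOverlapCds(stopPositions = c(30, 80), agrCount = 5, seed = 14)
  reg <- extractGauRegion(g$cds, code5)
  ## shuffled == original
  m0 <- replicateMetrics(g$cds, g$cds, reg, code5, gauCode = code5)
  expect_equal(m0$frac_altered_gene, 0)
  expect_equal(m0$frac_altered_gau, 0)
  expect_equal(m0$frac_gau_aa_unchanged, 100)
  expect_identical(m0$gau_stop_count, length(stopPositions(reg)))
  ## one forced synonymous substitution inside the gau span
  codons <- substring(g$cds, seq(1, nchar(g$cds) - 2, 3),
                      seq(3, nchar(g$cds), 3))
  aa <- unname(codonTable(code5)[codons])
  kIn <- which(3 * seq_along(codons) >= g$gauStart &
                 3 * seq_along(codons) - 2 <= g$gauEnd)
  k <- NULL
  for (cand in kIn) {
    fam <- names(codonTable(code5))[codonTable(code5) == aa[cand]]
    if (length(fam) > 1) { k <- cand; alt <- setdiff(fam, codons[cand])[1]; break }
  }
  mod <- codons; mod[k] <- alt
  m1 <- replicateMetrics(g$cds, paste(mod, collapse = ""), reg, code5,
                         gauCode = code5)
  expect_equal(m1$frac_altered_gene, 100 / (length(codons) - 1))
  expect_equal(m1$frac_altered_gau, 100 / length(kIn))
  ## a non-synonymous change must be rejected
  bad <- codons
  bad[2] <- setdiff(names(codonTable(code5))[codonTable(code5) !=
                                               aa[2]], stopCodons(code5))[1]
  expect_error(replicateMetrics(g$cds, paste(bad, collapse = ""), reg, code5,
                                gauCode = code5), "not preserved")
})

test_that("enumerateStopSites agrees with a brute-force single-change scan", {
  g <- makeOverlapCds(stopPositions = c(20, 55), agrCount = 6, seed = 30)
  reg <- extractGauRegion(g$cds, code5)
  sites <- enumerateStopSites(g$cds, code5, reg, gauCode = code2)
  ## oracle: substitute every synonymous single-codon variant, re-extract
  ## the region through the locator, and collect new stop indices
  codons <- substring(g$cds, seq(1, nchar(g$cds) - 2, 3),
                      seq(3, nchar(g$cds), 3))
  aa <- unname(codonTable(code5)[codons])
  nat <- stopPositions(extractGauRegion(g$cds, code2))
  found <- integer(0)
  for (k in seq_len(length(codons) - 1)) {
    fam <- names(codonTable(code5))[codonTable(code5) == aa[k]]
    anchorHit <- findAnchor(g$cds, code5)
    for (alt in setdiff(fam, codons[k])) {
      mod <- codons; mod[k] <- alt
      st <- stopPositions(extractGauRegion(paste(mod, collapse = ""), code2,
                                           anchor = anchorHit))
      found <- union(found, setdiff(st, nat))
    }
  }
  ## joint enumeration is a superset of the single-change scan
  expect_true(all(found %in% sites))
  expect_identical(attr(sites, "natural"), nat)
  expect_true(all(nat %in% attr(sites, "possible")))
})

test_that("a third-position-locked antisense frame admits no stop sites", {
  ## all-glycine sense region: gau codons are CCx, never a stop
  cds <- paste0(strrep("GGG", 102), "TAA")
  reg <- new("GauRegion", parentId = "gly", strand = "-", startNt = 3L,
             endNt = 305L,
             codons = rep("CCC", 101), anchorCodonIndex = 2L,
             protein = strrep("P", 101), stopPositions = integer(0),
             agrCount = 0L, codeId = "2")
  sites <- enumerateStopSites(cds, code2, reg, gauCode = code2)
  expect_length(sites, 0)
  expect_length(attr(sites, "possible"), 0)
})

test_that("replicate stop counts never exceed the enumerated bound", {
  g <- makeOverlapCds(stopPositions = c(25, 40, 90), agrCount = 8, seed = 55)
  reg <- extractGauRegion(g$cds, code5)
  sites <- enumerateStopSites(g$cds, code5, reg, gauCode = code2)
  bound <- length(attr(sites, "possible"))
  for (i in 1:10) {
    shuf <- shuffleSynonymous(g$cds, code5, seed = 1000 + i)
    m <- replicateMetrics(g$cds, shuf, reg, code5, gauCode = code2)
    expect_lte(m$gau_stop_count, bound)
  }
})

test_that("summarizeReplicates reproduces closed-form t statistics", {
  base <- data.frame(seed = 1:4, frac_altered_gene = c(50, 52, 50, 52),
                     frac_altered_gau = c(51, 51, 51, 51),
                     frac_gau_aa_unchanged = 80,
                     frac_altered_to_aa_change = 40, gau_stop_count = 10,
                     pct_ident_or_sim_vs_reference = NA_real_)
  ## paired differences are {1,-1,1,-1}: t = 0, p = 1
  s <- summarizeReplicates(base)
  expect_equal(s$paired_t, 0)
  expect_equal(s$paired_p, 1)
  ## a 5-point dataset against the closed-form paired t
  d <- c(2.3, 1.1, -0.4, 3.0, 0.8)
  df5 <- data.frame(seed = 1:5, frac_altered_gene = 50,
                    frac_altered_gau = 50 + d,
                    frac_gau_aa_unchanged = 80,
                    frac_altered_to_aa_change = 40, gau_stop_count = 10,
                    pct_ident_or_sim_vs_reference = NA_real_)
  s5 <- summarizeReplicates(df5)
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(s5$paired_t, tHand)
  expect_equal(s5$paired_p, 2 * pt(abs(tHand), 4, lower.tail = FALSE))
  ## zero-variance differences are flagged degenerate
  dfDeg <- df5; dfDeg$frac_altered_gau <- 51
  sd_ <- summarizeReplicates(dfDeg)
  expect_true(sd_$degenerate)
  expect_true(is.na(sd_$paired_p))
  expect_error(summarizeReplicates(df5[1, ]), "at least 2")
})

test_that("runShuffleStudy is reproducible and internally consistent", {
  g <- makeOverlapCds(stopPositions = c(35, 70), agrCount = 6, seed = 77)
  st1 <- runShuffleStudy(g$cds, code5, nReps = 6, seed = 5, gauCode = code2)
  st2 <- runShuffleStudy(g$cds, code5, nReps = 6, seed = 5, gauCode = code2)
  expect_identical(st1$replicates, st2$replicates)
  expect_identical(st1$summary$n_reps, 6L)
  expect_true(all(st1$replicates$frac_altered_gau >= 0 &
                    st1$replicates$frac_altered_gau <= 100))
  ## natural stop count under the AGR-as-stop code includes planted AGRs
  expect_identical(st1$natural$stop_count, 2L + 6L + 1L)
})
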