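test_that("similarity schemes are disjoint and classify pairs correctly", {
  tab3 <- similarityScheme("table3")
  expect_true(residuesSimilar(tab3, "I", "M"))
  expect_true(residuesSimilar(tab3, "K", "N"))
  expect_true(residuesSimilar(tab3, "Q", "H"))
  expect_false(residuesSimilar(tab3, "I", "K"))
  expect_true(residuesSimilar(tab3, "W", "W"))   # identity always similar
  expect_error(similarityScheme("x", list(c("A", "G"), c("G", "S"))),
               "disjoint")
})

test_that("global alignment matches the exhaustive affine-gap DP oracle", {
  ## exhaustive over short binary-alphabet pairs
  enum <- function(len) {
    if (len == 0) return("")
    apply(expand.grid(rep(list(c("A", "C")), len)), 1, paste, collapse = "")
  }
  for (la in 1:3) {
    for (lb in 1:3) {
      for (a in enum(la)) {
        for (b in enum(lb)) {
          aln <- globalAlignNt(a, b)
          expect_equal(aln@score, gotohScore(a, b), info = paste(a, b))
        }
      }
    }
  }
  ## random longer pairs
  set.seed(17)
  for (rep in 1:25) {
    a <- randomDna(sample(4:8, 1)); b <- randomDna(sample(4:8, 1))
    expect_equal(globalAlignNt(a, b)@score, gotohScore(a, b),
                 info = paste(a, b))
    ## score is symmetric in the inputs
    expect_equal(globalAlignNt(a, b)@score, globalAlignNt(b, a)@score)
  }
})

test_that("identical sequences align gapless at 100% identity", {
  s <- randomDna(60)
  aln <- globalAlignNt(s, s)
  expect_identical(alignedA(aln), s)
  expect_identical(alignedB(aln), s)
  tab <- frameComparisonTable(aln, geneticCode(5), geneticCode(5))
  expect_true(all(tab$pct_identical_nt == 100))
  expect_true(all(tab$pct_identical_aa == 100))
  expect_true(all(tab$pct_identical_or_similar_aa == 100))
  expect_equal(tab$pct_stop_a, tab$pct_stop_b)
})

test_that("partitionRegions maps seqA ranges onto alignment columns", {
  aln <- pairAlignmentFromAligned("AAACCC---GGGTTT", "AAACCCTTTGGGTTT")
  ## single covering range
  p1 <- partitionRegions(aln, data.frame(start = 1, end = 12))
  expect_identical(p1$aln_start, 1L)
  expect_identical(p1$aln_end, 15L)
  ## gap columns stick to the region of the preceding seqA position
  p2 <- partitionRegions(aln, data.frame(start = c(1, 7), end = c(6, 12)))
  expect_identical(p2$aln_end[1], 9L)     # the three gap columns join region 1
  expect_identical(p2$aln_start[2], 10L)
  expect_equal(sum(p2$end - p2$start + 1), 12)
  expect_error(partitionRegions(aln, data.frame(start = c(1, 6), end = c(6, 12))),
               "contiguous")
  expect_error(partitionRegions(aln, data.frame(start = 1, end = 20)),
               "contiguous")
})

test_that("frameComparisonTable matches a hand-computed toy cell", {
  ## two gap-free 4-codon sequences, compared in frame +1 under code 1
  a <- "ATGAAACCCTGG"   # M K P W
  b <- "ATGAAGCCATGG"   # M K P W (two silent third-position changes)
  aln <- globalAlignNt(a, b)
  tab <- frameComparisonTable(aln, geneticCode(1), geneticCode(1),
                              scheme = similarityScheme("table3"))
  p1 <- tab[tab$frame == "+1", ]
  expect_equal(p1$pct_identical_nt, 100 * 10 / 12)
  expect_equal(p1$pct_identical_aa, 100)
  expect_equal(p1$gap_indel_count, 0)
  ## -2 frame by hand: revcomp both, offset 1, three codons
  rcA <- revComp(a); rcB <- revComp(b)
  aaA <- frameProtein(translateFrame(a, geneticCode(1), "-2"))
  aaB <- frameProtein(translateFrame(b, geneticCode(1), "-2"))
  m2 <- tab[tab$frame == "-2", ]
  cmp <- strsplit(aaA, "")[[1]] == strsplit(aaB, "")[[1]]
  expect_equal(m2$pct_identical_aa, 100 * mean(cmp))
  expect_equal(m2$pct_stop_a,
               100 * mean(strsplit(aaA, "")[[1]] == "*"))
})

test_that("identity never exceeds identity-or-similarity", {
  pair <- makeDivergentPair(identity = 0.7, seed = 41)
  aln <- globalAlignNt(pair$seqA, pair$seqB)
  tab <- frameComparisonTable(aln, geneticCode(5), geneticCode(5))
  expect_true(all(tab$pct_identical_aa <=
                    tab$pct_identical_or_similar_aa + 1e-9))
  expect_true(all(tab$pct_identical_nt >= 0 & tab$pct_identical_nt <= 100))
})

test_that("five-region breakpoints partition a synthetic pair consistently", {
  pair <- makeDivergentPair(identity = 0.85, seed = 6)
  n <- nchar(pair$seqA)
  cuts <- round(seq(0, n, length.out = 6))
  bp <- data.frame(start = cuts[-6] + 1, end = cuts[-1])
  aln <- globalAlignNt(pair$seqA, pair$seqB)
  tab <- frameComparisonTable(aln, geneticCode(5), geneticCode(5),
                              breakpoints = bp)
  expect_identical(nrow(tab), 30L)   # 5 regions x 6 frames
  expect_identical(unique(tab$region), 1:5)
})

test_that("columnFamilyProfile tallies columns and flags family columns", {
  ## a column of 10 I and 3 M in 13 aligned sequences
  msa <- c(rep("IA", 10), rep("MA", 3))
  prof <- columnFamilyProfile(msa, similarityScheme("table3"))
  expect_identical(prof$profile[1], "I (10) M (3)")
  expect_true(prof$same_family[1])
  ## uniform column: no change, flag off
  expect_false(prof$same_family[2])
  expect_identical(prof$profile[2], "A (13)")
  ## mixed-group column flags off
  prof2 <- columnFamilyProfile(c("K", "I"), similarityScheme("table3"))
  expect_false(prof2$same_family[1])
  expect_error(columnFamilyProfile(c("AA", "A")), "ragged")
  ## random MSA against a brute-force tally
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- replicate(6, paste(sample(aas, 15, replace = TRUE), collapse = ""))
  pr <- columnFamilyProfile(m)
  mat <- do.call(rbind, strsplit(m, ""))
  for (j in sample(15, 4)) {
    tb <- sort(table(mat[, j]), decreasing = TRUE)
    expect_identical(pr$profile[j],
                     paste(sprintf("%s (%d)", names(tb), as.integer(tb)),
                           collapse = " "))
  }
})
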