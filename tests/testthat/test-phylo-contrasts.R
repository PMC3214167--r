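test_that("contrasts are mean differences, with the printed worked example", {
  ## velvet-monkey group: 11 AGR codons with the tRNA, 10.5 mean without
  expect_equal(computeContrast(11, 10.5), 0.5)
  expect_equal(computeContrast(c(3, 5), c(1, 3)), 2)
  expect_equal(computeContrast(c(4, 6), c(5, 5)), 0)
  expect_error(computeContrast(numeric(0), 1), "non-empty")
})

test_that("the sign test is the exact binomial tail in integer arithmetic", {
  ## all positive: (1/2)^n
  expect_equal(signTest(rep(1, 12))$p, 0.5^12)
  ## 6 of 7 positive
  expect_equal(signTest(c(rep(1, 6), -1))$p, 8 / 128)
  ## 9 of 13 positive: 1093/8192 (not the printed 0.0231)
  s913 <- signTest(c(rep(1, 9), rep(-1, 4)))
  expect_equal(s913$p, 1093 / 8192)
  ## against the stats::pbinom oracle over a grid
  for (n in c(5, 10, 13, 20)) {
    for (k in 0:n) {
      contrasts <- c(rep(1, k), rep(-1, n - k))
      expect_equal(signTest(contrasts)$p,
                   pbinom(k - 1, n, 0.5, lower.tail = FALSE),
                   tolerance = 1e-12, info = paste(n, k))
    }
  }
  ## zeros are dropped and counted
  sz <- signTest(c(1, 1, 0, 0, -1))
  expect_identical(sz$n, 3L)
  expect_identical(sz$n_zero, 2L)
  ## all-zero input is degenerate
  expect_true(signTest(c(0, 0))$degenerate)
  ## direction flips the counted sign
  expect_equal(signTest(c(-1, -1, -1), direction = "negative")$p, 0.5^3)
})

test_that("spearmanRho matches cor.test and exhaustive permutation", {
  expect_equal(spearmanRho(1:6, c(2, 4, 6, 8, 10, 12))$rs, 1)
  expect_equal(spearmanRho(1:6, 6:1)$rs, -1)
  ## untied n = 6: exact permutation equals cor.test's exact p
  set.seed(9)
  x <- c(3, 10, 2, 8, 5, 7); y <- c(1.2, 9.1, 2.3, 7.7, 4.4, 6.1)
  ours <- spearmanRho(x, y, alternative = "two.sided")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(ours$rs, unname(ct$estimate))
  expect_equal(ours$p, ct$p.value, tolerance = 1e-12)
  ## tied n = 6: against an independent lexicographic enumeration
  xt <- c(1, 2, 2, 4, 5, 6); yt <- c(2, 1, 4, 3, 6, 5)
  ours2 <- spearmanRho(xt, yt, alternative = "greater")
  rx <- rank(xt); ry <- rank(yt)
  perms <- lexPerms(6)
  null_rs <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(ours2$p, mean(null_rs >= ours2$rs - 1e-12))
  ## large n falls back to the t approximation
  set.seed(13)
  xl <- rnorm(30); yl <- xl + rnorm(30)
  big <- spearmanRho(xl, yl, alternative = "greater")
  expect_identical(big$method, "t approximation")
  expect_lt(big$p, 0.01)
  ## constant input is degenerate
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)$p))
})

test_that("Fitch parsimony equals brute force and phangorn on small trees", {
  ## all tips present: no changes
  t4 <- ape::read.tree(text = "((a,b),(c,d));")
  all1 <- setNames(c(1, 1, 1, 1), c("a", "b", "c", "d"))
  f <- fitchGainLoss(t4, all1)
  expect_identical(f$score, 0L)
  expect_identical(nrow(f$events), 0L)
  ## a single present tip is one gain on its terminal edge
  one <- setNames(c(1, 0, 0, 0), c("a", "b", "c", "d"))
  f1 <- fitchGainLoss(t4, one)
  expect_identical(f1$score, 1L)
  expect_identical(f1$events$type, "gain")
  expect_identical(f1$events$child, which(t4$tip.label == "a"))
  expect_error(fitchGainLoss(t4, setNames(1, "a")), "unlabelled")
  ## random trees up to 8 tips against exhaustive minimisation
  set.seed(21)
  for (rep in 1:15) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt)
    st <- setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    ours <- fitchGainLoss(tr, st)
    expect_identical(ours$score, as.integer(bruteFitchScore(tr, st)))
    expect_identical(nrow(ours$events), as.integer(ours$score))
    expect_lte(ours$score, sum(st == 1))
    ## cross-check with phangorn's Fitch score
    pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                  dimnames = list(names(st), NULL)),
                           type = "USER", levels = 0:1)
    expect_identical(as.integer(phangorn::fitch(tr, pd)), ours$score)
  }
})

test_that("runContrastAnalysis recovers planted effects and antisymmetry", {
  ## deterministic effect: every contrast equals +2, sign p = (1/2)^12
  ds <- makeContrastDataset(nGroups = 12, delta = 2, sigma = 0, nGains = 6,
                            seed = 3)
  res <- runContrastAnalysis(ds)
  expect_true(all(res$contrasts$contrast == 2))
  expect_identical(res$tests$n_positive, 12L)
  expect_equal(res$tests$sign_all$p, 0.5^12)
  ## swapping group labels negates every contrast and maps k to n - k
  swapped <- ds
  swapped$trna_present <- 1L - swapped$trna_present
  resSw <- runContrastAnalysis(swapped)
  expect_equal(resSw$contrasts$contrast, -res$contrasts$contrast)
  expect_identical(resSw$tests$sign_all$k,
                   res$tests$sign_all$n - res$tests$sign_all$k)
  ## a 13-group table built to have 9 positives reports exactly that
  tab <- do.call(rbind, lapply(1:13, function(g) {
    delta <- if (g <= 9) 1 else -1
    data.frame(taxon = paste0("t", g, c("w", "o")),
               group_id = g, trna_present = c(1L, 0L),
               agr_count = c(10 + delta, 10),
               divergence_time_my = g, scenario = "gain")
  }))
  r13 <- runContrastAnalysis(tab)
  expect_identical(r13$tests$n_positive, 9L)
  expect_equal(r13$tests$sign_all$p, 1093 / 8192)
})

test_that("effect recovery strengthens monotonically with delta", {
  frac_pos <- vapply(c(0.5, 2, 6), function(d) {
    ds <- makeContrastDataset(nGroups = 40, delta = d, sigma = 2, nGains = 20,
                              seed = 101)
    res <- runContrastAnalysis(ds)
    res$tests$n_positive / res$tests$n_contrasts
  }, numeric(1))
  expect_true(all(diff(frac_pos) >= 0))
  expect_gt(frac_pos[3], 0.95)
})

test_that("scenarios can be derived from a tree by Fitch labelling", {
  ## two clades: one gained the tRNA (single present tip), one lost it
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  tab <- data.frame(
    taxon = c("a1", "a2", "b1", "b2"),
    group_id = c("A", "A", "B", "B"),
    trna_present = c(1L, 0L, 1L, 0L),
    agr_count = c(12, 10, 9, 11),
    divergence_time_my = c(5, 5, 8, 8))
  res <- suppressWarnings(runContrastAnalysis(tab, tree = tr))
  expect_identical(sort(unique(res$contrasts$scenario)), "gain")
  expect_equal(res$contrasts$contrast[res$contrasts$group_id == "A"], 2)
})
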