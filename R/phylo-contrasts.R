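## Phylogenetically independent contrasts of gau AGR-codon counts against
## antitermination-tRNA presence: exact sign tests, Spearman correlations
## against divergence time, and Fitch parsimony gain/loss labelling.

#' Count AGR (AGA/AGG) codons
#'
#' AGR codons are arginine in the standard code but stops in the vertebrate
#' mitochondrial code; their count in the gau frame is the trait contrasted
#' against antitermination-tRNA presence.
#'
#' @param x a \code{\linkS4class{GauRegion}} or a character vector of
#'   codons.
#' @return integer count.
#' @export
countAgr <- function(x) {
  codons <- if (is(x, "GauRegion")) x@codons else toupper(x)
  sum(codons %in% c("AGA", "AGG"))
}

#' Phylogenetic contrast of AGR counts
#'
#' Mean AGR count of the tRNA-possessing taxa minus the mean of the matched
#' tRNA-lacking taxa.
#'
#' @param withCounts,withoutCounts non-empty numeric vectors of AGR counts.
#' @return the contrast (with - without).
#' @examples
#' computeContrast(11, 10.5)  # +0.5, the velvet-monkey group
#' @export
computeContrast <- function(withCounts, withoutCounts) {
  if (!length(withCounts) || !length(withoutCounts))
    stop("both groups must be non-empty")
  mean(withCounts) - mean(withoutCounts)
}

## exact binomial tail P(X >= k | n, 1/2) by integer arithmetic:
## cumulative Pascal-row sums (exact in doubles below 2^53)
.exactSignTail <- function(n, k) {
  if (k <= 0) return(1)
  row <- 1                       # choose(n, 0..n) built by Pascal recurrence
  for (i in seq_len(n)) row <- c(row, 0) + c(0, row)
  sum(row[(k + 1L):(n + 1L)]) / 2^n
}

#' Exact one-sided sign test
#'
#' Exact binomial tail \eqn{P(X \ge k \mid n, 1/2)} over the nonzero
#' contrasts; zeros are dropped and their count reported. Binomials are
#' accumulated by integer arithmetic (Pascal recurrence), not a floating
#' density.
#'
#' @param contrasts numeric vector of signed contrasts.
#' @param direction which sign counts as a success (\code{"positive"} or
#'   \code{"negative"}).
#' @return list with \code{n} (nonzero contrasts), \code{k} (successes),
#'   \code{n_zero}, \code{p} (one-sided exact), \code{degenerate} (TRUE
#'   when all contrasts are zero; \code{p} is then NA).
#' @examples
#' signTest(rep(1, 12))$p  # (1/2)^12
#' @export
signTest <- function(contrasts, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  nz <- contrasts[contrasts != 0]
  nZero <- sum(contrasts == 0)
  if (!length(nz))
    return(list(n = 0L, k = 0L, n_zero = nZero, p = NA_real_,
                degenerate = TRUE))
  k <- if (direction == "positive") sum(nz > 0) else sum(nz < 0)
  list(n = length(nz), k = as.integer(k), n_zero = nZero,
       p = .exactSignTail(length(nz), k), degenerate = FALSE)
}

## all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with small-n exact permutation p
#'
#' Ranks use midranks for ties; \eqn{r_s} is the Pearson correlation of the
#' ranks. For \eqn{n \le} \code{exactMax} the p-value is exact over all
#' \eqn{n!} permutations of one variable; otherwise the t approximation
#' with \eqn{n - 2} df is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alternative \code{"two.sided"}, \code{"greater"} (positive
#'   association) or \code{"less"}.
#' @param exactMax largest n for exhaustive permutation (default 8).
#' @return list with \code{rs}, \code{p}, \code{n}, \code{method}.
#' @export
spearmanRho <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exactMax = 8L) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal-length vectors with n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rs = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  rs <- stats::cor(rx, ry)
  if (n <= exactMax) {
    perms <- .permutations(n)
    null_rs <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    eps <- 1e-12
    p <- switch(alternative,
      greater = mean(null_rs >= rs - eps),
      less = mean(null_rs <= rs + eps),
      two.sided = mean(abs(null_rs) >= abs(rs) - eps))
    method <- "exact permutation"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- switch(alternative,
      greater = pt(tstat, n - 2, lower.tail = FALSE),
      less = pt(tstat, n - 2),
      two.sided = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
    method <- "t approximation"
  }
  list(rs = rs, p = p, n = n, method = method)
}

#' Fitch parsimony for a binary character
#'
#' Bottom-up (preliminary state sets) and top-down (final states) Fitch
#' passes on a rooted tree; every edge whose endpoints differ is a change,
#' labelled gain (0 to 1) or loss (1 to 0). Ambiguous final states resolve
#' to the parent's state; an ambiguous root resolves to 0 (trait absent
#' ancestrally), which fixes the gain/loss labelling deterministically.
#'
#' @param tree a rooted \code{ape::phylo} tree.
#' @param tipStates named 0/1 vector covering every tip label.
#' @return list with \code{score} (minimal change count), \code{states}
#'   (final state per node, tips first, ape node numbering),
#'   \code{state_sets} (preliminary sets as a two-column logical matrix
#'   [allows 0, allows 1]), and \code{events} (data.frame: \code{edge},
#'   \code{parent}, \code{child}, \code{type} gain/loss).
#' @export
fitchGainLoss <- function(tree, tipStates) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(tipStates)))
    stop("unlabelled tip(s): ",
         paste(setdiff(tree$tip.label, names(tipStates)), collapse = ", "))
  st <- as.integer(tipStates[tree$tip.label])
  if (any(is.na(st) | !st %in% c(0L, 1L)))
    stop("tip states must be 0/1 for every tip")
  nn <- nt + tree$Nnode
  sets <- matrix(FALSE, nn, 2L)           # col 1: allows 0, col 2: allows 1
  sets[cbind(seq_len(nt), st + 1L)] <- TRUE
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  score <- 0L
  ## bottom-up in reverse node order (ape numbers internal nodes root-out)
  for (nd in sort(unique(tree$edge[, 1]), decreasing = TRUE)) {
    ch <- kids[[as.character(nd)]]
    inter <- c(TRUE, TRUE)
    for (c_ in ch) inter <- inter & sets[c_, ]
    if (any(inter)) sets[nd, ] <- inter
    else {
      uni <- c(FALSE, FALSE)
      for (c_ in ch) uni <- uni | sets[c_, ]
      sets[nd, ] <- uni
      score <- score + 1L
    }
  }
  ## top-down final states
  final <- integer(nn)
  root <- nt + 1L
  final[root] <- if (sets[root, 2] && !sets[root, 1]) 1L else 0L
  ord <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(ord))) {
    p <- ord[i, 1]; c_ <- ord[i, 2]
    final[c_] <- if (sets[c_, final[p] + 1L]) final[p]
                 else if (sets[c_, 1]) 0L else 1L
  }
  chg <- which(final[tree$edge[, 2]] != final[tree$edge[, 1]])
  events <- data.frame(
    edge = chg, parent = tree$edge[chg, 1], child = tree$edge[chg, 2],
    type = ifelse(final[tree$edge[chg, 2]] == 1L, "gain", "loss"),
    stringsAsFactors = FALSE)
  list(score = score, states = final, state_sets = sets, events = events)
}

#' Run the contrast analysis over a taxon table
#'
#' Input mirrors the comparative design: monophyletic groups each holding
#' tRNA-possessing and tRNA-lacking taxa, with the group's divergence time
#' and (optionally) a gain/loss scenario. When scenarios are absent and a
#' tree is supplied, Fitch parsimony on tRNA presence labels each group by
#' the state change reconstructed on the stem of its tRNA-possessing taxa.
#'
#' @param table data.frame with columns \code{taxon}, \code{group_id},
#'   \code{trna_present} (0/1), \code{agr_count}, and optionally
#'   \code{divergence_time_my} and \code{scenario} ("gain"/"loss").
#' @param tree optional rooted \code{ape::phylo} with tip labels matching
#'   \code{taxon}, used only to derive missing scenarios.
#' @return list with \code{contrasts} (data.frame: \code{group_id},
#'   \code{contrast}, \code{min_n}, \code{divergence_time_my},
#'   \code{scenario}) and \code{tests} (list: \code{n_contrasts},
#'   \code{n_positive}, \code{sign_all}, \code{sign_gains},
#'   \code{spearman_gains} (one-sided, positive), \code{spearman_losses}
#'   (two-sided)).
#' @export
runContrastAnalysis <- function(table, tree = NULL) {
  need <- c("taxon", "group_id", "trna_present", "agr_count")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  groups <- split(table, table$group_id)
  if (length(groups) < 2L) stop("need at least 2 groups to contrast")
  scenarioFromTree <- NULL
  if (!"scenario" %in% names(table) && !is.null(tree)) {
    fit <- fitchGainLoss(tree, setNames(table$trna_present, table$taxon))
    scenarioFromTree <- fit
  }
  rows <- lapply(groups, function(g) {
    w <- g$agr_count[g$trna_present == 1]
    wo <- g$agr_count[g$trna_present == 0]
    if (!length(w) || !length(wo))
      stop("group ", g$group_id[1],
           " must contain both tRNA-present and tRNA-absent taxa")
    scen <- if ("scenario" %in% names(g)) as.character(g$scenario[1])
            else if (!is.null(scenarioFromTree)) {
              ## state change on the stem edges of the tRNA-present tips
              tips <- match(g$taxon[g$trna_present == 1], tree$tip.label)
              ev <- scenarioFromTree$events
              hit <- ev$type[ev$child %in% tips]
              if (length(hit)) hit[1] else "loss"
            } else NA_character_
    data.frame(group_id = g$group_id[1],
               contrast = computeContrast(w, wo),
               min_n = min(length(w), length(wo)),
               divergence_time_my = if ("divergence_time_my" %in% names(g))
                 g$divergence_time_my[1] else NA_real_,
               scenario = scen, stringsAsFactors = FALSE)
  })
  cdf <- do.call(rbind, rows)
  rownames(cdf) <- NULL
  signAll <- signTest(cdf$contrast)
  gains <- cdf[!is.na(cdf$scenario) & cdf$scenario == "gain", , drop = FALSE]
  losses <- cdf[!is.na(cdf$scenario) & cdf$scenario == "loss", , drop = FALSE]
  signGains <- if (nrow(gains)) signTest(gains$contrast) else NULL
  spearGains <- spearLosses <- NULL
  if (nrow(gains) >= 3 && all(!is.na(gains$divergence_time_my)))
    spearGains <- spearmanRho(gains$divergence_time_my, gains$contrast,
                              alternative = "greater")
  else if (nrow(gains))
    warning("divergence times missing or too few gains; Spearman skipped")
  if (nrow(losses) >= 3 && all(!is.na(losses$divergence_time_my)))
    spearLosses <- spearmanRho(losses$divergence_time_my, losses$contrast,
                               alternative = "two.sided")
  list(contrasts = cdf,
       tests = list(n_contrasts = nrow(cdf),
                    n_positive = sum(cdf$contrast > 0),
                    sign_all = signAll, sign_gains = signGains,
                    spearman_gains = spearGains,
                    spearman_losses = spearLosses))
}
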