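---
title: "Locating and testing the antisense ORF of cox1"
author: "gauscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and testing the antisense ORF of cox1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gauscan)
```

## The problem

Mitochondrial genomes are compact, and both strands are transcribed. On the
complementary strand of the cytochrome c oxidase subunit I gene (*cox1*), a
positionally conserved open reading frame — *gau*, "gene antisense
ubiquitous" — has been described across eukaryotic mitochondria and
alpha-proteobacteria. It sits in the reading frame in which third codon
positions of *cox1* and of the antisense frame pair with each other, is
roughly 100 codons long, and is anchored by a strongly conserved
pentapeptide, GSPPP, whose glycine is residue 2 of the putative protein.

Whether *gau* is a real protein-coding gene is contested, and most of the
computational arguments about it reduce to a handful of quantitative
analyses that this package implements as reusable, tested machinery:

1. **Frame geometry** (`translateFrame`, `sixFrameTranslate`,
   `minus2Codon`): translation under NCBI genetic-code tables, and the
   antisense codon geometry in which the codon paired with sense codon
   $k$ takes bases 1–2 from the complement of positions 2–1 of codon
   $k{+}1$ and base 3 from the complement of position 3 of codon $k$.
   First and second antisense codon positions are therefore "locked" to
   conserved sense positions, while third positions pair with third
   positions.
2. **Locator** (`findAnchor`, `extractGauRegion`): the 101-codon region
   [anchor − 1, anchor + 99], its stop catalogue, AGR (AGA/AGG) codon
   count, candidate start codons, hydropathy and charge-domain profiles.
3. **Conservation tables** (`globalAlignNt`, `frameComparisonTable`,
   `columnFamilyProfile`): per-region, per-frame amino-acid identity and
   similarity between two *cox1* genes, each translated under its own
   code, plus per-column residue family profiles of an aligned set of Gau
   proteins.
4. **Synonymous-shuffle null model** (`runShuffleStudy`): redraw each
   sense codon from its synonymous family at the gene's own usage
   frequencies — leaving the Cox1 protein untouched — and measure how much
   the antisense frame moves.
5. **Comparative contrasts** (`runContrastAnalysis`): phylogenetically
   independent contrasts of gau AGR-codon counts between clades with and
   without predicted antitermination (antisense) tRNAs whose anticodons
   read the AGR stop codons, with exact sign tests, Spearman rank
   correlations against divergence time, and Fitch parsimony gain/loss
   labelling.
6. **Genome scan** (`scanRecord`, `aggregateScan`): a GSPPP-anchored
   three-window stop-codon survey across genome collections.

## Genetic codes and conventions

Built-in codes are NCBI tables 1 (standard), 2 (vertebrate mt), 3 (yeast
mt), 4 (mold/protozoan mt) and 5 (invertebrate mt), taken from
`Biostrings::GENETIC_CODE_TABLE`; custom tables load from TSV. The
vertebrate mitochondrial code reassigns AGA/AGG from arginine to stop
(`agrAsStop(geneticCode(2))` is `TRUE`), which is why vertebrate gau
frames are punctuated by stops that invertebrate frames do not have; stop
bookkeeping inside gau therefore defaults to table 2 and is switchable
everywhere.

DNA and RNA are both accepted (U is normalised to T); codons containing
ambiguity codes translate to `X` and never count as stops. Coordinates
are 1-based inclusive on the parent sense strand, the GenBank convention;
minus-frame offsets follow the reverse complement. Translation always
runs through stops — the object of study is where the stops are.

Which code a non-vertebrate taxon "should" use for gau stop counting is
genuinely open; functions take the code as an argument and the default is
documented rather than asserted.

## The locator

`extractGauRegion` fixes the region as one codon upstream of the anchor
glycine (candidate start, residue 1; mitochondrial initiation at
AUA/AUU/AUC/GUG is common, so the start set is configurable) through
codon 101, which is typically an ochre/amber candidate stop. On the human
mitochondrial genome distributed with the seqinr package (NC_001807) this
yields the 303-nt span 6288–6590 on the sense strand, with GSPPP at
residues 2–6 — the same span the antigen peptide used to raise an
anti-Gau antibody was taken from (residues 2–15).

When GSPPP occurs more than once, the locator prefers a hit in frame −2
(then the 5'-most minus-frame hit) and reports all hits via `findAnchor`.
Whether a published span includes the position-101 stop codon can differ
by one codon between conventions; this locator's convention is fixed as
above and stated here rather than inferred per input.

Hydropathy profiles use the Kyte–Doolittle scale with a default window of
9 (odd windows only); stop symbols are excluded from window means rather
than scored as 0, so a stop-containing window reflects only its residues.
Charge/hydrophobic domains operationalise the "positively charged block
followed by a very hydrophobic block" architecture as maximal runs of
windows with net charge ≥ +3 over ≥ 10 residues (K,R = +1, D,E = −1, H
neutral) and mean hydropathy ≥ 1.5 over ≥ 15 residues. These thresholds
are design choices — the published figures bold the domains without
defining them numerically — and are exposed as arguments.

## Conservation tables

`globalAlignNt` is Needleman–Wunsch with affine gaps behind
`Biostrings::pairwiseAlignment`; default scoring is match +1, mismatch
−1, gap open 5, gap extend 2 (a length-$L$ gap costs $5 + 2L$). The
scoring is configurable, and a pre-computed alignment can be supplied via
`pairAlignmentFromAligned` for exact reproduction against another
aligner's output. Regions are defined by breakpoints on the first
sequence; gap columns attach to the region of the preceding first-
sequence position. Within each region, columns gapped in either sequence
are dropped before codon extraction (they are tallied as indel events),
so percentages are over gap-free codon columns — the denominators of
published tables are not always stated, and this is the convention used
throughout.

Similarity is defined by a partition of amino acids into disjoint groups.
The families observed to interchange in Gau alignment columns (F/L/I/M/V,
K/N, Q/H) ship as scheme `"table3"`; the default scheme
`"physicochemical"` is a broader disjoint partition (GAVLIM / FYW / ST /
NQ / DE / KRH). A ClustalW-style "strong group" scheme was considered and
rejected because its groups overlap, which breaks the disjointness that
`columnFamilyProfile`'s single-family flag relies on.

## The shuffle null model

The null hypothesis the shuffle operationalises: if *cox1* codon usage
were indifferent to the antisense frame, synonymous reshuffling should
degrade the antisense frame as much as any other constraint allows.
Every sense codon except the terminal stop is redrawn independently from
its synonymous family at the frequencies observed in the gene itself
(stop codons are never reassigned; the six-fold leucine and serine
families are treated as single families, so reassignment may cross codon
blocks). The Cox1 protein is bit-identical by construction and asserted
on every replicate.

Per replicate, the package reports the altered-codon fraction gene-wide
and within the gau-complementary span, the fraction of the 101 gau
residues left unchanged, the number of changed gau residues per altered
sense codon in the span, and the gau stop count. Expected altered
fraction within a family with frequencies $p_i$ is $1 - \sum p_i^2$,
which the test suite verifies by simulation at $n = 10^5$ draws.
`summarizeReplicates` applies a two-tailed paired t test (gene vs gau
altered fractions) and, when a reference Gau protein is supplied, a
two-tailed one-sample t test of replicate similarity against the natural
value; zero-variance differences are flagged degenerate instead of
producing a p-value.

`enumerateStopSites` answers "where could a stop exist without touching
the protein?" Each gau codon depends on two sense codons, so the
enumeration varies both parent codons jointly over their synonymous
families; this is a superset of single-codon substitution and is what
makes the bound *replicate stop count ≤ |possible stop positions|* exact.
Twenty replicates with counter-based seeds (master seed + index) are the
default study size.

Replicate metrics on the human gene are computed by the acceptance
script (`scripts/acceptance.R`); note that the NC_001807 sequence
distributed today is revision .4, whose gau frame carries 12 stops (10
AGR + 2 TAA/TAG) and 17 possible stop positions — analyses published
against earlier revisions of the accession report slightly higher stop
censuses, and the shuffle means shift accordingly by a point or two.

## Comparative contrasts

Each monophyletic group contributes one contrast: mean gau AGR count of
taxa predicted to possess an antitermination AGR tRNA minus the mean of
matched taxa without it. If the tRNA enables translation of AGR-bearing
frames, contrasts should be predominantly positive, and gain-scenario
contrasts should grow with time since the gain.

- `signTest` is the exact one-sided binomial tail
  $P(X \ge k \mid n, 1/2)$ over nonzero contrasts, accumulated by a
  Pascal-row integer recurrence (exact below $2^{53}$) rather than a
  floating density; zeros are dropped and counted. Published one-tailed
  p-values for such tests sometimes disagree with the exact tail (e.g.
  9 of 13 positive has exact tail 1093/8192 ≈ 0.133); this package
  reports the exact tail and makes no attempt to reproduce any other
  variant.
- `spearmanRho` uses midranks, and for $n \le 8$ computes the p-value by
  exhaustive permutation (ties handled naturally); larger $n$ falls back
  to the t approximation. Gains are tested one-sided (positive), losses
  two-sided, matching the asymmetric prediction.
- `fitchGainLoss` is a hand-written two-pass Fitch reconstruction used
  only to label scenarios when they are not supplied; ambiguous final
  states resolve to the parent state and an ambiguous root to absence,
  making the labelling deterministic. tRNA presence itself is always an
  input column — the package does not predict tRNAs.
- Divergence times are user-supplied per contrast; no dating is done.

## Genome scan

`scanRecord` anchors each record at GSPPP (searching all six frames,
minus frames preferred) and reads three 100-codon windows: (i) upstream
of the glycine, (ii) from the glycine — the gau sequence, whose window
positions 1–100 are region residues 2–101 — and (iii) the next 100
codons. Window i records the *last* stop position (how close to the gau
start the upstream frame stays open), windows ii and iii the *first*.
Positions bin into deciles (`ceiling(p/10) * 10`, read as the bin's
upper bound); `aggregateScan` tabulates deciles and stop-free counts per
phylum and window. Records whose windows run off the sequence are
flagged uncovered and excluded from that window's tallies.

## Synthetic data: what it emulates, what it does not

The generators plant exactly the features the analyses recover, so every
pipeline stage is testable without downloads, and their defaults are the
study conditions used throughout the tests:

- `makeOverlapCds`: a sense CDS (default 25 codons of flank either side)
  whose −2 frame holds a 101-codon region with GSPPP at residues 2–6, a
  chosen start codon at residue 1, planted stops, a planted AGR count,
  and TAA at residue 101; the sense frame is stop-free to its terminal
  stop, and the anchor is unique across the six frames. Generation
  defaults to the invertebrate mt code, under which AGR codons are
  serine, so planted stop and AGR counts stay independent; under an
  AGR-as-stop code the AGR positions read as additional stops, which is
  itself a tested invariant. Background codons are drawn uniformly from
  the non-stop, non-AGR pool to avoid biasing the shuffle tests.
- `makeDivergentPair`: a fixed number of positions (outside the 15-nt
  anchor span) mutated to hit a target identity within ±1%.
- `makeContrastDataset`: 13 groups (7 gains, 6 losses), baseline AGR
  count $\mu = 12$ with $\sigma = 2$ — non-negative integer counts on
  the scale observed in primate gau frames (8–17) — true effect
  $\delta = 1$, divergence times uniform on 1–60 My. At $\sigma = 0$
  every contrast equals $\delta$ exactly, which the truth-recovery
  tests rely on.
- `makeGenomeSet`: genomes embedding a 300-codon anchored frame with
  Poisson(2) stops per window at known positions, plus a configurable
  anchor-free fraction.

What the generators deliberately do not emulate: realistic mitochondrial
genome architecture (tRNA genes, control regions), phylogenetic
correlation among sequences (each genome is independent), substitution-
model evolution (divergent pairs are i.i.d. point mutations), or codon
usage bias in the background. Passing tests therefore demonstrate that
the machinery recovers planted truth and obeys its invariants — not that
real mitochondrial data will show any particular effect size.

## Numerical choices and degenerate inputs

- All generators and the shuffle take explicit seeds; replicate seeds are
  counter-based (master + index) and logged in the replicate table.
  Generator internals restore the caller's RNG state.
- Exact tests are exact: sign-test binomials by integer recurrence,
  Spearman by full permutation at small $n$ (with a $10^{-12}$ tolerance
  when comparing permutation statistics to the observed one).
- Degenerate cases are flagged, not silently computed: all-zero contrast
  vectors, constant Spearman inputs, zero-variance paired differences.
- Alignment tie-breaking is delegated to `pairwiseAlignment`, which is
  deterministic; scores (not paths) are what the tables consume.
- Problem sizes in the test suite — 20-codon to 200-codon synthetic CDS,
  $10^5$-draw convergence checks, 1000-replicate preservation sweeps,
  trees to 8 tips against exhaustive labelings — were chosen so the
  whole suite exercises every exact oracle comfortably on one CPU.

## Known limitations

- The package reads pre-extracted sequences; it does not fetch
  accessions, parse GenBank feature tables, or re-annotate mtDNA.
- dN/dS site-model fitting, secondary-structure and targeting
  prediction, and database (BLAST/EST) evidence are out of scope.
- The comparative analysis takes tRNA presence and divergence times as
  inputs; it neither predicts antisense tRNAs nor dates nodes.
- Conservation percentages depend on alignment parameters and gap
  conventions; both are configurable and documented, but reproducing a
  table computed with an unknown aligner may require supplying that
  alignment via `pairAlignmentFromAligned`.
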