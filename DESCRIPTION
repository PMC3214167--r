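Package: gauscan
Title: Locating and Testing the Conserved Antisense ORF (gau) of cox1
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of 'gau', the positionally
    conserved open reading frame on the complementary strand of the
    cytochrome c oxidase subunit I (cox1) gene. Provides frame-aware
    translation under NCBI genetic-code tables and the sense/antisense
    (-2 frame) codon geometry; a GSPPP-anchored locator for the 101-codon
    gau region with stop and AGR codon catalogues, Kyte-Doolittle
    hydropathy and charge-domain profiles; pairwise six-frame conservation
    tables and per-column amino-acid family profiles; a sense-protein-
    preserving synonymous-codon shuffle null model with replicate metrics,
    exhaustive stop-site enumeration and paired t summaries;
    phylogenetically independent contrasts of AGR codon counts against
    antitermination-tRNA presence with exact sign tests, Spearman rank
    correlations and Fitch parsimony labelling; a GSPPP-anchored
    three-window stop-codon genome scan; and deterministic synthetic-data
    generators that plant every feature the analyses recover.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
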