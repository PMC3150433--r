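Package: degenkit
Title: Codon Degeneracy Recoding and Signal Dissection for Protein-Coding
    Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting synonymous and nonsynonymous signal in
    concatenated in-frame protein-coding nucleotide alignments. Implements
    degen1 codon degeneration (collapsing each codon to its maximally
    degenerate IUPAC representation so that only nonsynonymous differences
    remain informative), fourfold-synonymous third-position masking,
    construction of codon-position and leucine/arginine character sets
    (nt1/nt2/nt3, LRall1, noLRall1nt2, LRall1nt3), rate-ranked gene binning,
    seeded column shuffling and complementary fractional subsampling,
    bipartition-level bootstrap support and conflict accounting against a
    reference topology, a per-gene phylogenetic-utility statistic,
    per-taxon base-composition heterogeneity analysis with Euclidean
    distance dendrograms, shared-indel screening, and a synthetic codon
    alignment generator for validating the whole pipeline. Reads and writes
    NEXUS (with CHARSET/EXSET metadata), FASTA and relaxed PHYLIP.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
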