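Package: kmersplits
Title: Alignment-Free Phylogenetic Splits from k-mer Presence/Absence Patterns
Version: 1.0.0
Authors@R:
    person("kmersplits", "developers", email = "kmersplits@example.org",
           role = c("aut", "cre"))
Description: Estimates phylogenetic split systems directly from whole-genome
    sequence data, without alignments or pairwise distance computations.
    Canonical k-mers are extracted from FASTA/FASTQ input (IUPAC ambiguity
    codes are expanded to all compatible DNA words), their presence/absence
    patterns across the input genomes are aggregated into weighted splits
    (geometric-mean weights, by default with pseudocounts), and the resulting
    split system can be filtered (top-x, greedy tree, two greedy trees,
    greedy weakly compatible) and exported as a tab-separated split table, a
    NEXUS splits block for split-network visualization, or a Newick tree when
    the selected splits are pairwise compatible. Includes a sequence
    simulator with known ground-truth trees and precision/recall evaluation
    of called splits against a reference tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
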