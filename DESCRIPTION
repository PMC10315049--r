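Package: mitocomp
Title: Comparative Analysis of Closely Related Plant Mitochondrial Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing mitogenome size variation among closely
    related plant species into its sources: chloroplast-to-mitochondrion
    intracellular DNA transfer (IDT), intragenomic duplication, sequence gain
    and loss, putative horizontal transfer and nuclear-homologous sequence.
    Includes pairwise genome comparison (blastn-backed local search, anchor
    chaining into collinear blocks, inversion detection, non-alignable region
    extraction), a per-base origin classifier with a per-pair accounting
    table, dispersed-repeat census and long-read repeat-mediated
    recombination assays, substitution and indel tabulation with Kimura
    two-parameter and modified Nei-Gojobori (Ks/Ka) distances, three-taxon
    substitution polarisation and calibrated molecular-clock dating,
    detection of recurrent IDT as a chimeric breakpoint with
    neighbor-joining partition trees and a population fixation survey, and a
    fully ledgered three-lineage organelle genome simulator providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: blastn (NCBI BLAST+), mafft
Config/testthat/edition: 3
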