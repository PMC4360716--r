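Package: viroclade
Title: Clade Delineation, Host Prediction and Evolutionary Analysis of
    Uncultivated Phage Contigs from Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise uncultivated phage populations from
    assembled virome contigs: marker-gene (major capsid protein) screening
    with domain-coverage rules, distance-based phylogenies with bootstrap
    support and clade delineation, gene-content sharing matrices and their
    concordance with marker trees via a Robinson-Foulds leaf-permutation
    test, metagenomic read recruitment with presence calls and windowed
    coverage profiles, composition-based host prediction from
    tetranucleotide frequency signatures with calibrated distance tiers,
    CRISPR-spacer matching, and a Nei-Gojobori counting estimator of
    dN/dS.  A fully deterministic synthetic-data generator produces
    clade-structured phage genomes, host-ameliorated composition, reads
    and spacers with known truth so the whole pipeline can be exercised
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: mafft (for progressive multiple alignment)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
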