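Package: phylopi
Title: Phylogenetic Informativeness Profiling for Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles the phylogenetic informativeness of candidate loci for
    phylogenetic study design. Per-site substitution rates are estimated by
    maximum likelihood on a user-supplied ultrametric tree (Felsenstein pruning
    under JC69, K80, HKY85, GTR or a 20-state Poisson model), converted to
    informativeness profiles over time, integrated in closed form over epochs
    of interest, and used to rank loci. Reads DNA and amino-acid alignments in
    FASTA, Phylip and NEXUS formats (with charset partitions) and trees in
    Newick or NEXUS; writes rate-vector tables, profile spreadsheets, epoch
    rankings and publication-quality SVG figures that align the chronogram
    with the profiles on a shared time axis. Includes a sequence simulator for
    validating rate recovery and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
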