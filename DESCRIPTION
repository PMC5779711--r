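Package: clonesim
Title: In Silico Molecular Cloning and Recombineering Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of molecular-cloning workflows. DNA
    molecules are modelled as double-stranded sequences with explicit
    topology and typed ends (overhang polarity and sequence,
    5'-phosphorylation, hairpins), and every wet-lab operation --
    restriction and CRISPR digestion, end modification, ligation,
    site-specific and homologous recombination (including lambda Red,
    Gibson/SLIC-style assembly), PCR by single-strand annealing, gel
    separation, feature and PCR screening, transformation and
    incubation in simulated hosts -- is a node in a recalculable
    workflow graph. Product sets are enumerated exhaustively, including
    intermediates and by-products, so a cloning strategy can be
    validated before any bench work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cli,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
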