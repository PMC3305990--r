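Package: crnrealize
Title: Dense, Sparse and Core Realizations of Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether the structure of a mass-action chemical reaction
    network is uniquely determined by its dynamics. Implements the
    linear-programming sweep for the dense realization (the unique
    super-structure containing every dynamically equivalent reaction graph
    over a fixed complex set), a mixed-integer search for sparse realizations
    with the minimal number of reactions, enumeration of all minimal
    structures, the per-reaction feasibility test for core reactions that
    must appear in every equivalent realization, and constrained variants of
    all of these under reaction-exclusion constraint sets. Also ships a
    Monte Carlo tester for the reachability-based structural
    identifiability of sparse linear gene-network models, programmatic
    constructors for four literature example systems, a plain-text network
    exchange format, DOT graph export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
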