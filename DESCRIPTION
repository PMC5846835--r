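Package: codonmd
Title: Genetic Code Optimization of Codon-Level Nucleic Acid Dynamics
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the impact of single-base codon substitutions on
    nucleic acid dynamics and asks whether the canonical genetic code is
    unusually organized with respect to those impacts.  Per-codon molecular
    dynamics summary profiles (backbone atomic fluctuations and atomic
    correlation matrices over a 5-nucleotide mask) yield per-transition
    impact scores (dFLUX, dCORR); a dinucleotide BII-occupancy flexibility
    scale yields a purely sequence-based impact (dTRX).  Category totals
    (synonymous/nonsynonymous and their strand-symmetric refinements) under
    the canonical code are compared against the exhaustive ensemble of
    13,823 degeneracy-preserving alternative codes obtained by permuting
    base labels independently at each codon position, and empirical ECDF
    p-values are reported.  A seeded synthetic profile generator stands in
    for GPU molecular dynamics runs so the full pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Collate: 
    'codonmd-package.R'
    'code_tables.R'
    'alt_codes.R'
    'impact_metrics.R'
    'md_io.R'
    'optimization_test.R'
    'synthetic_data.R'
    'trx_flex.R'
    'report_cli.R'
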