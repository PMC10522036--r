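Package: rvensemble
Title: Rare-Variant Aggregation Tests and Min-P Bonferroni Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workbench for region-based rare-variant association testing in
    case-control studies. Implements a registry of burden, variance-component
    and omnibus aggregation tests (CAST, CMC, weighted burden score,
    Madsen-Browning weighted sum, SSU/SSUw, C-alpha, SKAT, SKAT-O and
    moment-adjusted small-sample variants), numerical p-values for quadratic
    forms in Gaussian variables (Imhof/Davies inversion with a Liu
    moment-matched fallback), a min-p Bonferroni ensemble combiner with three
    data-driven ensemble-construction algorithms, and a full simulation
    framework (site-frequency-spectrum haplotype pools, logistic case-control
    phenotype models, type-I-error and empirical-power experiment grids) for
    building and validating ensembles. Application mode reads genotypes from
    VCF and phenotypes from delimited tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
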