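Package: cfdecon
Title: Fragment-Level Methylation Deconvolution of Cell-Free DNA and
    Detectability Limits for Rare Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for asking whether DNA released
    by a rare dying cell type (such as spinal motor neurons) is detectable in
    plasma cell-free DNA by whole genome bisulfite sequencing. Provides a
    synthetic fragment-level methylome generator (PAT dialect), greedy
    segmentation of the CpG universe into co-methylated blocks, selection and
    ranking of cell-type-specific hypomethylated marker blocks, fragment-level
    U/X/M classification with non-negative least-squares deconvolution of
    cfDNA mixtures, a spike-in grid harness measuring detection probability,
    AUC and recovery linearity, and a closed-form steady-state pharmacokinetic
    bound on the achievable cfDNA fraction together with its inverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
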