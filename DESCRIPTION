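Package: pcrbias
Title: Compositional Modelling of Amplification Bias in Multi-Template PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models multi-template PCR as a deterministic amplification
    process with template-specific efficiencies and analyses the resulting
    distortion of community composition in the isometric log-ratio (ILR)
    space defined by a phylogeny of the templates. Balances of amplicon
    counts evolve linearly in cycle number; a hierarchical Bayesian model
    (fitted with a built-in No-U-Turn sampler) estimates per-template
    amplification efficiencies, the efficiency-biased initial profile and
    per-balance noise from replicated multi-cycle amplicon libraries. The
    package also reconstructs the community at arbitrary cycles, generates
    fully specified synthetic calibration experiments with ground truth,
    and tests putative drivers of efficiency differences (Mantel test on
    edit distances, robust regression on GC content and secondary-structure
    free energy).
License: MIT
Encoding: UTF-8
Imports:
    ape,
    coda,
    jsonlite,
    MASS,
    stats,
    utils,
    vegan
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
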