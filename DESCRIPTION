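Package: glkin
Title: Kinship and Fraternity Coefficients from Low-Depth Genotype Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Method-of-moments estimation of pairwise kinship and fraternity
    (IBD2) coefficients directly from the genotype likelihoods of low-depth
    whole-genome sequencing data, without hard genotype calls. Additive and
    dominance genetic relationship matrices are built from genotype
    probability triplets standardized by sample genotype frequencies, and the
    depth-dependent downward bias of the raw moment estimates is corrected by
    extrapolating per-pair regressions of point-wise estimates on genotype
    "fuzziness" (the per-genotype variance of the likelihood triplet) to zero
    fuzziness. Includes a pedigree gene-dropping simulator with Haldane
    recombination and a Poisson read model that emits genotype likelihoods
    with known identity-by-descent ground truth, plus VCF (GL/PL) input and
    output.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    vcfR,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
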