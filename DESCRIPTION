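Package: stabarch
Title: Genetic Architecture of Complex Traits Under Pleiotropic Stabilizing Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative model and inference machinery for the genetic
    architecture of highly polygenic quantitative traits shaped by
    pleiotropic stabilizing selection. Computes allele-frequency
    distributions under underdominant selection and piecewise-constant
    demography with a Wright-Fisher diffusion solver, fits the
    distribution of selection coefficients f(s) together with the
    heritability per site (h2/L) and mutational target size (L) by
    ascertainment-corrected maximum likelihood on genome-wide significant
    GWAS hits, and provides model criticism through residual p-values,
    block cross-validation and alpha-model baselines, model-predicted
    allele ages from trajectory simulation, synthetic GWAS-hit
    generation, and scaling-law collapse analyses of hit architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
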