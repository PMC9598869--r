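Package: stochsim
Title: Random-Sampling Effects on Stochasticity Inference in Microbial
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation pipeline for quantifying how the random-sampling
    (undersampling) step inherent to microbial community profiling inflates
    Bray-Curtis beta-diversity and biases null-model inference of community
    assembly stochasticity.  Generates lognormal seed communities at
    realistic environmental scale (10^4 taxa, 10^8 organisms), perturbs
    them to mimic drift and dispersal limitation, rarefies them to typical
    sequencing depths, and contrasts the stochastic ratio and the
    abundance-based Raup-Crick metric between full-scale and undersampled
    profiles, for whole communities and for abundant/rare subcommunities,
    under two null-model randomization schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
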