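Package: ncii
Title: Quantitative Genetics for Full-Factorial (North Carolina II) Breeding Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of full-factorial (North Carolina II)
    breeding experiments with crossed sire, dam and sire-by-dam random
    effects, motivated by quantitative-genetic studies of salmonid embryos
    under pollutant-stress environments. Provides a restricted
    maximum-likelihood (REML) engine for Gaussian linear mixed models with
    crossed variance components, a Laplace-approximation logistic mixed
    model for rare binary outcomes, likelihood-ratio tests with boundary
    corrections, single-step multiplicity-adjusted pairwise treatment
    contrasts, variance decomposition into additive, maternal and dominance
    components with narrow-sense heritability, a blocked Gibbs sampler with
    inverse-gamma priors yielding highest-posterior-density intervals,
    posterior modes, DIC and Heidelberger-Welch convergence diagnostics,
    genotype-by-environment reaction-norm tests, cross-environment genetic
    correlations from paternal sibgroup means, and a reproducible
    end-to-end analysis pipeline with a matching synthetic-data generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
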