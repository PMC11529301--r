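Package: catrer
Title: Association of Relative Evolutionary Rates with Categorical Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association of per-branch relative evolutionary
    rates (RERs) with non-ordinal categorical traits on a phylogeny.
    Implements maximum-likelihood ancestral state reconstruction under a
    continuous-time Markov model with ER/SYM/ARD and custom rate models,
    likelihood-ratio model selection, per-gene Kruskal-Wallis/Dunn and
    ANOVA/Tukey association tests with epsilon-squared and eta-squared
    effect sizes, phylogeny-aware permutation ("permulation") null
    phenotypes for categorical traits with an optional relaxed rejection
    criterion, rank-based pathway enrichment with fold-enrichment curves
    and permulation-corrected p-values, an amino-acid site screen for
    category-specific composition, and a synthetic-data generator with
    planted rate shifts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
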