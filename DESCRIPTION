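Package: traitspace
Title: Social-Affective Personality Space, Face Trait Judgments, and
    Neuronal Representational Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline linking a
    four-dimensional social-affective personality space to social trait
    judgments of faces and to single-neuron representational geometry,
    with matched autism-spectrum-like and control groups. Provides a
    synthetic-cohort generator with planted ground truth (factor
    loadings, judgment couplings, neuronal tuning), behavioral and
    neuronal quality-control filters, maximum-likelihood exploratory
    factor analysis with oblimin rotation and a Cattell-Nelson-Gorsuch
    factor-count rule, group comparisons of factor scores and trait
    judgments, identity-level representational similarity analysis
    against neuronal population responses with a group permutation
    test, and inter-subject (dyadic) representational similarity
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
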