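Package: gamebattery
Title: Serious-Game Assessment Battery for Childhood ADHD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-driven scoring engines for a six mini-game computer-based
    assessment battery probing executive functions (planning, visual working
    memory, response inhibition, simple reaction time), delay aversion, and
    time production in children aged 4-8 years; a calibrated generative model
    of control and ADHD child responders grounded in the triple-pathway model
    of ADHD that emits raw event logs; and the clinical validation statistics
    chain: within-group outlier winsorization, Pearson/Spearman age-correlation
    battery, two-group linear discriminant analysis with Wilks' lambda,
    Bartlett chi-square, structure matrix and resubstitution classification
    metrics, and univariate group tests (general linear model F, Mann-Whitney
    U, Pearson chi-square, independent-samples t) with their effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
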