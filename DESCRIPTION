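Package: rangeplan
Title: Range Model of Planning in Music Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the range model of incremental planning in music
    performance: serial-proximity and metrical-similarity activation of
    sequence events, predicted movement gradients of serial-ordering
    errors, and the analysis pipeline around it. Includes construction
    of binary metrical accent grids, score-to-performance alignment and
    pitch-error coding (contextual and noncontextual errors, exchanges,
    chord errors, exclusion filters), movement-gradient and
    range-of-planning summaries, accent-conditioned error rates and
    keystroke-intensity summaries, two-step model fitting (memory
    parameter and tactus weight) with variance-accounted-for and AIC
    model comparison, Monte-Carlo chance simulations, and a synthetic
    performance generator that emulates the two-context, two-tempo
    keyboard production design so every stage is testable by parameter
    recovery without participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
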