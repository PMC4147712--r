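Package: spacedrecall
Title: Adaptive Spaced-Retrieval Memory Training: Simulation and Usability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for adaptive spaced-retrieval memory
    training protocols of the kind used in cognitive rehabilitation for
    early-stage dementia. Implements a two-phase session engine (a staircase
    assessment phase that calibrates a participant's recall span, followed
    by an expanding-interval training phase), quiz item banks for text- and
    graphic-modality tasks, simulated participants whose recall probability
    follows an exponential forgetting curve with a guessing floor, the
    standard usability measures (response time, elapsed time per question,
    first-attempt correct score, post-task satisfaction, and weighted
    NASA-TLX workload), and a study-analysis layer with descriptive
    statistics, one-way ANOVA, and all-pairs Pearson correlations for
    small-sample two-task usability experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
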