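Package: tbrsi
Title: Simulating Working Memory in Complex Span Tasks with Decay and Interference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator of working memory performance in complex
    span tasks under the time-based resource-sharing framework, extended with
    interference between distractors and the distributed representations of
    memoranda (the TBRS*-I model). Items are bound to overlapping positional
    contexts by associative weights that decay exponentially with time and are
    reactivated by attentional refreshing during free time; distractors distort
    item representations by value averaging on shared feature units, and
    refreshing restores them toward their long-term memory engrams. Provides
    generators for stimulus lexicons with controlled memoranda-distractor
    overlap and distance, single-trial simulation with full event logging, a
    compiled engine for large factorial simulation grids over task and stimulus
    factors, span scoring, tidy aggregation, and plotting of benchmark effects
    such as the cognitive load effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
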