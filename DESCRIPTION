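Package: dietmap
Title: Mapping Detailed Food-Diary Records onto Short Food Questionnaire Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map the food codes of a detailed weighed food diary onto
    the food groups of a short food questionnaire (SFQ), build an augmented
    consumption database carrying per-food coverage verdicts, and quantify the
    fraction of habitual consumption (frequency and amount) the questionnaire
    fails to capture. Provides a stepwise matching algorithm (exact name and
    description matching, normalised-Levenshtein fuzzy matching, token search
    with include/exclude keywords), per-subject-day coverage ratios,
    boundary-corrected density estimates of those ratios, exact and permutation
    Wilcoxon rank-sum tests across days of the week, and a seeded synthetic-data
    generator with known ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
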