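Package: ifmcdm
Title: Intuitionistic Fuzzy Multi-Criteria Decision Analysis with AHP,
    DEMATEL and CoCoSo
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for hybrid multi-criteria decision analysis
    under intuitionistic fuzzy uncertainty, aimed at healthcare performance
    evaluation. Expert panels rate decision elements on linguistic scales
    encoded as intuitionistic fuzzy numbers (membership, non-membership,
    hesitancy); the package derives criterion weights by an intuitionistic
    fuzzy analytic hierarchy process (IF-AHP) with expert-importance
    weighting, fuzzy-entropy priorities and Saaty consistency checking,
    maps cause-effect influence networks with an intuitionistic fuzzy
    DEMATEL (total-relation matrix, prominence/relation scores,
    significant-link thresholding), and ranks alternatives with the
    combined compromise solution (CoCoSo), including weakness reporting.
    Bundled fixtures reproduce a published three-hospital emergency
    department case study, and a synthetic panel generator supports
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
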