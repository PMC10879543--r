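Package: dyadkit
Title: Microanalysis of Caregiver-Infant Dyadic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subsecond microanalysis of caregiver-infant
    interaction sessions coded as behavioral event streams (0.2-s bins)
    with call annotations. Partitions each session into five mutually
    exclusive social contexts, extracts rejection-to-dismount intervals
    and classifies dismounts as forced or voluntary via a segmented
    log-survivorship regression, derives caregiver parenting parameters
    (retrieval latency, rejection rate, carrying rate) and infant
    attachment metrics (avoidant behaviors, context-dependent call usage),
    and runs the accompanying nonparametric statistics (exact Wilcoxon
    tests, Holm/BH-adjusted correlation matrices, Cohen's kappa, and a
    cluster-level permutation test). A generative simulator of dyadic
    sessions with latent caregiver styles supports power analysis and
    parameter-recovery testing.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
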