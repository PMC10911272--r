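Package: ribomethr
Title: RiboMeth-Seq Scoring and Differential rRNA 2'-O-Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ribose 2'-O-methylation of human ribosomal RNA from
    RiboMeth-seq fragment end-count profiles. Converts per-position fragment
    end counts into per-site methylation scores in [0,1], tests for growth-state
    specific methylation changes with a donor-blocked two-factor ANOVA,
    Benjamini-Hochberg adjustment and Tukey range post-hoc contrasts,
    embeds samples in two dimensions with optional batch-factor elimination,
    and relates site methylation to guide-snoRNA expression (stem-loop qPCR,
    northern blots) and to pre-rRNA processing ratios. Includes a
    ground-truthed synthetic-data generator emulating alkaline-hydrolysis
    sequencing with Poisson counting noise, donor batch effects and planted
    state effects, plus an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
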