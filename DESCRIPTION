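Package: ploidyscreen
Title: Expression-Dosage Aneuploidy Screening and Transcriptomic Shift for
    Diploid-Triploid RNA-Seq Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting whole-chromosome aneuploidy from bulk
    RNA-seq expression data in mixed-ploidy designs, motivated by triploid
    oyster aquaculture. Provides counts-per-million normalization and
    low-expression filtering, construction of covariate-matched
    diploid/triploid sample pairs, per-chromosome log-CPM regression slopes
    and robust median dosage-ratio statistics with outlier-based aneuploidy
    calls, a variance-weighted principal-component distance between matched
    samples (transcriptomic shift), and a negative-binomial count simulator
    that emulates the multi-site, multi-cohort crossing design with planted
    chromosome copy-number events for power analysis and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
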