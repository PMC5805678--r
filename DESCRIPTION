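Package: epidermeth
Title: Methylome Landscape and Subtype Analysis for Epidermal Lesion Cohorts
Version: 0.1.0
Authors@R:
    person("Epidermeth", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for Infinium-style DNA methylation (beta value)
    data from healthy epidermis, actinic keratosis (AK) and cutaneous squamous
    cell carcinoma (cSCC) cohorts. Implements probe-level quality filtering,
    empirical-Bayes moderated differential methylation with Benjamini-Hochberg
    correction, cancer-methylome landscape statistics (CpG island/shore/shelf/
    open-sea shifts, lamina-associated-domain hypomethylation, non-CpG
    methylation), methylation-age prediction with a pluggable clock,
    keratin-gene and enhancer-based two-subclass calling against reference
    methylomes, and a confidence-score filter for annotated whole-exome
    variant tables. Ships a synthetic-data generator that emulates the
    statistical structure of such cohorts so the entire pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
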