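Package: posenrich
Title: 13C-Positional Enrichment Analysis for GC-MS TMS Derivatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 13C-positional enrichments of amino and organic acids
    from GC-EI-MS measurements of their trimethylsilyl (TMS) derivatives.
    Provides a curated registry of mass fragments with known carbon
    backbones, correction of raw isotopic-cluster areas for naturally
    occurring isotopes of non-backbone elements (and optionally for
    backbone natural 13C abundance and tracer isotopic purity), calculation
    of positional enrichments by linear combination of fragment mean
    enrichments, a validation framework based on binomial 13C-PT reference
    standards, a forward simulator of labeled GC-MS spectra, and an
    end-to-end batch pipeline with light/dark group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
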