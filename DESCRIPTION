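Package: bloomtrack
Title: Inference of Bloom-Responding Prokaryotes and Their Viruses from
    Microcosm Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links phytoplankton-lysate treatments in seawater microcosms to
    treatment-specific prokaryotes and prokaryotic viruses. Calibrates
    amplicon sequence variant (ASV) and viral OTU (vOTU) read abundances to
    absolute scales (cells/mL, particles/mL) using flow-cytometry totals and
    a virus-read-fraction correction, screens for abundant taxa by rank and
    fold-change rules, tests class/subclass differential enrichment with a
    Kruskal-Wallis plus bootstrapped linear-discriminant effect-size
    procedure, detects burst-size-thresholded viral increases, and predicts
    host-virus pairs by taxonomy-guided co-occurrence (Spearman correlation
    with permutation p-values and Benjamini-Hochberg correction) on an
    environmental time series. Ships a synthetic microcosm generator with
    known ground truth so every inference stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
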