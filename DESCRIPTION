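Package: screenpop
Title: Population-Dynamics Modelling of Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene-knockout fitness effects from pooled CRISPR screen
    readcounts with an explicit two-population cell-growth model and a
    negative-binomial (NB2) count likelihood. Includes reads-per-million
    normalization, plasmid-DNA batch handling, log-fold-change computation,
    clonal-outgrowth masking, staged first-order fitting of gene effects and
    guide/line knockout efficacies, post-hoc copy-number bias correction via a
    two-dimensional cubic spline, control-based normalization, screen quality
    metrics (NNMD, unexpressed false-positive rate, precision-recall of
    essential genes), and a generative screen simulator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
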