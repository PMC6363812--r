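Package: flowploidy
Title: Genome Size and Endopolyploidy Estimation from Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deconvolves propidium-iodide flow-cytometry event data into
    endopolyploidy (Cx) clusters, estimates genome size (C-value) against a
    co-analysed internal reference standard, and reproduces the summary
    statistics commonly reported in insect genome-size surveys: one-sample
    t-tests of adjacent-cluster fluorescence ratios against the expected 2.0,
    chi-square comparison of ploidy-class composition, one-way ANOVA with
    Fisher's LSD compact letter display (including summary-statistic
    reconstructions), and pooled two-sample t-tests. A synthetic listmode
    event generator emulates the endopolyploidy phenotypes of Helicoverpa
    larval tissues and the Drosophila melanogaster adult-head reference, so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
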