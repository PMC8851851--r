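Package: contactnorm
Title: Contact-Normalization Transcriptome Classification from Layered Cocultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes by how coculture contact with nontransformed
    cells reverses the transcriptional effects of oncogenic Src, using the
    four-group layered-culture design (normal-self, transformed-self,
    transformed-over-normal, transformed-over-cadherin-knockout). Converts
    counts to transcripts per million (TPM), applies an expression filter,
    and runs a three-stage fold-change/t-test cascade (Src effect, contact
    reversal, cadherin dependence) yielding nested "onion-layer" gene
    classes. Includes a negative-binomial simulator with planted gene
    classes for recovery benchmarking, cellular-location and interaction-
    network summaries of classified genes, and percent-of-control
    statistics for growth and densitometry assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
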