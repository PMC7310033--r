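Package: plastdiv
Title: Comparative Plastome Divergence Analysis and Barcode Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular chloroplast genomes
    (plastomes): detection and canonical orientation of the quadripartite
    LSC/IRa/SSC/IRb structure with inverted-repeat junction reports;
    nucleotide-diversity, site-classification and haplotype statistics on
    multiple alignments with sliding-window divergence-hotspot discovery;
    pairwise Ka/Ks selection screening with NG86 and YN00 estimators;
    microsatellite (SSR) and long-sequence-repeat (LSR) annotation with
    cross-genome polymorphism classification; and hotspot-to-barcode marker
    development with IUPAC consensus primer design, in-silico PCR under
    explicit stringency rules, and exact-match discriminatory-power scoring.
    Includes a fully seeded synthetic plastome clade simulator with known
    truth so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
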