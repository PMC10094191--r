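Package: codonbias
Title: Codon Usage Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of synonymous codon usage bias in coding
    sequences. Computes relative synonymous codon usage (RSCU), Wright's
    effective number of codons (ENc), synonymous third-position base
    composition under the codonW convention (U3s/C3s/A3s/G3s/GC3s), the
    codon adaptation index (CAI), codon bias index (CBI), frequency of
    optimal codons (Fop), GRAVY and aromaticity; screens preferred codons
    by the delta-RSCU contrast and intersects them with high-frequency
    codons to determine optimal codons; runs correspondence analysis and
    hierarchical clustering of RSCU profiles with Pearson correlation
    panels; and builds neighbor-joining trees from Poisson-corrected
    amino-acid distances with bootstrap supports. Includes a synthetic
    coding-sequence generator with controlled GC3 bias and group
    structure, and packaged codon-count and index fixtures from a study
    of plant xyloglucan endotransglycosylase (XET) genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    MASS,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
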