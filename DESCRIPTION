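Package: phagetx
Title: Inferring Bacteriophage Transcription Strategies from Genome Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers the transcription strategy of a lytic bacteriophage
    directly from its genome sequence and gene annotations. Extracts and
    orients upstream intergenic regions; discovers low-copy, well-conserved
    phage-sigma-factor promoters by pairwise local alignment of intergenic
    regions with a word-Poisson significance estimate; tracks additional
    promoter copies with a supervised core-motif scan scored by an exact
    score-tail p-value; searches for host sigma70 promoters with a composite
    position weight matrix model (-35, spacer, -10, optional -15) normalized
    so the consensus configuration scores zero, selecting a reporting
    threshold by strand positional bias; provides a Gibbs site-sampler
    baseline with a restart-robustness score; and integrates the promoter
    predictions into early/middle/late temporal gene classes. A synthetic
    phage-genome simulator with planted promoters and full truth records
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
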