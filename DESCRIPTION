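Package: phasebin
Title: Two-Phase Binning of Metagenomic Contigs from Coverage and
    Probabilistic k-mer Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised binning of assembled metagenomic contigs into
    putative species. Each contig is represented by its mean read coverage
    across samples and by a self-standardized tetranucleotide signature:
    canonical k-mer counts are converted to z-scores under a per-contig
    binomial null model, removing composition and length bias. Long contigs
    are clustered with k-medoids on the combined profile; short contigs are
    then attached to the resulting bins by L1 distance in an unstandardized
    coverage + composition space. Includes an occupancy-based estimator of
    the number of species, precision/recall evaluation against a ground
    truth, a synthetic community generator for validation, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
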