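Package: ampedit
Title: Tiled-Amplicon Minor Variant Detection and CRISPR Edit Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting low-frequency (minor species)
    variants in tiled-amplicon deep sequencing of large dsDNA viral genomes, and
    for attributing them to CRISPR-Cas9 editing. Includes a deterministic
    synthetic-data generator (reference genome with planted protospacers and
    AT-rich homologous-repeat arrays, two-pool tiled primer scheme, paired-end
    reads with spiked indel haplotypes), banded affine-gap read alignment with
    indel left-normalization, primer clipping and alignment filtering, a
    quality-aware pileup and variant caller with a Fisher's exact test error
    model, technical-replicate concordance filtering, guide-RNA edit-window
    prediction and off-target scanning, and cross-passage variant conservation
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
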