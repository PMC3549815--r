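Package: kcorrect
Title: Quality-Aware k-mer Spectrum Error Correction for Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects substitution errors in short sequencing reads with
    highly non-uniform coverage, as produced by single-cell multiple
    displacement amplification (MDA). Reads are decomposed into k-mers with
    per-position error probabilities aggregated from Phred qualities;
    k-mers are clustered into connected components of a Hamming graph
    without all-pairs comparison, refined by BIC-penalized m-means
    subclustering under a quality-weighted likelihood, and a set of solid
    (trusted) k-mers is selected by cluster quality and expanded over fully
    covered reads. Reads are then corrected by consensus voting of solid
    k-mers and solid cluster centers. Includes a ground-truthed synthetic
    read simulator with lognormal amplification bias for end-to-end
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
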