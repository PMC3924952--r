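Package: fragal
Title: Fragmented Pairwise Alignment for Weakly Conserved Protein Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects weakly conserved functional segments (such as BRC
    repeats, phosphorylation sites and HAT motifs) shared by two protein
    sequences. Both sequences are sliced into overlapping fixed-length
    fragments, every fragment pair is globally aligned under a high
    gap-opening penalty, and each pair is scored with a weighted
    identity/similarity score (FRscore). Passing matches are ranked by best
    average score or stitched into collinear non-overlapping chains ranked
    by cumulative score, and can be filtered against a feature annotation
    track of the target. Includes shuffle-based significance z-scores with a
    Smith-Waterman local aligner, a planted-motif synthetic benchmark
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
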