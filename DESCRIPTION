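Package: repdetect
Title: Self-Training De Novo Repeat Detection and Masking for Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects repetitive elements in assembled or unassembled genomes
    without a repeat library. Every genomic position is scored by the
    background-adjusted genome-wide count of the k-mer starting there, where
    the background is a Markov chain trained on the same genome. Candidate
    repetitive regions are auto-labeled by Gaussian smoothing of the score
    track followed by a second-derivative peak test, a two-track hidden
    Markov model over logarithmic score levels is trained on those labels,
    and Viterbi decoding segments the genome into repetitive and
    non-repetitive intervals. Includes soft/hard FASTA masking, BED interval
    output, masking-benchmark metrics (class-wise sensitivity, exon
    specificity, percentage predicted, false-positive length on
    Markov-simulated random genomes, potential-repeat content), and a seeded
    synthetic-genome simulator with planted interspersed and tandem repeat
    families for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
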