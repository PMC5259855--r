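Package: seedvote
Title: Seed-and-Vote Short-Read Alignment with a Modular-Prime k-mer Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A short-read aligner built on the seed-and-vote strategy. The
    reference genome is indexed by hashing fixed-length k-mers (default 31 bp)
    taken at a fixed stride (default 8 bp) into 32-bit keys via 2-bit base
    encoding and reduction modulo a large prime. Reads are mapped by letting
    every seed vote for the genome block it implies; the block with the most
    votes wins, mismatch-heavy alignments are rescued by Smith-Waterman on a
    36 bp extended window, and confidence is scored by the vote difference
    between the best and second-best blocks. Includes a wgsim-style read
    simulator with truth tracking and an accuracy-evaluation protocol
    (confident-mapping and error fractions over a mapping-quality sweep),
    plus FASTA/FASTQ input and SAM output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    withr
Config/testthat/edition: 3
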