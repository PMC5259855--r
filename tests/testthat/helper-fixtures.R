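# Shared fixture builders: tiny references with planted reads, and a
# brute-force seed-and-vote oracle that scans every block start by
# direct k-mer comparison at the indexed phases.

# reference-consumed span of a cigar string
cigar_ref_span <- function(cg) {
  ops <- regmatches(cg, gregexpr("\\d+[MIDNSX=]", cg))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# single-sequence reference with an optional planted phase:
# plant_at chooses the global 0-based start of the region later read
plant_reference <- function(len = 1200L, name = "chr1") {
  reference_set(stats::setNames(random_dna(len), name))
}

mutate_at <- function(seq, pos1, to = NULL) {
  # substitute the 1-based positions with a different base
  for (p in pos1) {
    old <- substr(seq, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), old)
    substr(seq, p, p) <- if (is.null(to)) alt[1] else to
  }
  seq
}

# Brute-force voting oracle for a single-sequence N-free reference:
# votes(b) = number of read offsets o with (b + o) divisible by the
# stride, the window inside the sequence, and an exact sl-mer match.
oracle_votes <- function(ref_seq, read, sl, w) {
  L <- nchar(ref_seq)
  n <- nchar(read)
  res <- integer(0)
  blocks <- integer(0)
  for (b in 0:(L - n)) {
    v <- 0L
    for (o in 0:(n - sl)) {
      c0 <- b + o
      if (c0 %% w != 0L) next
      if (c0 + sl > L) next
      if (substr(ref_seq, c0 + 1L, c0 + sl) ==
          substr(read, o + 1L, o + sl)) v <- v + 1L
    }
    if (v > 0L) {
      blocks <- c(blocks, b)
      res <- c(res, v)
    }
  }
  data.frame(block_start = blocks, votes = res)
}
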