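#' Alignment scoring scheme
#'
#' Affine-gap local-alignment scores used by the Smith-Waterman rescue.
#' A gap of length L costs `gap_open + L * gap_extend`.  The defaults
#' (+1/-3/-5/-2) follow common short-read practice.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open gap opening penalty (< 0).
#' @param gap_extend per-base gap extension penalty (< 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Hamming distance between a read and its block
#'
#' Position-wise mismatch count of the read against the reference block
#' `[block_start, block_start + nchar(read))`.  An N (or any non-ACGT
#' character) in the reference counts as a mismatch.
#'
#' @param read DNA string, oriented as it aligns to the forward strand.
#' @param ref a [reference_set()].
#' @param block_start global 0-based block start.
#' @return integer mismatch count.
#' @export
count_mismatches <- function(read, ref, block_start) {
  stopifnot(inherits(ref, "reference_set"))
  n <- nchar(read)
  if (block_start < 0 || block_start + n > ref$total_length)
    stop("block outside reference")
  C_count_mismatches(ref$genome, as.integer(block_start), toupper(read))
}

#' Extend a block for rescue alignment
#'
#' The rescue window is the block extended `pad` bases upstream and
#' downstream, clipped to the containing sequence (the window never
#' spans a sequence boundary).
#'
#' @param ref a [reference_set()].
#' @param block_start global 0-based block start.
#' @param read_length block length.
#' @param pad extension on each side (default 36).
#' @return integer vector `c(start, end)`: a half-open global interval.
#' @export
extend_block <- function(ref, block_start, read_length, pad = 36L) {
  stopifnot(inherits(ref, "reference_set"))
  si <- seq_index_of(ref, block_start)
  s0 <- ref$offsets[si]
  s1 <- s0 + ref$lengths[si]
  c(max(block_start - pad, s0), min(block_start + read_length + pad, s1))
}

#' Smith-Waterman local alignment
#'
#' Full dynamic-programming local alignment with affine gaps and
#' traceback.  Traceback ties resolve with fixed operator precedence
#' (diagonal, then gap in the reference consuming a read base, then gap
#' in the read), so results are deterministic.  Unaligned read ends are
#' reported as soft clips in the CIGAR.
#'
#' @param read DNA string (rows of the DP).
#' @param segment reference segment (columns).
#' @param scheme a [scoring_scheme()].
#' @return an object of class `local_alignment`: `score`, `cigar`,
#'   `read_span` and `ref_span` (0-based half-open), `edit_distance`.
#'   When no cell scores above 0, a list with `score` and `ok = FALSE`.
#' @export
smith_waterman <- function(read, segment, scheme = scoring_scheme()) {
  stopifnot(nchar(read) > 0, nchar(segment) > 0,
            inherits(scheme, "scoring_scheme"))
  r <- C_smith_waterman(toupper(read), toupper(segment), scheme$match,
                        scheme$mismatch, scheme$gap_open, scheme$gap_extend)
  if (!isTRUE(r$ok)) return(list(score = r$score, ok = FALSE))
  structure(list(score = r$score, cigar = r$cigar,
                 read_span = c(r$read_start, r$read_end),
                 ref_span = c(r$ref_start, r$ref_end),
                 edit_distance = r$edit_distance, ok = TRUE),
            class = "local_alignment")
}

#' Align a read to its selected block, rescuing heavy-mismatch cases
#'
#' With at most `max_mismatches` (default 2) position-wise mismatches
#' the ungapped alignment is kept (CIGAR `nM`).  Otherwise the block is
#' extended `pad` bases in both directions and realigned with
#' [smith_waterman()]; the reported position is then the start of the
#' local alignment's reference span, superseding the block start.  A
#' rescue with no positive-scoring alignment leaves the read unmapped.
#'
#' @param read DNA string, oriented as it aligns to the forward strand.
#' @param ref a [reference_set()].
#' @param block_start global 0-based block start.
#' @param scheme a [scoring_scheme()].
#' @param pad rescue extension (default 36).
#' @param max_mismatches ungapped-acceptance threshold (default 2).
#' @return list with `ok`, `rescued`, `pos` (global 0-based leftmost),
#'   `cigar`, `edit_distance` and `score`.
#' @export
rescue_alignment <- function(read, ref, block_start,
                             scheme = scoring_scheme(), pad = 36L,
                             max_mismatches = 2L) {
  stopifnot(inherits(ref, "reference_set"))
  n <- nchar(read)
  if (block_start < 0 || block_start + n > ref$total_length)
    stop("block outside reference")
  a <- C_align_to_block(ref$genome, ref$offsets, ref$lengths, toupper(read),
                        as.integer(block_start), scheme$match,
                        scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                        as.integer(pad), as.integer(max_mismatches))
  list(ok = a$ok, rescued = a$rescued,
       pos = if (a$ok) a$pos else NA_integer_,
       cigar = if (a$ok) a$cigar else NA_character_,
       edit_distance = if (a$ok) a$nm else NA_integer_, score = a$score)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string; characters outside A/C/G/T are reversed
#'   unchanged.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  vapply(seq, C_revcomp, character(1), USE.NAMES = FALSE)
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local_alignment: score %d, cigar %s\n", x$score, x$cigar))
  cat(sprintf("  read span [%d, %d), ref span [%d, %d), edit distance %d\n",
              x$read_span[1], x$read_span[2], x$ref_span[1], x$ref_span[2],
              x$edit_distance))
  invisible(x)
}
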