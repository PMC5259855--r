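#' Voting parameters
#'
#' Constants of the seed-and-vote stage.  A read maps only when its best
#' block gathers at least `min_votes` votes; a seed whose key retrieves
#' more than `max_occurrence` coordinates is considered unrepresentative
#' and skipped; mapping quality is `min((optimal - suboptimal) *
#' mapq_scale, mapq_cap)`, forced to 0 on ties.  With `verify_hits` on
#' (the default), a hash hit only counts when the reference k-mer at the
#' retrieved coordinate equals the seed text, which removes spurious
#' votes from distinct k-mers that collide modulo the prime.
#'
#' @param min_votes minimum votes of the winning block (default 2).
#' @param max_occurrence occurrence cap per seed (default 450).
#' @param seed_length optional fixed seed length; `NULL` uses the
#'   index's seed length.
#' @param mapq_scale vote-difference multiplier (default 6).
#' @param mapq_cap mapping-quality ceiling (default 60).
#' @param verify_hits verify hash hits against the reference text.
#' @param merge_window collapse blocks closer than this many bases into
#'   one candidate before selection (default 0 = no merging).
#' @return an object of class `vote_params`.
#' @export
vote_params <- function(min_votes = 2L, max_occurrence = 450L,
                        seed_length = NULL, mapq_scale = 6L, mapq_cap = 60L,
                        verify_hits = TRUE, merge_window = 0L) {
  stopifnot(min_votes >= 1L, max_occurrence >= 1L, mapq_scale >= 1L,
            mapq_cap >= 0L, merge_window >= 0L)
  if (!is.null(seed_length)) {
    seed_length <- as.integer(seed_length)
    if (seed_length < 16L || seed_length > 32L)
      stop("seed_length must be between 16 and 32")
  }
  structure(list(min_votes = as.integer(min_votes),
                 max_occurrence = as.integer(max_occurrence),
                 seed_length = seed_length,
                 mapq_scale = as.integer(mapq_scale),
                 mapq_cap = as.integer(mapq_cap),
                 verify_hits = isTRUE(verify_hits),
                 merge_window = as.integer(merge_window)),
            class = "vote_params")
}

#' Automatic seed-length selection
#'
#' Chooses the largest seed length `s` in 16..32 such that
#' `(read_length - s + 1)` is a multiple of the index stride, which
#' makes the maximum vote count of an exactly matching read independent
#' of its alignment phase relative to the indexed positions.  Without
#' this property a block with mismatches can out-vote a perfect-match
#' block whose first in-phase seed starts one stride later.  For 150 bp
#' reads the rule picks 31, for 125 bp reads 30.
#'
#' @param read_length read length in bases (>= 36).
#' @param stride index stride (default 8).
#' @return integer seed length.
#' @export
auto_seed_length <- function(read_length, stride = 8L) {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 36L)
    stop(structure(
      class = c("seedvote_unsupported_read_length", "error", "condition"),
      list(message = paste0("read length ", read_length,
                            " unsupported (minimum 36; reads over 100 bp ",
                            "recommended)"),
           call = NULL)))
  cand <- 16:32
  cand <- cand[(read_length - cand + 1L) %% stride == 0L]
  if (length(cand) == 0L) return(min(31L, read_length))
  max(cand)
}

#' Extract all seeds of a read
#'
#' One seed per start offset `0 .. n - sl` (unit stride).  Seeds
#' containing a non-ACGT character are omitted.  Although seeds exist at
#' every offset, only those in phase with the stride of the index can
#' retrieve coordinates -- that is the intended mechanism, not a loss.
#'
#' @param read DNA string.
#' @param sl seed length.
#' @return data.frame with columns `read_offset` (0-based), `seed`
#'   (text) and `value` (decimal-string 2-bit encoding).
#' @export
extract_seeds <- function(read, sl) {
  read <- toupper(read)
  n <- nchar(read)
  if (n < sl)
    return(data.frame(read_offset = integer(0), seed = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  off <- 0:(n - sl)
  seeds <- substring(read, off + 1L, off + sl)
  ok <- !grepl("[^ACGT]", seeds)
  off <- off[ok]; seeds <- seeds[ok]
  data.frame(read_offset = off, seed = seeds,
             value = vapply(seeds, C_encode_kmer, character(1),
                            USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Collect votes for one read orientation
#'
#' Every seed of the read is hashed and looked up in the index; each
#' surviving coordinate `c` retrieved by the seed at read offset `o`
#' adds one vote to the candidate block starting at `c - o` (a block is
#' a reference interval of read length).  Seeds whose coordinate vector
#' exceeds `max_occurrence` are skipped entirely; blocks that would
#' leave the sequence containing the hit are discarded.
#'
#' @param read DNA string (the orientation to vote with; call again on
#'   the reverse complement for the other strand).
#' @param index a [build_index()] result.
#' @param params a [vote_params()].
#' @return data.frame with columns `block_start` (global 0-based) and
#'   `votes`, ordered by `block_start`.
#' @export
collect_votes <- function(read, index, params = vote_params()) {
  stopifnot(inherits(index, "hash_index"), inherits(params, "vote_params"))
  ref <- index$ref
  t <- C_collect_votes(ref$genome, ref$offsets, ref$lengths, index$keys,
                       index$cs, index$coords, toupper(read),
                       index$params$seed_length, index$params$modulus,
                       params$max_occurrence, params$verify_hits,
                       params$merge_window)
  data.frame(block_start = t$block_start, votes = t$votes)
}

#' Select the winning block from a vote tally
#'
#' The block with the most votes wins.  A best block below `min_votes`
#' means the read cannot be mapped.  When several blocks share the
#' maximum, one is chosen uniformly at random (R's RNG) and the
#' selection is flagged as tied, which forces mapping quality 0.
#'
#' @param tally data.frame with columns `block_start` and `votes`
#'   (e.g. from [collect_votes()]), possibly merged across strands.
#' @param params a [vote_params()].
#' @return list with `status` ("mapped", "tied" or "unmapped"),
#'   `block_start`, `optimal` and `suboptimal` vote counts.
#' @export
select_block <- function(tally, params = vote_params()) {
  if (nrow(tally) == 0L)
    return(list(status = "unmapped", block_start = NA_integer_,
                optimal = 0L, suboptimal = 0L))
  opt <- max(tally$votes)
  if (opt < params$min_votes)
    return(list(status = "unmapped", block_start = NA_integer_,
                optimal = as.integer(opt), suboptimal = 0L))
  arg <- which(tally$votes == opt)
  if (length(arg) > 1L) {
    pick <- arg[sample.int(length(arg), 1L)]
    return(list(status = "tied", block_start = tally$block_start[pick],
                optimal = as.integer(opt), suboptimal = as.integer(opt)))
  }
  rest <- tally$votes[-arg]
  sub <- if (length(rest)) max(rest) else 0L
  list(status = "mapped", block_start = tally$block_start[arg],
       optimal = as.integer(opt), suboptimal = as.integer(sub))
}

#' Mapping quality from vote counts
#'
#' `mapq = min((optimal - suboptimal) * 6, 60)`; a tied selection
#' overrides the result to 0.  All values are multiples of 6 capped at
#' 60.
#'
#' @param optimal votes of the best block.
#' @param suboptimal votes of the second-best block (0 if none).
#' @param tie was the selection a random tie-break?
#' @param scale,cap scoring constants (defaults 6 and 60).
#' @return integer mapping quality (vectorized).
#' @export
mapping_quality <- function(optimal, suboptimal, tie = FALSE, scale = 6L,
                            cap = 60L) {
  if (any(optimal < suboptimal))
    stop("optimal must be >= suboptimal")
  q <- pmin((optimal - suboptimal) * scale, cap)
  as.integer(ifelse(rep_len(tie, length(q)), 0L, q))
}

#' Maximum vote count of an exactly matching read (closed form)
#'
#' For a read of length `n`, seed length `sl`, stride `w` and phase `d`
#' (the 1-based read position of the first seed in phase with the
#' indexed coordinates), the in-phase seeds start at `d, d+w, d+2w, ...`
#' with `start + sl - 1 <= n`, so an exact match gathers
#' `floor((n - sl + 1 - d)/w) + 1` votes.  With `sl` chosen by
#' [auto_seed_length()] this count is the same for every `d` in `1..w`.
#'
#' @param read_length read length `n`.
#' @param sl seed length.
#' @param w stride (default 8).
#' @param d 1-based phase in `1..w` (vectorized).
#' @return integer vote count(s), 0 when no in-phase seed fits.
#' @export
max_votes_closed_form <- function(read_length, sl, w = 8L, d = 1L) {
  stopifnot(all(d >= 1L), all(d <= w))
  v <- floor((read_length - sl + 1L - d) / w) + 1L
  as.integer(pmax(v, 0L))
}
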