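# Per-read orchestration: vote on both strands, merge the candidate
# pools, select, score, rescue, and emit SAM.

# reference-consumed length of a cigar (M/D/N/=/X)
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    ops <- regmatches(cg, gregexpr("(\\d+)([MIDNSHP=X])", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# raw batch mapping; returns a data.frame plus tied-candidate lists
map_batch <- function(index, reads, params = vote_params(),
                      scheme = scoring_scheme(), pad = 36L,
                      max_mismatches = 2L) {
  stopifnot(inherits(index, "hash_index"))
  ref <- index$ref
  sl <- if (is.null(params$seed_length)) index$params$seed_length
        else params$seed_length
  if (sl != index$params$seed_length)
    stop("requested seed length ", sl, " does not match the index (",
         index$params$seed_length, "); rebuild the index or use auto mode")
  r <- C_map_batch(ref$genome, ref$offsets, ref$lengths, index$keys,
                   index$cs, index$coords, toupper(reads), sl,
                   index$params$modulus, params$max_occurrence,
                   params$verify_hits, params$min_votes, scheme$match,
                   scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                   as.integer(pad), as.integer(max_mismatches),
                   params$mapq_scale, params$mapq_cap, params$merge_window)
  out <- data.frame(mapped = r$mapped, tie = r$tie, strand = r$strand,
                    block_start = r$block_start, pos = r$pos,
                    optimal = r$optimal, suboptimal = r$suboptimal,
                    mapq = r$mapq, cigar = r$cigar, nm = r$nm,
                    rescued = r$rescued, stringsAsFactors = FALSE)
  attr(out, "tied_blocks") <- r$tied_blocks
  attr(out, "tied_strands") <- r$tied_strands
  out
}

as_alignment_result <- function(row, ref, name) {
  mapped <- row$mapped
  if (mapped) {
    loc <- global_to_local(ref, row$pos)
    seqn <- loc$seq; pos1 <- loc$pos
  } else {
    seqn <- NA_character_; pos1 <- NA_integer_
  }
  structure(list(name = name, mapped = mapped, seq = seqn, pos = pos1,
                 strand = row$strand, mapq = row$mapq, cigar = row$cigar,
                 edit_distance = row$nm, optimal = row$optimal,
                 suboptimal = row$suboptimal, tie = row$tie,
                 rescued = row$rescued),
            class = "alignment_result")
}

#' Map a single read
#'
#' Votes are collected for the read and its reverse complement against
#' the forward-strand index; the two strand tallies form one candidate
#' pool (strand recorded per candidate).  The best block is selected
#' (random tie-break with mapping quality forced to 0), quality is the
#' capped, scaled vote difference, and alignments with more than two
#' mismatches are rescued by Smith-Waterman on the extended block.
#'
#' @param read DNA string.
#' @param index a [build_index()] result.
#' @param params a [vote_params()].
#' @param scheme a [scoring_scheme()].
#' @param name read name carried into the result.
#' @return an object of class `alignment_result` with fields `mapped`,
#'   `seq`, `pos` (1-based), `strand`, `mapq`, `cigar`,
#'   `edit_distance`, `optimal`, `suboptimal`, `tie`, `rescued`.
#' @export
map_single <- function(read, index, params = vote_params(),
                       scheme = scoring_scheme(), name = "read") {
  b <- map_batch(index, read, params, scheme)
  as_alignment_result(b[1, ], index$ref, name)
}

# outer distance of two block placements (global 0-based starts)
outer_distance <- function(b1, n1, b2, n2) {
  max(b1 + n1, b2 + n2) - min(b1, b2)
}

#' Map a read pair
#'
#' Mates are mapped independently.  When one or both mates have tied
#' best blocks, the candidate combination placing the mates on opposite
#' strands of the same sequence within `insert_max` of each other is
#' preferred over the random tie-break (tied selections keep mapping
#' quality 0).  Proper-pair status requires both mates mapped to the
#' same sequence on opposite strands within `insert_max`.
#'
#' @param read1,read2 mate DNA strings (FR library orientation).
#' @param index a [build_index()] result.
#' @param params a [vote_params()].
#' @param scheme a [scoring_scheme()].
#' @param insert_max maximum outer distance of a concordant pair.
#' @param name pair name.
#' @return list with elements `r1` and `r2` (two `alignment_result`s),
#'   `proper` and `tlen` (outer distance, 0 when not computable).
#' @export
map_pair <- function(read1, read2, index, params = vote_params(),
                     scheme = scoring_scheme(), insert_max = 1000L,
                     name = "pair") {
  b1 <- map_batch(index, read1, params, scheme)
  b2 <- map_batch(index, read2, params, scheme)
  res <- resolve_pair(index, c(read1, read2), b1, b2, 1L, params, scheme,
                      insert_max)
  b1 <- res$b1; b2 <- res$b2
  r1 <- as_alignment_result(b1[1, ], index$ref, name)
  r2 <- as_alignment_result(b2[1, ], index$ref, name)
  proper <- isTRUE(r1$mapped) && isTRUE(r2$mapped) &&
    identical(r1$seq, r2$seq) && r1$strand != r2$strand &&
    outer_distance(b1$pos[1], cigar_ref_len(b1$cigar[1]),
                   b2$pos[1], cigar_ref_len(b2$cigar[1])) <= insert_max
  tlen <- if (isTRUE(r1$mapped) && isTRUE(r2$mapped) &&
              identical(r1$seq, r2$seq))
    outer_distance(b1$pos[1], cigar_ref_len(b1$cigar[1]),
                   b2$pos[1], cigar_ref_len(b2$cigar[1]))
  else 0L
  list(r1 = r1, r2 = r2, proper = proper, tlen = as.integer(tlen))
}

# Concordance-aware override of tied selections for pair i.
# reads = c(read1, read2) for this pair only (batch rows are 1-row).
resolve_pair <- function(index, reads, b1, b2, i, params, scheme,
                         insert_max) {
  t1b <- attr(b1, "tied_blocks")[[i]]; t1s <- attr(b1, "tied_strands")[[i]]
  t2b <- attr(b2, "tied_blocks")[[i]]; t2s <- attr(b2, "tied_strands")[[i]]
  if (is.null(t1b) || is.null(t2b)) return(list(b1 = b1, b2 = b2))
  if (!(b1$tie[i] || b2$tie[i])) return(list(b1 = b1, b2 = b2))
  n1 <- nchar(reads[1]); n2 <- nchar(reads[2])
  ref <- index$ref
  best <- NULL
  for (a in seq_along(t1b)) {
    for (b in seq_along(t2b)) {
      if (t1s[a] == t2s[b]) next                       # need opposite strands
      s1 <- seq_index_of(ref, t1b[a]); s2 <- seq_index_of(ref, t2b[b])
      if (s1 != s2) next
      d <- outer_distance(t1b[a], n1, t2b[b], n2)
      if (d > insert_max) next
      if (is.null(best) || d < best$d) best <- list(a = a, b = b, d = d)
    }
  }
  if (is.null(best)) return(list(b1 = b1, b2 = b2))
  b1 <- override_selection(index, reads[1], b1, i, t1b[best$a], t1s[best$a],
                           params, scheme)
  b2 <- override_selection(index, reads[2], b2, i, t2b[best$b], t2s[best$b],
                           params, scheme)
  list(b1 = b1, b2 = b2)
}

override_selection <- function(index, read, b, i, block, strand01, params,
                               scheme) {
  if (isTRUE(b$mapped[i]) && !is.na(b$block_start[i]) &&
      b$block_start[i] == block &&
      ((b$strand[i] == "-") == (strand01 == 1L)))
    return(b)
  ref <- index$ref
  seq <- toupper(read)
  if (strand01 == 1L) seq <- C_revcomp(seq)
  a <- C_align_to_block(ref$genome, ref$offsets, ref$lengths, seq,
                        as.integer(block), scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend, 36L, 2L)
  b$block_start[i] <- block
  b$strand[i] <- if (strand01 == 1L) "-" else "+"
  if (a$ok) {
    b$mapped[i] <- TRUE
    b$pos[i] <- a$pos
    b$cigar[i] <- a$cigar
    b$nm[i] <- a$nm
    b$rescued[i] <- a$rescued
  } else {
    b$mapped[i] <- FALSE
    b$pos[i] <- NA_integer_
    b$cigar[i] <- NA_character_
  }
  b
}

#' SAM header for an index
#'
#' @param index a [build_index()] result.
#' @param cl command line recorded in the `@PG` line.
#' @return character vector of header lines (`@HD`, `@SQ`, `@PG`).
#' @export
sam_header <- function(index, cl = "seedvote") {
  ref <- index$ref
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$names, ref$lengths),
    sprintf("@PG\tID:seedvote\tPN:seedvote\tVN:%s\tCL:%s",
            as.character(utils::packageVersion("seedvote")), cl))
}

reverse_chars <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# vectorized SAM record builder for one batch of reads
sam_lines_single <- function(index, b, names, seqs, quals = NULL) {
  ref <- index$ref
  n <- nrow(b)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  flag <- ifelse(b$mapped, ifelse(b$strand == "-", 16L, 0L), 4L)
  loc <- list(seq = rep("*", n), pos = rep(0L, n))
  if (any(b$mapped)) {
    gl <- global_to_local(ref, b$pos[b$mapped])
    loc$seq[b$mapped] <- gl$seq
    loc$pos[b$mapped] <- gl$pos
  }
  out_seq <- ifelse(b$mapped & b$strand == "-", revcomp(seqs), toupper(seqs))
  out_qual <- ifelse(b$mapped & b$strand == "-", reverse_chars(quals), quals)
  cig <- ifelse(b$mapped, b$cigar, "*")
  mapq <- ifelse(b$mapped, b$mapq, 0L)
  tags <- ifelse(b$mapped,
                 sprintf("NM:i:%d\tvo:i:%d\tvs:i:%d", b$nm, b$optimal,
                         b$suboptimal),
                 sprintf("vo:i:%d\tvs:i:%d", b$optimal, b$suboptimal))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
          names, flag, loc$seq, loc$pos, mapq, cig, out_seq, out_qual, tags)
}

sam_lines_paired <- function(index, b1, b2, names, s1, s2, q1, q2,
                             insert_max) {
  ref <- index$ref
  n <- nrow(b1)
  if (is.null(q1)) q1 <- strrep("I", nchar(s1))
  if (is.null(q2)) q2 <- strrep("I", nchar(s2))
  loc <- function(b) {
    out <- list(seq = rep("*", n), pos = rep(0L, n))
    if (any(b$mapped)) {
      gl <- global_to_local(ref, b$pos[b$mapped])
      out$seq[b$mapped] <- gl$seq
      out$pos[b$mapped] <- gl$pos
    }
    out
  }
  l1 <- loc(b1); l2 <- loc(b2)
  end1 <- ifelse(b1$mapped, b1$pos + cigar_ref_len(b1$cigar), NA_integer_)
  end2 <- ifelse(b2$mapped, b2$pos + cigar_ref_len(b2$cigar), NA_integer_)
  same_seq <- b1$mapped & b2$mapped & l1$seq == l2$seq
  outer <- ifelse(same_seq,
                  pmax(end1, end2) - pmin(b1$pos, b2$pos), 0L)
  proper <- same_seq & (b1$strand != b2$strand) & outer <= insert_max
  tlen1 <- ifelse(same_seq, ifelse(b1$pos <= b2$pos, outer, -outer), 0L)
  tlen2 <- ifelse(same_seq, -tlen1, 0L)
  flag_of <- function(b, mate, first) {
    f <- 1L + if (first) 64L else 128L
    f <- f + ifelse(proper, 2L, 0L)
    f <- f + ifelse(b$mapped, 0L, 4L) + ifelse(mate$mapped, 0L, 8L)
    f <- f + ifelse(b$mapped & b$strand == "-", 16L, 0L)
    f + ifelse(mate$mapped & mate$strand == "-", 32L, 0L)
  }
  f1 <- flag_of(b1, b2, TRUE)
  f2 <- flag_of(b2, b1, FALSE)
  rn1 <- ifelse(b1$mapped & b2$mapped, ifelse(l1$seq == l2$seq, "=", l2$seq),
                "*")
  rn2 <- ifelse(b1$mapped & b2$mapped, ifelse(l1$seq == l2$seq, "=", l1$seq),
                "*")
  pn1 <- ifelse(b1$mapped & b2$mapped, l2$pos, 0L)
  pn2 <- ifelse(b1$mapped & b2$mapped, l1$pos, 0L)
  line <- function(b, l, f, rn, pn, tl, seqs, quals) {
    out_seq <- ifelse(b$mapped & b$strand == "-", revcomp(seqs),
                      toupper(seqs))
    out_qual <- ifelse(b$mapped & b$strand == "-", reverse_chars(quals),
                       quals)
    tags <- ifelse(b$mapped,
                   sprintf("NM:i:%d\tvo:i:%d\tvs:i:%d", b$nm, b$optimal,
                           b$suboptimal),
                   sprintf("vo:i:%d\tvs:i:%d", b$optimal, b$suboptimal))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
            names, f, l$seq, l$pos, ifelse(b$mapped, b$mapq, 0L),
            ifelse(b$mapped, b$cigar, "*"), rn, pn, tl, out_seq, out_qual,
            tags)
  }
  list(lines1 = line(b1, l1, f1, rn1, pn1, tlen1, s1, q1),
       lines2 = line(b2, l2, f2, pn = pn2, rn = rn2, tl = tlen2, seqs = s2,
                     quals = q2))
}

#' Map a set of reads and produce SAM
#'
#' The workhorse behind the command-line `align` step.  Single-end when
#' `reads2` is `NULL`; paired-end (FR orientation) otherwise, with
#' mates emitted on adjacent lines.  Tie-breaks draw from R's RNG, so
#' `set.seed()` makes runs reproducible.
#'
#' @param index a [build_index()] result.
#' @param reads character vector of read sequences (mate 1 for pairs).
#' @param names read names; defaults to `read1..readN`.
#' @param quals,quals2 optional phred quality strings.
#' @param reads2 mate-2 sequences for paired-end input.
#' @param params a [vote_params()].
#' @param scheme a [scoring_scheme()].
#' @param insert_max maximum concordant outer distance (default 1000).
#' @return an object of class `sam_output`: list with `header`, `lines`
#'   (one per SAM record) and `stats` (mapped/unmapped/tied/rescued
#'   counts).
#' @export
map_reads <- function(index, reads, names = NULL, quals = NULL,
                      reads2 = NULL, quals2 = NULL, params = vote_params(),
                      scheme = scoring_scheme(), insert_max = 1000L) {
  if (is.null(names)) names <- paste0("read", seq_along(reads))
  if (is.null(reads2)) {
    b <- map_batch(index, reads, params, scheme)
    lines <- sam_lines_single(index, b, names, reads, quals)
    stats <- c(reads = length(reads), mapped = sum(b$mapped),
               unmapped = sum(!b$mapped), tied = sum(b$tie),
               rescued = sum(b$rescued))
  } else {
    stopifnot(length(reads) == length(reads2))
    b1 <- map_batch(index, reads, params, scheme)
    b2 <- map_batch(index, reads2, params, scheme)
    needs <- which(b1$tie | b2$tie)
    for (i in needs) {
      res <- resolve_pair_i(index, reads[i], reads2[i], b1, b2, i, params,
                            scheme, insert_max)
      b1 <- res$b1; b2 <- res$b2
    }
    sl <- sam_lines_paired(index, b1, b2, names, reads, reads2, quals,
                           quals2, insert_max)
    lines <- as.vector(rbind(sl$lines1, sl$lines2))
    stats <- c(reads = 2L * length(reads),
               mapped = sum(b1$mapped) + sum(b2$mapped),
               unmapped = sum(!b1$mapped) + sum(!b2$mapped),
               tied = sum(b1$tie) + sum(b2$tie),
               rescued = sum(b1$rescued) + sum(b2$rescued))
  }
  structure(list(header = sam_header(index), lines = lines, stats = stats),
            class = "sam_output")
}

# single-pair wrapper around resolve_pair operating on row i of batches
resolve_pair_i <- function(index, read1, read2, b1, b2, i, params, scheme,
                           insert_max) {
  t1b <- attr(b1, "tied_blocks"); t1s <- attr(b1, "tied_strands")
  t2b <- attr(b2, "tied_blocks"); t2s <- attr(b2, "tied_strands")
  sb1 <- b1[i, , drop = FALSE]
  attr(sb1, "tied_blocks") <- t1b[i]; attr(sb1, "tied_strands") <- t1s[i]
  sb2 <- b2[i, , drop = FALSE]
  attr(sb2, "tied_blocks") <- t2b[i]; attr(sb2, "tied_strands") <- t2s[i]
  res <- resolve_pair(index, c(read1, read2), sb1, sb2, 1L, params, scheme,
                      insert_max)
  for (col in names(b1)) {
    b1[i, col] <- res$b1[1, col]
    b2[i, col] <- res$b2[1, col]
  }
  list(b1 = b1, b2 = b2)
}

#' Render one alignment result as a SAM line
#'
#' Single-end conventions: flag 4 with position 0 and CIGAR `*` for
#' unmapped reads; flag 16 with the stored sequence reverse-complemented
#' (and qualities reversed) for reverse-strand hits.  The `NM` tag
#' carries the edit distance and the `vo`/`vs` tags the optimal and
#' suboptimal vote counts.
#'
#' @param result an `alignment_result` from [map_single()].
#' @param read the read sequence.
#' @param qual optional quality string.
#' @return a single SAM record (character).
#' @export
to_sam <- function(result, read, qual = NULL) {
  stopifnot(inherits(result, "alignment_result"))
  flag <- if (result$mapped) { if (result$strand == "-") 16L else 0L } else 4L
  rname <- if (result$mapped) result$seq else "*"
  pos <- if (result$mapped) result$pos else 0L
  mapq <- if (result$mapped) result$mapq else 0L
  cig <- if (result$mapped) result$cigar else "*"
  seq <- if (result$mapped && result$strand == "-") revcomp(read)
         else toupper(read)
  if (is.null(qual)) qual <- strrep("I", nchar(read))
  qv <- if (result$mapped && result$strand == "-") reverse_chars(qual)
        else qual
  tags <- if (result$mapped)
    sprintf("NM:i:%d\tvo:i:%d\tvs:i:%d", result$edit_distance,
            result$optimal, result$suboptimal)
  else sprintf("vo:i:%d\tvs:i:%d", result$optimal, result$suboptimal)
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
          result$name, flag, rname, pos, mapq, cig, seq, qv, tags)
}

#' Write SAM output
#'
#' @param x a `sam_output` from [map_reads()] (or a character vector of
#'   lines, written verbatim).
#' @param path output path; `""` streams to stdout.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path) {
  lines <- if (inherits(x, "sam_output")) c(x$header, x$lines) else x
  if (identical(path, "")) writeLines(lines)
  else writeLines(lines, path)
  invisible(path)
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$mapped) {
    cat(sprintf("%s: mapped %s:%d (%s) mapq=%d cigar=%s NM=%d votes=%d/%d%s%s\n",
                x$name, x$seq, x$pos, x$strand, x$mapq, x$cigar,
                x$edit_distance, x$optimal, x$suboptimal,
                if (x$tie) " [tied]" else "",
                if (x$rescued) " [rescued]" else ""))
  } else {
    cat(sprintf("%s: unmapped (best block %d vote(s))\n", x$name, x$optimal))
  }
  invisible(x)
}

#' @export
print.sam_output <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "sam_output: %d records | mapped %d, unmapped %d, tied %d, rescued %d\n",
    length(x$lines), s[["mapped"]], s[["unmapped"]], s[["tied"]],
    s[["rescued"]]))
  invisible(x)
}
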