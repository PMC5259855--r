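# wgsim-style read simulation with truth tracking, and the accuracy
# evaluation protocol (correct = placed within 30 bp of the origin;
# sweep of confident/error/unmapped fractions over mapq thresholds).

#' Simulation parameters
#'
#' Emulates the standard whole-genome read-simulation setup: uniform
#' fragments, 0.4% per-base sequencing error, 0.1% mutation rate split
#' into 0.085% SNPs and 0.015% indels (indel lengths geometric with
#' mean 2, capped at 10).
#'
#' @param base_error_rate per-base sequencing error probability.
#' @param mutation_rate per-base mutation probability (SNP + indel).
#' @param snp_fraction fraction of mutations that are SNPs (0.85 gives
#'   the 0.085%/0.015% split).
#' @param read_length read length in bases.
#' @param paired generate FR mate pairs?
#' @param insert_mean,insert_sd outer fragment-size distribution for
#'   paired mode.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(base_error_rate = 0.004, mutation_rate = 0.001,
                       snp_fraction = 0.85, read_length = 150L,
                       paired = FALSE, insert_mean = 500, insert_sd = 50) {
  rates <- c(base_error_rate, mutation_rate, snp_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(read_length >= 36L, insert_mean >= read_length, insert_sd >= 0)
  structure(list(base_error_rate = base_error_rate,
                 mutation_rate = mutation_rate,
                 snp_rate = mutation_rate * snp_fraction,
                 indel_rate = mutation_rate * (1 - snp_fraction),
                 read_length = as.integer(read_length),
                 paired = isTRUE(paired), insert_mean = insert_mean,
                 insert_sd = insert_sd),
            class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic reference genome
#'
#' i.i.d. uniform A/C/G/T sequences.  `repeat_spec` copies a segment to
#' a second locus, manufacturing an exact repeat whose reads must tie
#' (mapping quality 0); `n_run` overwrites a stretch with Ns.
#'
#' @param length length of each sequence in bases (>= 1000).
#' @param n_sequences number of sequences (named `chr1`, `chr2`, ...).
#' @param repeat_spec optional list with `src_start`, `length`,
#'   `dest_start` (1-based, within sequence 1) copying
#'   `[src_start, src_start+length)` over `dest_start`.
#' @param n_run optional list with `start`, `length`: N run placed in
#'   sequence 1.
#' @param seed optional RNG seed (`set.seed()` applied when given).
#' @return a [reference_set()].
#' @export
generate_reference <- function(length, n_sequences = 1L, repeat_spec = NULL,
                               n_run = NULL, seed = NULL) {
  if (length < 1000L) stop("reference length must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_sequences), function(i)
    paste(sample(BASES, length, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_sequences))
  if (!is.null(repeat_spec)) {
    rs <- repeat_spec
    seg <- substr(seqs[[1]], rs$src_start, rs$src_start + rs$length - 1L)
    substr(seqs[[1]], rs$dest_start, rs$dest_start + rs$length - 1L) <- seg
  }
  if (!is.null(n_run))
    substr(seqs[[1]], n_run$start, n_run$start + n_run$length - 1L) <-
      strrep("N", n_run$length)
  reference_set(seqs)
}

rgeom_capped <- function(n, mean_len = 2, cap = 10L) {
  pmin(stats::rgeom(n, prob = 1 / mean_len) + 1L, cap)
}

# Mutate one template string: SNPs at snp_rate, indels at indel_rate.
# Returns list(seq, n_snp, n_ins, n_del).
mutate_template <- function(template, snp_rate, indel_rate) {
  n <- nchar(template)
  n_snp_sites <- stats::rbinom(1L, n, snp_rate)
  n_indel_sites <- stats::rbinom(1L, n, indel_rate)
  n_ins <- 0L; n_del <- 0L
  if (n_snp_sites > 0L) {
    pos <- sample.int(n, n_snp_sites)
    for (p in pos) {
      old <- substr(template, p, p)
      new <- sample(setdiff(BASES, old), 1L)
      substr(template, p, p) <- new
    }
  }
  if (n_indel_sites > 0L) {
    pos <- sort(sample.int(n, n_indel_sites), decreasing = TRUE)
    for (p in pos) {
      len <- rgeom_capped(1L)
      if (stats::runif(1) < 0.5) {      # insertion after position p
        ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
        template <- paste0(substr(template, 1L, p), ins,
                           substr(template, p + 1L, nchar(template)))
        n_ins <- n_ins + 1L
      } else {                          # deletion starting at p
        template <- paste0(substr(template, 1L, p - 1L),
                           substr(template, p + len, nchar(template)))
        n_del <- n_del + 1L
      }
    }
  }
  list(seq = template, n_snp = n_snp_sites, n_ins = n_ins, n_del = n_del)
}

# sequencing errors: each base substituted with prob err_rate
add_errors <- function(read, err_rate) {
  n <- nchar(read)
  k <- stats::rbinom(1L, n, err_rate)
  if (k == 0L) return(list(seq = read, n_err = 0L))
  pos <- sample.int(n, k)
  for (p in pos) {
    old <- substr(read, p, p)
    alt <- setdiff(BASES, old)
    if (length(alt) == 0L) alt <- BASES
    substr(read, p, p) <- sample(alt, 1L)
  }
  list(seq = read, n_err = k)
}

#' Simulate reads with known truth
#'
#' Fragments are drawn uniformly over the reference (sequences weighted
#' by length), strands uniformly.  Haplotype mutations (SNPs to a
#' different base; indels with geometric length, mean 2, capped at 10)
#' are applied at the configured rates, then sequencing errors at
#' `base_error_rate`.  Truth (origin sequence, 1-based leftmost start,
#' end, strand) is encoded in the read name
#' (`seq_start_end_strand_serial`) and returned as a truth table; for
#' reverse-strand reads the truth start is the leftmost forward-strand
#' coordinate.  Paired mode emits proper FR mates with outer insert
#' `~ Normal(insert_mean, insert_sd)`; mates share one name and carry
#' their own truth rows (`mate` 1 and 2).
#'
#' @param ref a [reference_set()].
#' @param n_reads number of reads (pairs in paired mode).
#' @param params a [sim_params()].
#' @param seed optional RNG seed.
#' @return list with `reads` (data.frame `name`, `seq`, `qual`; paired
#'   mode adds `reads2`) and `truth` (data.frame `name`, `mate`, `seq`,
#'   `start`, `end`, `strand`, `n_snp`, `n_ins`, `n_del`, `n_err`).
#' @export
simulate_reads <- function(ref, n_reads, params = sim_params(),
                           seed = NULL) {
  stopifnot(inherits(ref, "reference_set"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  rl <- params$read_length
  buf <- 12L  # template buffer so deletions cannot shorten the read
  if (params$paired) {
    if (any(ref$lengths < params$insert_mean + 4 * params$insert_sd + buf))
      stop("reference shorter than the fragment length")
  } else if (any(ref$lengths < rl + buf)) {
    stop("reference shorter than the read length")
  }
  qual <- strrep("9", rl)  # constant phred 24 ~ the 0.4% error regime
  chrom_i <- sample.int(length(ref$names), n_reads, replace = TRUE,
                        prob = ref$lengths)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  # Emit one read whose leftmost forward-strand coordinate is
  # `leftmost`.  The mutated template carries `buf` spare bases (on the
  # far side of the read) so deletions cannot shorten the read; with
  # indels the reported truth start is exact only up to the net indel
  # shift, well inside the 30 bp correctness tolerance.
  one_read <- function(ci, s, leftmost) {
    if (s == "+") {
      tpl <- substr_seq(ref, ci, leftmost, rl + buf)
      mut <- mutate_template(tpl, params$snp_rate, params$indel_rate)
      raw <- substr(mut$seq, 1L, rl)
    } else {
      tpl <- substr_seq(ref, ci, leftmost - buf, rl + buf)
      mut <- mutate_template(tpl, params$snp_rate, params$indel_rate)
      L2 <- nchar(mut$seq)
      raw <- C_revcomp(substr(mut$seq, max(L2 - rl + 1L, 1L), L2))
    }
    if (nchar(raw) < rl)  # only reachable after extreme deletion pile-ups
      raw <- paste0(raw, paste(sample(BASES, rl - nchar(raw),
                                      replace = TRUE), collapse = ""))
    err <- add_errors(raw, params$base_error_rate)
    list(seq = err$seq, start = as.integer(leftmost),
         end = as.integer(leftmost + rl - 1L), n_snp = mut$n_snp,
         n_ins = mut$n_ins, n_del = mut$n_del, n_err = err$n_err)
  }

  if (!params$paired) {
    starts <- vapply(seq_len(n_reads), function(i)
      buf + sample.int(ref$lengths[chrom_i[i]] - rl - 2L * buf + 1L, 1L),
      integer(1))
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads))
      rows[[i]] <- one_read(chrom_i[i], strand[i], starts[i])
    starts_out <- vapply(rows, `[[`, integer(1), "start")
    ends_out <- vapply(rows, `[[`, integer(1), "end")
    name <- sprintf("%s_%d_%d_%s_%d", ref$names[chrom_i], starts_out,
                    ends_out, ifelse(strand == "+", "f", "r"),
                    seq_len(n_reads))
    reads <- data.frame(name = name,
                        seq = vapply(rows, `[[`, character(1), "seq"),
                        qual = qual, stringsAsFactors = FALSE)
    truth <- data.frame(name = name, mate = 1L, seq = ref$names[chrom_i],
                        start = starts_out, end = ends_out, strand = strand,
                        n_snp = vapply(rows, `[[`, integer(1), "n_snp"),
                        n_ins = vapply(rows, `[[`, integer(1), "n_ins"),
                        n_del = vapply(rows, `[[`, integer(1), "n_del"),
                        n_err = vapply(rows, `[[`, integer(1), "n_err"),
                        stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }

  # paired: fragment on the forward strand; mate1 from the fragment
  # strand's 5' end, mate2 the reverse complement of the other end
  frag <- pmax(as.integer(round(stats::rnorm(n_reads, params$insert_mean,
                                             params$insert_sd))),
               rl + buf + 1L)
  frag <- pmin(frag, ref$lengths[chrom_i] - 2L * buf - 1L)
  fstart <- vapply(seq_len(n_reads), function(i)
    buf + sample.int(ref$lengths[chrom_i[i]] - frag[i] - 2L * buf + 1L, 1L),
    integer(1))
  r1 <- vector("list", n_reads)
  r2 <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    left_start <- fstart[i]
    right_start <- fstart[i] + frag[i] - rl
    if (strand[i] == "+") {
      r1[[i]] <- one_read(chrom_i[i], "+", left_start)
      r2[[i]] <- one_read(chrom_i[i], "-", right_start)
    } else {
      r1[[i]] <- one_read(chrom_i[i], "-", right_start)
      r2[[i]] <- one_read(chrom_i[i], "+", left_start)
    }
  }
  name <- sprintf("%s_%d_%d_%s_%d", ref$names[chrom_i], fstart,
                  fstart + frag - 1L, ifelse(strand == "+", "f", "r"),
                  seq_len(n_reads))
  get <- function(rows, f, what) vapply(rows, `[[`, f, what)
  truth_of <- function(rows, mate, str)
    data.frame(name = name, mate = mate, seq = ref$names[chrom_i],
               start = get(rows, integer(1), "start"),
               end = get(rows, integer(1), "end"), strand = str,
               n_snp = get(rows, integer(1), "n_snp"),
               n_ins = get(rows, integer(1), "n_ins"),
               n_del = get(rows, integer(1), "n_del"),
               n_err = get(rows, integer(1), "n_err"),
               stringsAsFactors = FALSE)
  s1 <- ifelse(strand == "+", "+", "-")
  s2 <- ifelse(strand == "+", "-", "+")
  list(reads = data.frame(name = name, seq = get(r1, character(1), "seq"),
                          qual = qual, stringsAsFactors = FALSE),
       reads2 = data.frame(name = name, seq = get(r2, character(1), "seq"),
                           qual = qual, stringsAsFactors = FALSE),
       truth = rbind(truth_of(r1, 1L, s1), truth_of(r2, 2L, s2)))
}

# substring of sequence ci (1-based local coords) of length len
substr_seq <- function(ref, ci, start, len) {
  g0 <- ref$offsets[ci] + start  # global 1-based
  substr(ref$genome, g0, g0 + len - 1L)
}

#' Write a truth table as TSV
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table
#'
#' @param path TSV written by [write_truth()].
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Evaluate alignments against simulation truth
#'
#' A record is correct when it is mapped to its origin sequence within
#' `max_dist` (default 30) bases of the true leftmost position.  For
#' each mapping-quality threshold the sweep reports the confident
#' fraction (mapq >= threshold among all reads; `strict = TRUE` uses >),
#' the error fraction among confident records, and the unmapped
#' fraction.
#'
#' @param sam path to a SAM file or a data.frame from [read_sam()].
#' @param truth truth data.frame from [simulate_reads()] (or
#'   [read_truth()]).
#' @param thresholds mapq thresholds to sweep (default 1:60).
#' @param max_dist correctness distance in bases (default 30).
#' @param strict use `mapq > threshold` instead of `>=`.
#' @return data.frame of class `eval_sweep` with columns `threshold`,
#'   `confident`, `error`, `unmapped` (fractions in [0, 1]).  A warning
#'   is raised when the error fraction is not non-increasing in the
#'   threshold.
#' @export
evaluate_alignments <- function(sam, truth, thresholds = 1:60,
                                max_dist = 30L, strict = FALSE) {
  rec <- if (is.character(sam)) read_sam(sam) else sam
  rec <- rec[bitwAnd(rec$flag, 256L) == 0L & bitwAnd(rec$flag, 2048L) == 0L,
             , drop = FALSE]
  mate <- ifelse(bitwAnd(rec$flag, 128L) > 0L, 2L, 1L)
  key <- paste(rec$qname, mate)
  tkey <- paste(truth$name, truth$mate)
  ti <- match(key, tkey)
  if (anyNA(ti)) {
    bad <- unique(rec$qname[is.na(ti)])
    stop("no truth record for: ", paste(utils::head(bad, 10L),
                                        collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  mapped <- bitwAnd(rec$flag, 4L) == 0L
  correct <- mapped & rec$rname == truth$seq[ti] &
    abs(rec$pos - truth$start[ti]) <= max_dist
  n <- nrow(rec)
  sweep <- do.call(rbind, lapply(thresholds, function(t) {
    conf <- if (strict) mapped & rec$mapq > t else mapped & rec$mapq >= t
    data.frame(threshold = t, confident = sum(conf) / n,
               error = if (any(conf)) sum(conf & !correct) / sum(conf) else 0,
               unmapped = sum(!mapped) / n)
  }))
  if (is.unsorted(rev(sweep$error), strictly = FALSE))
    warning("error fraction is not non-increasing in the mapq threshold")
  class(sweep) <- c("eval_sweep", "data.frame")
  attr(sweep, "n_records") <- n
  attr(sweep, "n_correct") <- sum(correct)
  sweep
}

#' Write an evaluation sweep as TSV (percent units)
#'
#' @param sweep an `eval_sweep` from [evaluate_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval <- function(sweep, path) {
  out <- data.frame(threshold = sweep$threshold,
                    confident_pct = 100 * sweep$confident,
                    error_pct = 100 * sweep$error,
                    unmapped_pct = 100 * sweep$unmapped)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
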