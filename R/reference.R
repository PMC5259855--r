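#' Reference sequence set
#'
#' Holds a set of named DNA sequences as a virtual concatenation: each
#' sequence occupies a half-open interval of global 0-based coordinates,
#' and `offsets` records the cumulative start of each sequence.  All
#' genome coordinates inside the package are global 0-based; SAM output
#' converts to per-sequence 1-based positions.
#'
#' @param sequences named character vector of DNA sequences.  Bases are
#'   uppercased; any character other than A/C/G/T (N, IUPAC codes, ...)
#'   is kept verbatim and treated as ambiguous downstream.
#' @return an object of class `reference_set` with elements `names`,
#'   `lengths`, `offsets` (0-based starts), `total_length` and `genome`
#'   (the concatenated sequence).
#' @export
reference_set <- function(sequences) {
  if (length(sequences) == 0L) stop("reference must contain at least one sequence")
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("all reference sequences must be named")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  structure(
    list(names = names(sequences),
         lengths = as.integer(lens),
         offsets = as.integer(offs),
         total_length = sum(as.integer(lens)),
         genome = paste(sequences, collapse = "")),
    class = "reference_set")
}

#' Read a reference genome from FASTA
#'
#' Accepts multi-record, line-wrapped and gzip-compressed FASTA.
#' Sequence names are truncated at the first whitespace, as aligners
#' conventionally do.
#'
#' @param path FASTA file path.
#' @return a [reference_set()].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_set(seqs)
}

#' Write a reference set to FASTA
#'
#' @param ref a [reference_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(get_sequences(ref))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract the individual sequences of a reference set
#'
#' @param ref a [reference_set()].
#' @return named character vector of sequences.
#' @export
get_sequences <- function(ref) {
  stopifnot(inherits(ref, "reference_set"))
  out <- substring(ref$genome, ref$offsets + 1L, ref$offsets + ref$lengths)
  names(out) <- ref$names
  out
}

# index of the sequence containing global 0-based position `pos`
seq_index_of <- function(ref, pos) {
  findInterval(pos, ref$offsets)
}

#' Convert a global 0-based coordinate to (sequence, 1-based position)
#'
#' @param ref a [reference_set()].
#' @param pos global 0-based coordinate(s).
#' @return data.frame with columns `seq` and `pos` (1-based, local).
#' @export
global_to_local <- function(ref, pos) {
  if (any(pos < 0 | pos >= ref$total_length, na.rm = TRUE))
    stop("coordinate outside reference")
  i <- seq_index_of(ref, pos)
  data.frame(seq = ref$names[i], pos = as.integer(pos - ref$offsets[i] + 1L),
             stringsAsFactors = FALSE)
}

#' Convert (sequence name, 1-based position) to a global 0-based coordinate
#'
#' @param ref a [reference_set()].
#' @param seq sequence name(s).
#' @param pos 1-based local position(s).
#' @return integer global 0-based coordinate(s).
#' @export
local_to_global <- function(ref, seq, pos) {
  i <- match(seq, ref$names)
  if (anyNA(i)) stop("unknown sequence name: ", paste(seq[is.na(i)], collapse = ", "))
  if (any(pos < 1L | pos > ref$lengths[i]))
    stop("position outside sequence")
  as.integer(ref$offsets[i] + pos - 1L)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$names), "sequence(s),",
      x$total_length, "bp total\n")
  show <- utils::head(seq_along(x$names), 6L)
  for (i in show)
    cat(sprintf("  %s  %d bp\n", x$names[i], x$lengths[i]))
  if (length(x$names) > 6L) cat("  ...\n")
  invisible(x)
}
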