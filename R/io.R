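# FASTQ and SAM carriers shared by the mapper, simulator and CLI.

#' Read a FASTQ file
#'
#' Accepts gzip-compressed input.  Read names are truncated at the
#' first whitespace.
#'
#' @param path FASTQ path.
#' @return data.frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(name = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `name`, `seq`, `qual` (as
#'   produced by [simulate_reads()]).
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+",
                           reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Parse a SAM file
#'
#' Minimal reader for the eleven mandatory columns plus the raw
#' optional-tag string; header lines are returned as an attribute.
#'
#' @param path SAM path.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `tags`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(rec) == 0L) {
    out <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "header") <- hdr
    return(out)
  }
  parts <- strsplit(rec, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L)) stop("malformed SAM record")
  get <- function(i) vapply(parts, `[[`, character(1), i)
  out <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext = as.integer(get(8)), tlen = as.integer(get(9)),
    seq = get(10), qual = get(11),
    tags = vapply(parts, function(p)
      if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else "",
      character(1)),
    stringsAsFactors = FALSE)
  attr(out, "header") <- hdr
  out
}
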