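#' Index parameters
#'
#' Parameters of the modular-prime k-mer hash index.  Reference
#' subsequences of `seed_length` bases are taken every `stride` bases,
#' 2-bit encoded (A=0, C=1, G=2, T=3, first base most significant) and
#' reduced modulo the prime `modulus` to give a 32-bit key.
#'
#' The default seed length of 31 bp makes the maximum vote count of a
#' 150 bp read independent of its alignment phase relative to the
#' indexed positions (see [auto_seed_length()]); 32 bp is a hard upper
#' bound because a longer seed no longer fits a 64-bit integer.  The
#' default modulus is the largest prime below 2^32, maximizing the key
#' space of the 32-bit table.
#'
#' @param seed_length seed/window length in bases, 16..32.
#' @param stride spacing between indexed windows in bases (>= 1).
#' @param modulus prime modulus, at most 2^32 - 1.
#' @return an object of class `index_params`.
#' @export
index_params <- function(seed_length = 31L, stride = 8L,
                         modulus = 4294967291) {
  seed_length <- as.integer(seed_length)
  stride <- as.integer(stride)
  if (is.na(seed_length) || seed_length < 16L || seed_length > 32L)
    stop("seed_length must be between 16 and 32")
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")
  if (modulus > 2^32 - 1) stop("modulus must fit a 32-bit unsigned integer")
  if (!is_prime(modulus)) stop("modulus must be prime")
  structure(list(seed_length = seed_length, stride = stride,
                 modulus = modulus),
            class = "index_params")
}

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n %% 2 == 0) return(n == 2)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Encode a DNA k-mer as an integer
#'
#' A k-mer of length `k` maps to its base-4 big-endian value under
#' A=0, C=1, G=2, T=3 (first base most significant).  Because a 31-mer
#' needs 62 bits, the value is carried as an exact decimal string.
#'
#' @param seq DNA string of length 1..32, A/C/G/T only.
#' @return an object of class `encoded_kmer` with fields `value`
#'   (decimal string) and `length`.
#' @export
encode_kmer <- function(seq) {
  if (grepl("[^ACGT]", seq))
    stop(ambiguous_base_error(seq))
  structure(list(value = C_encode_kmer(seq), length = nchar(seq)),
            class = "encoded_kmer")
}

ambiguous_base_error <- function(seq) {
  structure(
    class = c("seedvote_ambiguous_base", "error", "condition"),
    list(message = "k-mer contains a non-ACGT character", call = NULL))
}

#' Decode an encoded k-mer back to its DNA string
#'
#' @param kmer an `encoded_kmer`, or a decimal-string value (then
#'   `length` is required).
#' @param length k-mer length when `kmer` is a bare value.
#' @return DNA string.
#' @export
decode_kmer <- function(kmer, length = NULL) {
  if (inherits(kmer, "encoded_kmer")) {
    C_decode_kmer(kmer$value, kmer$length)
  } else {
    if (is.null(length)) stop("length required when decoding a bare value")
    C_decode_kmer(as.character(kmer), as.integer(length))
  }
}

#' Hash key of an encoded k-mer
#'
#' The 32-bit key is the k-mer value reduced modulo the prime `modulus`.
#'
#' @param kmer an `encoded_kmer` (or decimal-string value).
#' @param modulus prime modulus, at most 2^32 - 1.
#' @return numeric key in `[0, modulus)`.
#' @export
compute_key <- function(kmer, modulus = 4294967291) {
  if (!is_prime(modulus)) stop("modulus must be prime")
  v <- if (inherits(kmer, "encoded_kmer")) kmer$value else as.character(kmer)
  C_key_from_value(v, modulus)
}

#' Build the hash index of a reference
#'
#' Enumerates windows of `seed_length` bases at local offsets 0, stride,
#' 2*stride, ... within each sequence (windows never span a sequence
#' boundary; the stride restarts at each sequence), hashes each
#' ACGT-only window to its key, and stores the window's global 0-based
#' coordinate in the key's coordinate vector.  Windows containing any
#' other character are dropped without key calculation.  Only the
#' forward strand is indexed; reverse-strand reads are handled at query
#' time by also voting with the reverse complement.
#'
#' @param ref a [reference_set()].
#' @param params an [index_params()].
#' @return an object of class `hash_index` carrying the parameters, the
#'   reference, and the sparse key -> coordinate-vector table.
#' @export
build_index <- function(ref, params = index_params()) {
  stopifnot(inherits(ref, "reference_set"), inherits(params, "index_params"))
  tab <- C_build_index(ref$genome, ref$offsets, ref$lengths,
                       params$seed_length, params$stride, params$modulus)
  if (tab$n_windows == 0)
    warning("reference contains no indexable window; index is empty")
  structure(list(params = params, ref = ref, keys = tab$keys, cs = tab$cs,
                 coords = tab$coords, n_windows = tab$n_windows,
                 n_dropped = tab$n_dropped),
            class = "hash_index")
}

#' Look up the coordinate vector of a key
#'
#' @param index a [build_index()] result.
#' @param key numeric key in `[0, modulus)`.
#' @return integer vector of global 0-based coordinates, or `NULL` when
#'   no indexed window hashed to this key.
#' @export
lookup_key <- function(index, key) {
  stopifnot(inherits(index, "hash_index"))
  if (key < 0 || key >= index$params$modulus)
    stop("key outside [0, modulus)")
  v <- C_lookup(index$keys, index$cs, index$coords, key)
  if (length(v) == 0L) NULL else v
}

INDEX_MAGIC <- "seedvote-index"
INDEX_VERSION <- 1L

#' Save / load a hash index
#'
#' The index is written as a self-describing serialized archive with a
#' magic string and format version; `load_index()` refuses files that
#' do not carry them.
#'
#' @param index a `hash_index`.
#' @param path file path.
#' @return `save_index()` returns `path` invisibly; `load_index()`
#'   returns the `hash_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "hash_index"))
  saveRDS(list(magic = INDEX_MAGIC, version = INDEX_VERSION,
               index = unclass(index)),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable index file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, INDEX_MAGIC))
    stop("not a seedvote index file (magic string missing)")
  if (!identical(obj$version, INDEX_VERSION))
    stop("unsupported index format version: ", obj$version)
  idx <- obj$index
  class(idx$params) <- "index_params"
  class(idx$ref) <- "reference_set"
  class(idx) <- "hash_index"
  idx
}

#' @export
print.hash_index <- function(x, ...) {
  cat("hash_index:", format(x$n_windows, big.mark = ","), "windows over",
      length(x$ref$names), "sequence(s) (",
      format(x$ref$total_length, big.mark = ","), "bp )\n")
  cat(sprintf("  seed length %d, stride %d, modulus %.0f\n",
              x$params$seed_length, x$params$stride, x$params$modulus))
  cat(sprintf("  %s distinct keys, %s windows dropped (ambiguous bases)\n",
              format(length(x$keys), big.mark = ","),
              format(x$n_dropped, big.mark = ",")))
  invisible(x)
}

#' @export
print.index_params <- function(x, ...) {
  cat(sprintf("index_params: seed_length=%d stride=%d modulus=%.0f\n",
              x$seed_length, x$stride, x$modulus))
  invisible(x)
}
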