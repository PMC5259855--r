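# Independent arbitrary-precision oracles over decimal strings, used to
# check the 62-bit k-mer encoding and the mod-M key reduction without
# touching the package's own integer path.

# decimal-string s -> s * mul + add (schoolbook, digits as integers)
dec_mul_add <- function(s, mul, add) {
  d <- rev(as.integer(strsplit(s, "")[[1]]))
  d <- d * mul
  d[1] <- d[1] + add
  carry <- 0L
  i <- 1L
  while (i <= length(d) || carry > 0) {
    if (i > length(d)) d <- c(d, 0L)
    v <- d[i] + carry
    d[i] <- v %% 10L
    carry <- v %/% 10L
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  paste(rev(d), collapse = "")
}

# positional-notation (Horner) value of a DNA string as a decimal string
bigint_kmer_value <- function(seq) {
  digits <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- "0"
  for (ch in strsplit(seq, "")[[1]])
    v <- dec_mul_add(v, 4L, digits[[ch]])
  v
}

# decimal-string mod m via digit-by-digit long division (m < 2^32, so
# every intermediate stays well inside double precision)
bigint_mod <- function(s, m) {
  r <- 0
  for (d in as.integer(strsplit(s, "")[[1]]))
    r <- (r * 10 + d) %% m
  r
}
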