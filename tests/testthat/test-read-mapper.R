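# Per-read orchestration across strands, pairing, and SAM emission.

test_that("planted reads map back to their origin on both strands", {
  set.seed(450)
  ref <- plant_reference(3000L)
  idx <- build_index(ref)
  p <- 1234L
  read <- substr(ref$genome, p + 1L, p + 150L)
  r <- map_single(read, idx)
  expect_true(r$mapped)
  expect_equal(r$seq, "chr1")
  expect_equal(r$pos, p + 1L)  # SAM is 1-based
  expect_equal(r$strand, "+")
  expect_equal(r$mapq, 60L)
  rc <- map_single(revcomp(read), idx)
  expect_true(rc$mapped)
  expect_equal(rc$pos, p + 1L)
  expect_equal(rc$strand, "-")
})

test_that("strand symmetry holds across random planted reads", {
  set.seed(451)
  ref <- plant_reference(5000L)
  idx <- build_index(ref)
  for (i in 1:8) {
    p <- sample(0:(5000L - 150L), 1L)
    read <- substr(ref$genome, p + 1L, p + 150L)
    f <- map_single(read, idx)
    r <- map_single(revcomp(read), idx)
    expect_equal(f$pos, r$pos)
    expect_equal(f$strand, "+")
    expect_equal(r$strand, "-")
    expect_equal(f$mapq, r$mapq)
  }
})

test_that("reads from an exactly duplicated region tie with mapq 0", {
  ref <- generate_reference(6000L, repeat_spec = list(src_start = 1001L,
                                                      length = 500L,
                                                      dest_start = 4001L),
                            seed = 452)
  idx <- build_index(ref)
  set.seed(1)
  origins <- c(1000L, 4000L)  # 0-based starts of the two copies
  for (off in c(0L, 113L, 350L)) {
    read <- substr(ref$genome, 1001L + off, 1000L + off + 150L)
    r <- map_single(read, idx)
    expect_true(r$mapped)
    expect_true(r$tie)
    expect_equal(r$mapq, 0L)
    expect_true((r$pos - 1L) %in% (origins + off))
  }
})

test_that("short reads are unmapped rather than an error", {
  set.seed(453)
  ref <- plant_reference(2000L)
  idx <- build_index(ref)
  r <- map_single(random_dna(20L), idx)
  expect_false(r$mapped)
})

test_that("unique concordant mates form a proper pair", {
  set.seed(454)
  ref <- plant_reference(5000L)
  idx <- build_index(ref)
  p <- 2000L
  frag <- 500L
  m1 <- substr(ref$genome, p + 1L, p + 150L)
  m2 <- revcomp(substr(ref$genome, p + frag - 150L + 1L, p + frag))
  pr <- map_pair(m1, m2, idx)
  expect_true(pr$proper)
  expect_equal(pr$tlen, frag)
  expect_equal(pr$r1$strand, "+")
  expect_equal(pr$r2$strand, "-")
  expect_equal(pr$r1$pos, p + 1L)
  expect_equal(pr$r2$pos, p + frag - 150L + 1L)
})

test_that("a tied mate resolves to the locus concordant with its partner", {
  # duplicate a 500 bp segment; mate 1 lies outside it, mate 2 inside
  ref <- generate_reference(8000L, repeat_spec = list(src_start = 2001L,
                                                      length = 500L,
                                                      dest_start = 6001L),
                            seed = 455)
  idx <- build_index(ref)
  m1 <- substr(ref$genome, 1701L, 1850L)               # unique, before copy 1
  m2 <- revcomp(substr(ref$genome, 2101L, 2250L))      # inside the repeat
  # mate 2 alone ties between the two copies
  alone <- map_single(m2, idx)
  expect_true(alone$tie)
  set.seed(7)
  for (i in 1:5) {
    pr <- map_pair(m1, m2, idx)
    expect_equal(pr$r2$pos, 2101L)   # always the copy concordant with mate 1
    expect_equal(pr$r2$mapq, 0L)     # tie still reports quality 0
    expect_true(pr$proper)
  }
})

test_that("pairs with both mates unmapped carry the paired-unmapped flags", {
  set.seed(456)
  ref <- plant_reference(2000L)
  idx <- build_index(ref)
  out <- map_reads(idx, strrep("N", 150L), names = "nn",
                   reads2 = strrep("N", 150L))
  rec <- strsplit(out$lines, "\t")
  flags <- vapply(rec, function(x) as.integer(x[2]), integer(1))
  expect_equal(length(flags), 2L)
  for (f in flags) {
    expect_equal(bitwAnd(f, 1L), 1L)   # paired
    expect_equal(bitwAnd(f, 4L), 4L)   # unmapped
    expect_equal(bitwAnd(f, 8L), 8L)   # mate unmapped
  }
})

test_that("SAM records follow the format conventions", {
  set.seed(457)
  ref <- plant_reference(3000L)
  idx <- build_index(ref)
  p <- 500L
  read <- substr(ref$genome, p + 1L, p + 150L)
  # unmapped: flag 4, pos 0, cigar *
  un <- map_single(strrep("N", 150L), idx, name = "un")
  line <- strsplit(to_sam(un, strrep("N", 150L)), "\t")[[1]]
  expect_equal(as.integer(line[2]), 4L)
  expect_equal(line[4], "0")
  expect_equal(line[6], "*")
  # reverse strand: flag 16, stored sequence reverse-complemented
  rc <- map_single(revcomp(read), idx, name = "rc")
  line <- strsplit(to_sam(rc, revcomp(read)), "\t")[[1]]
  expect_equal(bitwAnd(as.integer(line[2]), 16L), 16L)
  expect_equal(line[10], read)
  # vote counts travel as tags
  expect_match(paste(line, collapse = "\t"), "vo:i:15")
})

test_that("emitted SAM parses cleanly with an independent SAM reader", {
  set.seed(458)
  ref <- plant_reference(4000L)
  idx <- build_index(ref)
  sim <- simulate_reads(ref, 30L, sim_params(read_length = 100L), seed = 3)
  out <- map_reads(idx, sim$reads$seq, names = sim$reads$name,
                   quals = sim$reads$qual)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(out, sam)
  bam <- withr::local_tempfile(fileext = ".bam")
  Rsamtools::asBam(sam, sub("\\.bam$", "", bam), overwrite = TRUE,
                   indexDestination = FALSE)
  parsed <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(parsed$qname), 30L)
  ours <- read_sam(sam)
  mapped <- bitwAnd(ours$flag, 4L) == 0L
  expect_equal(sort(as.character(parsed$qname)), sort(ours$qname))
  key_ours <- paste(ours$qname, ours$pos)[mapped]
  key_bam <- paste(as.character(parsed$qname), parsed$pos)[!is.na(parsed$pos)]
  expect_setequal(key_ours, key_bam)
})

test_that("every read appears exactly once and positions stay in bounds", {
  set.seed(459)
  ref <- reference_set(c(chrA = random_dna(2500L), chrB = random_dna(1500L)))
  idx <- build_index(ref)
  sim <- simulate_reads(ref, 200L, sim_params(), seed = 4)
  out <- map_reads(idx, sim$reads$seq, names = sim$reads$name)
  rec <- read_sam(textConnection(c(out$header, out$lines)))
  expect_equal(sort(rec$qname), sort(sim$reads$name))
  mapped <- rec[bitwAnd(rec$flag, 4L) == 0L, ]
  lens <- stats::setNames(ref$lengths, ref$names)
  expect_true(all(mapped$pos >= 1L))
  expect_true(all(mapped$pos <= lens[mapped$rname]))
  span <- vapply(mapped$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSX=]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  expect_true(all(mapped$pos - 1L + span <= lens[mapped$rname]))
})
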