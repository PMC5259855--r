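# Synthetic reference generation, wgsim-style reads, truth-based scoring.

test_that("reference generation is reproducible and honours repeat_spec", {
  r1 <- generate_reference(2000L, seed = 470)
  r2 <- generate_reference(2000L, seed = 470)
  expect_identical(r1$genome, r2$genome)
  rep_ref <- generate_reference(5000L,
                                repeat_spec = list(src_start = 501L,
                                                   length = 500L,
                                                   dest_start = 3001L),
                                seed = 471)
  expect_identical(substr(rep_ref$genome, 501L, 1000L),
                   substr(rep_ref$genome, 3001L, 3500L))
  n_ref <- generate_reference(2000L, n_run = list(start = 901L,
                                                  length = 50L),
                              seed = 472)
  expect_identical(substr(n_ref$genome, 901L, 950L), strrep("N", 50L))
})

test_that("base composition of a large draw is uniform", {
  ref <- generate_reference(1e6, seed = 473)
  counts <- table(strsplit(ref$genome, "")[[1]])
  # binomial 99% bounds around p = 1/4 at n = 1e6
  p <- 1 / 4
  half <- qnorm(0.995) * sqrt(p * (1 - p) / 1e6)
  expect_true(all(abs(counts / 1e6 - p) < half * 1.5))
})

test_that("zero-rate simulation emits exact substrings of the reference", {
  ref <- generate_reference(20000L, seed = 474)
  sim <- simulate_reads(ref, 100L,
                        sim_params(base_error_rate = 0, mutation_rate = 0),
                        seed = 475)
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    origin <- substr(ref$genome, tr$start, tr$end)
    observed <- if (tr$strand == "+") sim$reads$seq[i]
                else revcomp(sim$reads$seq[i])
    expect_identical(observed, origin)
  }
})

test_that("simulation with the same seed is byte-identical", {
  ref <- generate_reference(20000L, seed = 476)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(simulate_reads(ref, 50L, sim_params(), seed = 9)$reads, f1)
  write_fastq(simulate_reads(ref, 50L, sim_params(), seed = 9)$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("per-base mismatch rate matches the planted error + SNP rates", {
  ref <- generate_reference(3e5, seed = 477)
  sim <- simulate_reads(ref, 8000L, sim_params(), seed = 478)
  keep <- sim$truth$n_ins == 0L & sim$truth$n_del == 0L
  mm <- 0L; bases <- 0L
  for (i in which(keep)) {
    tr <- sim$truth[i, ]
    origin <- substr(ref$genome, tr$start, tr$end)
    observed <- if (tr$strand == "+") sim$reads$seq[i]
                else revcomp(sim$reads$seq[i])
    mm <- mm + sum(strsplit(observed, "")[[1]] != strsplit(origin, "")[[1]])
    bases <- bases + nchar(origin)
  }
  rate <- mm / bases
  # expectation ~ 0.004 + 0.00085 (ignoring the rare double-hit overlap)
  expect_gt(rate, 0.0042)
  expect_lt(rate, 0.0056)
})

test_that("paired simulation yields FR mates at the requested insert", {
  ref <- generate_reference(50000L, seed = 479)
  sim <- simulate_reads(ref, 200L, sim_params(paired = TRUE,
                                              base_error_rate = 0,
                                              mutation_rate = 0),
                        seed = 480)
  expect_equal(nrow(sim$reads), 200L)
  expect_equal(nrow(sim$reads2), 200L)
  expect_equal(nrow(sim$truth), 400L)
  t1 <- sim$truth[sim$truth$mate == 1L, ]
  t2 <- sim$truth[sim$truth$mate == 2L, ]
  expect_true(all(t1$strand != t2$strand))
  outer <- abs(pmax(t1$end, t2$end) - pmin(t1$start, t2$start)) + 1L
  expect_gt(mean(outer), 400)
  expect_lt(mean(outer), 600)
})

test_that("correctness uses the 30 bp rule and the sweep counts partitions", {
  truth <- data.frame(name = paste0("r", 1:10), mate = 1L, seq = "chr1",
                      start = seq(1000L, 9100L, by = 900L), end = 0L,
                      strand = "+", stringsAsFactors = FALSE)
  pos <- truth$start
  pos[1] <- pos[1] + 30L   # still correct (boundary)
  pos[2] <- pos[2] + 31L   # wrong
  pos[3] <- pos[3] - 31L   # wrong
  mapq <- rep(60L, 10L)
  flag <- rep(0L, 10L)
  flag[10] <- 4L           # one unmapped read
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:20000",
           sprintf("r%d\t%d\tchr1\t%d\t%d\t150M\t*\t0\t0\t%s\t*", 1:10,
                   flag, ifelse(flag == 4L, 0L, pos),
                   ifelse(flag == 4L, 0L, mapq), strrep("A", 150L)))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  sw <- suppressWarnings(evaluate_alignments(f, truth))
  expect_equal(nrow(sw), 60L)
  at60 <- sw[sw$threshold == 60L, ]
  expect_equal(at60$confident, 0.9)
  expect_equal(at60$error, 2 / 9)
  expect_equal(at60$unmapped, 0.1)
  # two wrong placements among ten confident records
  truth2 <- truth
  sam2 <- sam
  sw2 <- suppressWarnings(
    evaluate_alignments(read_sam(f)[1:9, ], truth, thresholds = 60L))
  expect_equal(sw2$error, 2 / 9)
})

test_that("evaluation demands a truth record for every read", {
  truth <- data.frame(name = "known", mate = 1L, seq = "chr1", start = 100L,
                      end = 249L, strand = "+", stringsAsFactors = FALSE)
  sam <- c("@SQ\tSN:chr1\tLN:1000",
           sprintf("unknown\t0\tchr1\t100\t60\t150M\t*\t0\t0\t%s\t*",
                   strrep("A", 150L)))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  expect_error(evaluate_alignments(f, truth), "unknown")
})

test_that("a clean full-pipeline run scores perfectly at every threshold", {
  ref <- generate_reference(100000L, seed = 481)
  idx <- build_index(ref)
  sim <- simulate_reads(ref, 300L,
                        sim_params(base_error_rate = 0, mutation_rate = 0),
                        seed = 482)
  set.seed(483)
  out <- map_reads(idx, sim$reads$seq, names = sim$reads$name)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(out, f)
  sw <- evaluate_alignments(f, sim$truth)
  expect_true(all(sw$error == 0))
  expect_equal(sw$unmapped, rep(0, 60L))
  expect_equal(sw$confident[1], 1)
})
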