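# Seed extraction, vote collection, block selection, mapping quality.

test_that("automatic seed length reproduces the documented choices", {
  expect_equal(auto_seed_length(150L), 31L)
  expect_equal(auto_seed_length(125L), 30L)
  # independent exhaustive search for 103 bp
  cand <- Filter(function(s) (103L - s + 1L) %% 8L == 0L, 16:32)
  expect_equal(auto_seed_length(103L), max(cand))
  expect_equal(auto_seed_length(103L), 32L)
  expect_error(auto_seed_length(35L),
               class = "seedvote_unsupported_read_length")
})

test_that("auto seed length makes the exact-match vote count phase-invariant", {
  for (rl in c(36L, 50L, 100L, 125L, 150L, 151L, 250L, 300L)) {
    sl <- auto_seed_length(rl)
    votes <- max_votes_closed_form(rl, sl, 8L, 1:8)
    expect_equal(length(unique(votes)), 1L,
                 info = paste("read length", rl))
  }
})

test_that("closed-form vote counts match the worked geometry", {
  # 150 bp, seed 31: 15 votes at every phase
  expect_equal(max_votes_closed_form(150L, 31L, 8L, 1:8), rep(15L, 8L))
  # 150 bp, seed 32: 15 at phases 1-7 but only 14 at phase 8
  expect_equal(max_votes_closed_form(150L, 32L, 8L, 1:7), rep(15L, 7L))
  expect_equal(max_votes_closed_form(150L, 32L, 8L, 8L), 14L)
})

test_that("a read yields one seed per offset, skipping ambiguous windows", {
  set.seed(420)
  r <- random_dna(150L)
  s <- extract_seeds(r, 31L)
  expect_equal(nrow(s), 120L)  # n - 30
  expect_equal(s$read_offset, 0:119)
  expect_identical(s$seed[1], substr(r, 1, 31))
  # single seed when the read equals the seed length
  expect_equal(nrow(extract_seeds(random_dna(31L), 31L)), 1L)
  # N at (1-based) position 41 kills windows with 0-based starts 10..40
  rn <- r
  substr(rn, 41L, 41L) <- "N"
  sn <- extract_seeds(rn, 31L)
  expect_equal(nrow(sn), 89L)
  expect_false(any(sn$read_offset %in% 10:40))
  # read shorter than the seed yields nothing
  expect_equal(nrow(extract_seeds(random_dna(20L), 31L)), 0L)
})

test_that("an exact phase-aligned match gathers the closed-form vote count", {
  set.seed(421)
  ref <- plant_reference(1200L)
  # seed 31: 15 votes regardless of phase
  idx31 <- build_index(ref, index_params(31L, 8L))
  for (p in c(400L, 401L, 403L)) {
    read <- substr(ref$genome, p + 1L, p + 150L)
    tally <- collect_votes(read, idx31)
    expect_equal(tally$votes[tally$block_start == p], 15L)
  }
  # seed 32, first in-phase seed at the 8th base pair: 14 votes
  idx32 <- build_index(ref, index_params(32L, 8L))
  p <- 401L  # first in-phase coordinate 408 = read offset 7 (1-based 8th)
  read <- substr(ref$genome, p + 1L, p + 150L)
  tally <- collect_votes(read, idx32)
  expect_equal(tally$votes[tally$block_start == p], 14L)
  # seed 32, phase 1, two mismatches beyond the last in-phase seed: 15
  p <- 400L
  read <- mutate_at(substr(ref$genome, p + 1L, p + 150L), c(145L, 146L))
  tally <- collect_votes(read, idx32)
  expect_equal(tally$votes[tally$block_start == p], 15L)
  # an all-N read votes for nothing
  expect_equal(nrow(collect_votes(strrep("N", 150L), idx31)), 0L)
})

test_that("vote totals never exceed the number of seeds", {
  set.seed(422)
  ref <- plant_reference(2000L)
  idx <- build_index(ref)
  for (i in 1:5) {
    p <- sample(0:(2000L - 150L), 1L)
    read <- mutate_at(substr(ref$genome, p + 1L, p + 150L),
                      sample(150L, sample(0:5, 1L)))
    tally <- collect_votes(read, idx)
    expect_lte(sum(tally$votes), nrow(extract_seeds(read, 31L)))
  }
})

test_that("block selection enforces the minimum-vote and tie rules", {
  p <- vote_params()
  # a single-vote best block cannot be mapped
  sel <- select_block(data.frame(block_start = 1000L, votes = 1L), p)
  expect_equal(sel$status, "unmapped")
  # empty tally
  expect_equal(select_block(data.frame(block_start = integer(0),
                                       votes = integer(0)), p)$status,
               "unmapped")
  # unique argmax
  sel <- select_block(data.frame(block_start = c(1000L, 2000L),
                                 votes = c(15L, 4L)), p)
  expect_equal(sel[c("status", "block_start", "optimal", "suboptimal")],
               list(status = "mapped", block_start = 1000L, optimal = 15L,
                    suboptimal = 4L))
  # tie: random choice among the tied blocks, quality forced to 0
  tally <- data.frame(block_start = c(1000L, 2000L), votes = c(7L, 7L))
  set.seed(1)
  sel <- select_block(tally, p)
  expect_equal(sel$status, "tied")
  expect_true(sel$block_start %in% c(1000L, 2000L))
  expect_equal(mapping_quality(sel$optimal, sel$suboptimal, tie = TRUE), 0L)
  # deterministic under a fixed seed
  set.seed(99); a <- select_block(tally, p)$block_start
  set.seed(99); b <- select_block(tally, p)$block_start
  expect_identical(a, b)
  # both tied blocks are reachable
  picks <- unique(vapply(1:50, function(i) select_block(tally, p)$block_start,
                         integer(1)))
  expect_setequal(picks, c(1000L, 2000L))
})

test_that("mapping quality is the capped, scaled vote difference", {
  expect_equal(mapping_quality(15L, 5L), 60L)
  expect_equal(mapping_quality(15L, 3L), 60L)
  expect_equal(mapping_quality(5L, 5L), 0L)
  expect_equal(mapping_quality(7L, 5L), 12L)
  expect_error(mapping_quality(3L, 5L), "optimal")
  # always a multiple of 6, never above 60
  grid <- expand.grid(opt = 0:20, sub = 0:20)
  grid <- grid[grid$opt >= grid$sub, ]
  q <- mapping_quality(grid$opt, grid$sub)
  expect_true(all(q %in% seq(0L, 60L, by = 6L)))
})

test_that("voting and selection agree with the brute-force block scan", {
  set.seed(423)
  for (rep in 1:3) {
    L <- sample(800:2000, 1L)
    ref <- plant_reference(L)
    idx <- build_index(ref)
    p <- sample(0:(L - 150L), 1L)
    read <- mutate_at(substr(ref$genome, p + 1L, p + 150L),
                      sample(150L, sample(0:4, 1L)))
    tally <- collect_votes(read, idx)
    oracle <- oracle_votes(get_sequences(ref)[[1]], read, 31L, 8L)
    expect_equal(tally, oracle)
    if (nrow(oracle) > 0L && max(oracle$votes) >= 2L) {
      sel <- select_block(tally, vote_params())
      expect_equal(sel$optimal, max(oracle$votes))
      expect_true(sel$block_start %in%
                    oracle$block_start[oracle$votes == sel$optimal])
    }
  }
})

test_that("seeds voting beyond the occurrence cap are dropped", {
  set.seed(424)
  # a reference that is one 31-mer repeated in phase many times
  unit <- random_dna(8L)
  seqs <- c(chr1 = strrep(unit, 80L))
  idx <- build_index(reference_set(seqs), index_params(31L, 8L))
  read <- paste0(strrep(unit, 18L), random_dna(6L))  # 150 bp
  # every seed of the periodic part retrieves ~77 coordinates
  unlimited <- collect_votes(read, idx, vote_params(max_occurrence = 450L))
  capped <- collect_votes(read, idx, vote_params(max_occurrence = 10L))
  expect_gt(sum(unlimited$votes), 0L)
  expect_equal(nrow(capped), 0L)
})
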