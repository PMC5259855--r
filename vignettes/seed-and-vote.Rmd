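---
title: "Seed-and-vote read alignment: model, parameters and design"
author: "seedvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-vote read alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedvote)
```

## The method

Short-read alignment asks: given a reference genome and millions of
100–300 bp reads, where did each read come from?  `seedvote` answers
with a *seed-and-vote* strategy rather than the usual seed-and-extend.

**Indexing.**  Windows of `sl` bases (default 31) are taken from the
reference every `w` bases (default 8).  Each ACGT-only window is
2-bit-encoded (A=0, C=1, G=2, T=3, first base most significant) into a
62-bit integer and reduced modulo a large prime `M` (default
4,294,967,291, the largest prime below 2^32) to a 32-bit key.  The hash
table conceptually has `M` slots; we store only occupied keys, each
mapping to the vector of genome coordinates of the windows that hashed
to it.  Windows containing any other character (N, IUPAC codes) are
dropped without key calculation.

**Voting.**  A read of length `n` contributes one seed per offset, so
`n - sl + 1` seeds (120 for a 150 bp read at `sl = 31`).  Each seed is
hashed the same way and looked up.  Every retrieved coordinate `c` for
the seed at read offset `o` casts one vote for the *block* starting at
`c - o` — a reference interval of read length, whose start is the
candidate mapping position.  Only seeds in phase with the stride can
hit the table; that is the mechanism, not a loss.  Four rules govern
the outcome:

1. the winning block needs at least 2 votes, else the read is unmapped;
2. blocks tied for most votes are resolved uniformly at random and the
   mapping quality is forced to 0;
3. an accepted block with more than 2 position-wise mismatches is
   realigned by Smith–Waterman against the block extended 36 bp in both
   directions (clipped at sequence bounds);
4. a seed retrieving more than 450 coordinates is *unrepresentative*
   and skipped entirely.

**Mapping quality.**  With `optimal` and `suboptimal` the vote counts
of the best and second-best blocks,

$$\mathrm{mapq} = \min\{(\mathrm{optimal} - \mathrm{suboptimal}) \times 6,\; 60\},$$

always a multiple of 6, at most 60, and 0 for tied selections.

## Why 31 and not 32

Seed length interacts with the stride.  For an exactly matching 150 bp
read, the in-phase seeds start at read positions $d, d+8, d+16, \dots$
where the phase $d \in 1..8$ depends on where the read happens to fall
relative to the indexed coordinates.  The maximum vote count is

$$\left\lfloor \frac{n - sl + 1 - d}{w} \right\rfloor + 1 .$$

With `sl = 32` this is 15 for phases 1–7 but 14 for phase 8 — so a
block with two mismatches past the last seed can out-vote a perfect
match elsewhere.  With `sl = 31`, $n - sl + 1 = 120$ is divisible by 8
and every phase yields 15 votes.  `auto_seed_length()` generalizes
this: it returns the largest $s \in [16, 32]$ with $(n - s + 1) \equiv
0 \pmod{w}$, which reproduces the documented choices 150 → 31 and
125 → 30 (and 103 → 32).  The exact rule behind those two published
choices is not spelled out anywhere; this reconstruction is the
simplest one with the phase-invariance property and is treated as a
design decision of this package.  32 is a hard ceiling because a
longer seed no longer fits a 64-bit integer.

```{r}
max_votes_closed_form(150, 31, 8, d = 1:8)
max_votes_closed_form(150, 32, 8, d = 1:8)
auto_seed_length(125)
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `seed_length` | 31 (auto) | bp | index window / seed size; 16–32 |
| `stride` | 8 | bp | spacing of indexed windows |
| `modulus` | 4294967291 | — | prime for the 32-bit key space |
| `min_votes` | 2 | votes | below this the read is unmapped |
| `max_occurrence` | 450 | coords | seed-drop threshold |
| `mapq_scale`, `mapq_cap` | 6, 60 | — | quality scaling |
| `verify_hits` | TRUE | — | confirm hash hits against the reference |
| `merge_window` | 0 | bp | optional tally clustering |
| `pad` | 36 | bp | rescue extension each side |
| `max_mismatches` | 2 | — | ungapped-acceptance threshold |
| match/mismatch/gap open/extend | 1 / −3 / −5 / −2 | — | rescue scoring |

Two of these deserve comment.

*`verify_hits`* — distinct 31-mers can share a key modulo `M`.  The
method's own accounting never mentions collisions, but an unverified
hit would inject a vote for an unrelated block.  We verify by direct
text comparison against the reference (cheap: one `memcmp` per hit)
and expose the flag for experimentation.  On collision-free toys the
tallies are identical either way.

*Scoring scheme* — the rescue is specified only as "Smith–Waterman".
We use affine gaps with +1/−3/−5/−2 (a gap of length $L$ costs
$-5 - 2L$), the common short-read practice, and make it configurable.
The rescue never changes the reported mapping quality: confidence is a
statement about votes, not about the realignment.

## Strands and pairs

Only the forward strand is indexed.  At query time votes are collected
for the read and for its reverse complement, and the two tallies form
one candidate pool with the strand recorded per candidate; selection,
tie-breaking and quality work on the merged pool.  This symmetric
treatment is the only unbiased choice given a one-strand index, and
halves index memory.

Paired-end logic is deliberately minimal: mates are mapped
independently; only when a mate's best blocks are tied does the pair
matter, and then the combination placing the mates on opposite strands
of the same sequence within `insert_max` (default 1000 bp, minimal
outer distance wins) is preferred over the random tie-break.  A
selection that was tied keeps mapping quality 0 even when concordance
resolved it — the tie-implies-zero invariant is kept unconditional.
There is no Smith–Waterman mate rescue.

## Numerical and degenerate-input choices

* Coordinates are global 0-based over the virtual concatenation of the
  reference sequences; windows and blocks never span a sequence
  boundary; SAM output is per-sequence 1-based.
* The Smith–Waterman traceback resolves ties with fixed precedence
  (diagonal, then the gap consuming a read base, then the gap consuming
  a reference base), starting from the first maximal cell in row-major
  order — results are fully deterministic.
* A rescue whose best local score is not positive leaves the read
  unmapped; any positive-score alignment is accepted (no extra score
  threshold).
* Tie-break randomness comes from R's RNG only, so `set.seed()` (or the
  CLI's `--rng-seed`) makes whole runs byte-reproducible.
* Reads shorter than the seed length are reported unmapped, not
  errors; `auto_seed_length()` refuses read lengths below 36 (the
  method is recommended for reads over 100 bp).
* When only one block exists, `suboptimal = 0`, giving an isolated
  unique hit the maximal quality — consistent with the cap.
* `lookup_key()` returns `NULL` for unseen keys (the table's NULL
  convention); an empty tally is a valid unmapped outcome.
* 62-bit k-mer values exceed exact double precision, so
  `encode_kmer()` carries the value as an exact decimal string; all
  modular arithmetic happens in 64-bit integers in compiled code.

## The simulator: what it emulates, and what it does not

`simulate_reads()` emulates the standard wgsim setup used to
benchmark aligners: fragments uniform over the genome, strands
uniform, haplotype mutations at 0.1% (85% SNPs to a different base,
15% indels with geometric length of mean 2 capped at 10), then
sequencing errors at 0.4% per base.  Truth (origin sequence, 1-based
leftmost forward-strand start, end, strand) is encoded in read names
and returned as a table; paired mode draws the outer insert from
Normal(500, 50) and emits FR mates.

It does **not** emulate: quality-dependent or position-dependent error
profiles, shared haplotypes between mates (each mate's template is
mutated independently), structural variants, coverage bias, or real
genome repeat structure — a uniform-random reference is far more
mappable than hs37d5.  Passing the recovery tests therefore shows the
machinery is correct and calibrated on unambiguous sequence, not that
real-genome accuracy figures are reproduced.  The duplicated-locus
generator (`repeat_spec`) adds the one repeat feature the method's
tie rule is about.

The evaluation protocol is the standard one for simulated reads: a
record is correct when placed on its origin sequence within 30 bp of
the true leftmost position, and the sweep reports confident fraction
(mapq at or above each threshold 1..60; the strict variant is a flag),
error fraction among confident records, and unmapped fraction.  The
error-versus-threshold trend is asserted to be non-increasing by the
test suite on this pipeline's output; `evaluate_alignments()` itself
only warns, because for arbitrary third-party input the quantity is
not mathematically monotone.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline on uniform-random
references of up to 1 Mb with 10,000 simulated 150 bp reads per
condition (error-free, and the 0.4%/0.085%/0.015% model), 500 random
pairs for the Smith–Waterman oracle comparison, and exhaustive
block-scan oracles on references up to 5 kb.  These sizes were chosen
to give stable Monte-Carlo estimates (binomial standard errors well
below the asserted margins) while staying desk-scale.

## Known limitations

* Multi-mapping reads report a single randomly chosen location with
  mapq 0; the full tied set is not emitted.
* Paired-end concordance is a tie-break heuristic, not a rescue; no
  attempt is made to recover a mate that failed the vote threshold.
* SNPs or errors in the middle of a read remove more seeds than ones
  near its ends, so mid-read variants cost votes disproportionately;
  indels cost all seeds spanning them (the rescue recovers placement
  but not votes).
* The index is held in memory; no memory-mapped or on-disk variant.
* No BAM/CRAM output and no multithreading; SAM is convertible
  downstream.
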