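---
title: "Methods: seeding, packed-cell wavefront DP, and pairing in micalite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeding, packed-cell wavefront DP, and pairing in micalite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(micalite)
```

micalite is a seed-and-extend short-read aligner built from four cooperating
pieces: an FM-index over the concatenated reference, a multi-round seed
search that tolerates *branching* and *non-branching* mismatches, an
affine-gap dynamic-programming (DP) verifier that fills its table in
anti-diagonal (wavefront) order over packed cells, and an insert-size-aware
pairing stage that decides *which* candidates are worth verifying before any
DP is spent on them. This vignette is the package's account of the model,
its parameters, and the design choices behind them.

## Reference model and FM-index

Contigs are concatenated with **no separator**; a single sentinel terminates
the whole text, so `length(bwt) == total_length + 1`. Seed hits or DP
windows that would straddle a contig boundary are filtered or clamped
instead of being prevented by separator characters. Bases are coded
A, C, G, T, N; `N` is indexed but never matched by a query, and sorts
between `T` and the sentinel.

The index stores the Burrows–Wheeler transform, a cumulative-count array,
occurrence checkpoints every `occ_rate` (default 64) rows, and suffix-array
samples every `sa_rate` (default 8) rows; unsampled positions are recovered
by LF-walking to the nearest sample. A backward-search step refines an
interval `[low, high)` per appended (leftward) character.

```{r fm}
ref <- reference(c(chr1 = "GATTACAGATTACA"))
idx <- build_fm_index(ref, occ_rate = 4L, sa_rate = 2L)
locate(idx, pattern_interval(idx, "ATTACA"))
```

## Seed search with branching and non-branching mismatches

A seed is matched right-to-left. At each step the search computes, for all
four bases, whether extending with that base keeps a non-empty interval.
The classification is:

* the read base extends: continue for free; additionally, if **two or more**
  bases extend and the branching budget (`max_bm`, default 1) is not
  exhausted, each mismatching extension is forked at the cost of one
  **branching mismatch (BM)** — the search genuinely branches;
* the read base fails and **exactly one** alternative base extends: the
  correction is forced, costs one **non-branching mismatch (NBM)**
  (`max_nbm`, default 2), and does not fork the search;
* the read base fails and several alternatives extend: each costs a BM.

The distinction matters because non-branching corrections are cheap — the
index leaves no choice — so a generous NBM budget buys sensitivity without
a combinatorial explosion, while the BM budget, which does multiply paths,
stays at one.

```{r bmnbm}
idx2 <- build_fm_index(reference(c(c1 = "ACGTGA")), 4L, 1L)
# read ACTTGA differs from the text at one position; the correction T->G is
# forced (only G extends "TGA"), so it costs an NBM, not a BM
str(search_seed(idx2, "ACTTGA", max_bm = 0L, max_nbm = 1L))
```

## Read-sensitive multi-round seeding

Rather than one seeding pass, reads descend through rounds of decreasing
seed length:

| round | seed length | overlap | occurrence limit |
|------:|------------:|--------:|-----------------:|
| 0     | 140         | 0       | 1000             |
| 1     | 80          | 0       | 1000             |
| 2     | 46          | 0       | 100              |

Long seeds are cheap and nearly always unique, so the bulk of reads resolve
in round 0; only reads the long seeds cannot place (indels, clustered
errors, repeats) pay for the more sensitive short-seed rounds. A seed whose
total occurrence count exceeds the round's limit is dropped as repetitive.
Seeds tile the read 5'→3' with a final seed anchored flush at the 3' end;
when base qualities are supplied, a seed spanning a base below the quality
floor is shifted aside when a clean placement exists. A round stops the
descent as soon as it yields a proper pair (or, single-end, an accepted
alignment).

A 3 bp insertion in the middle of a 150 bp read splits both 140 bp
round-0 seeds and both 80 bp round-1 seeds, so such reads demonstrably
resolve only in round 2:

```{r rounds}
g <- generate_genome(50000L, rng_seed = 7L)
gi <- build_fm_index(g)
read <- decode_bases(g$text[10001:10150])
broken <- paste0(substr(read, 1, 75), "GGG", substr(read, 76, 147))
align_read_single(gi, read)$round_used
align_read_single(gi, broken)$round_used
```

## Packed-cell anti-diagonal DP

Verification is a three-state Gotoh alignment, local over the read (both
ends may soft-clip for free) with free reference flanks. Default scoring:
match +1, mismatch −2, gap open −3, gap extend −1, first gap base paying
open + extend. The M, I and D scores of one cell live together as three
biased 17-bit fields of a single 64-bit word (carried exactly in a double);
out-of-range scores saturate explicitly with a warning rather than wrap.

The table is filled in anti-diagonal order: every cell on diagonal
`i + j` depends only on the two previous diagonals, so a wavefront is
computed as batches of up to `lane_width` independent cells (default 16).
The lane width is a throughput knob only — results are bit-identical for
any value — which the test suite asserts over lane widths 1, 4 and 16.

```{r dp}
tab <- fill_antidiagonal("AACCGGTT", "AACCTGGTT")
tab$best_score
dp_traceback(tab)$cigar
```

Among equal-scoring end cells, traceback prefers the cell aligning **more
of the read**, then the smaller reference coordinate, and prefers
match > deletion > insertion steps. Preferring read coverage over raw
leftmost coordinate is a deliberate package choice: it keeps determinism
while avoiding gratuitous clipping when a gapped alignment ties a clipped
one (as in the `4M1D4M` vs `4M4S` example above).

## Pair-before-DP and mate rescue

DP is the expensive step, so candidate regions from the two ends are paired
*first*: all cross pairs on one contig, opposite strands in FR layout, with
implied template length inside `mean ± n_sd·sd` (defaults 500 ± 4·25)
survive, sorted by combined seed support. Only surviving pairs are
DP-verified (up to `max_pairs_dp`). If pairing fails, the strongest
single-end candidate is verified and its mate sought by windowed DP over
the reference interval the insert band implies (**mate rescue**). The final
pair maximizes the summed score; mapping quality is
`60·(best − second)/best` over distinct loci, 0 for ambiguous placements.

## Synthetic data and evaluation

The `synthetic_data` functions are first-class: `generate_genome` (i.i.d.
bases at a target GC), `mutate_genome` (SNPs and 1–3 bp indels at given
rates, with exact donor↔reference lift-over), `simulate_read_pairs`
(FR pairs, default 150 bp reads, insert 500 ± 25, 0.5% substitution
errors — the package's study conditions) and `evaluate_alignments`
(sensitivity, FDR, proper-pair counts against truth, ±5 bp tolerance).

```{r eval}
sim <- simulate_read_pairs(g, 200L, rng_seed = 8L)
sam <- tempfile(fileext = ".sam")
align_files(gi, sim$fastq_1, sim$fastq_2, out_sam = sam)
evaluate_alignments(sam, sim$truth)
```

## Limitations

* Full-window (unbanded) DP per candidate: fine at desk scale, not tuned
  for mammalian-genome throughput; no SIMD kernels.
* CIGARs use `M` (no `X`/`=` distinction); no supplementary/secondary
  alignments, one best placement per read.
* Only FR paired-end orientation; no RF/FF libraries, no split-read or
  long-indel handling beyond the DP window margin.
* The simulator plants substitution errors only in reads (indels enter via
  the donor genome), with a two-level quality model.
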