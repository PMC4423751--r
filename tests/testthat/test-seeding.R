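test_that("seed tiling follows the step rule with a 3'-anchored final seed", {
  cfg <- round_config(140L, 0L, 1000L)
  expect_equal(tile_seeds(150L, cfg)$offset, c(0L, 10L))
  expect_equal(nrow(tile_seeds(100L, cfg)), 0L)           # round skipped
  expect_equal(tile_seeds(8L, round_config(4L, 0L))$offset, c(0L, 4L))
  expect_equal(tile_seeds(10L, round_config(4L, 2L))$offset, c(0L, 2L, 4L, 6L))
  # exact fit: no duplicate anchor
  expect_equal(tile_seeds(140L, cfg)$offset, 0L)
})

test_that("low-quality bases are shifted to seed boundaries when possible", {
  q <- rep(30L, 20L); q[9L] <- 5L
  tl <- tile_seeds(20L, round_config(8L, 0L), q, quality_floor = 13L)
  # seed originally at offset 8 spans base 9; a shift exists placing it clear
  for (k in seq_len(nrow(tl)))
    expect_false(9L %in% (tl$offset[k] + 1L):(tl$offset[k] + 8L) &&
                   tl$offset[k] != 0L)
  # unshiftable: every window contains the low base -> kept as tiled
  q2 <- rep(30L, 10L); q2[5L] <- 5L
  tl2 <- tile_seeds(10L, round_config(8L, 0L), q2, quality_floor = 13L)
  expect_equal(tl2$offset, c(0L, 2L))
  # disabled floor leaves tiling untouched
  expect_equal(tile_seeds(20L, round_config(8L, 0L), q, quality_floor = 0L)$offset,
               c(0L, 8L, 12L))
})

test_that("branching and non-branching mismatches classify as specified", {
  # branching: the step before G admits both T and A
  idx <- make_index("ATGAAG")
  h <- search_seed(idx, "ACG", max_bm = 1L, max_nbm = 0L)
  expect_equal(flatten_hits(h), c(0L, 3L))
  expect_true(all(vapply(h, `[[`, 1L, "n_bm") == 1L))
  expect_true(all(vapply(h, `[[`, 1L, "n_nbm") == 0L))
  # without the BM budget nothing is found
  expect_equal(flatten_hits(search_seed(idx, "ACG", 0L, 2L)), integer(0))

  # non-branching: only G extends "TGA"
  idx2 <- make_index("ACGTGA")
  h2 <- search_seed(idx2, "ACTTGA", max_bm = 0L, max_nbm = 1L)
  expect_equal(flatten_hits(h2), 0L)
  expect_equal(h2[[1]]$n_nbm, 1L)
  expect_equal(h2[[1]]$n_bm, 0L)

  # exact match consumes no budget
  idx3 <- make_index("ACGTACGT")
  h3 <- search_seed(idx3, "ACGT", 0L, 0L)
  expect_equal(flatten_hits(h3), c(0L, 4L))
  expect_true(all(vapply(h3, function(x) x$n_bm + x$n_nbm, 1L) == 0L))

  # a seed containing N matches nothing
  expect_equal(search_seed(idx3, "ANGT", 1L, 2L), list())
})

test_that("index seed search equals the text-space recursive oracle", {
  set.seed(606)
  for (k in 1:60) {
    g <- rand_seq(sample(200:1500, 1))
    l <- sample(8:40, 1)
    s0 <- sample(nchar(g) - l, 1)
    seed <- substr(g, s0, s0 + l - 1)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      sv <- strsplit(seed, "")[[1]]
      for (p in sample(l, nmut))
        sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1)
      seed <- paste(sv, collapse = "")
    }
    idx <- make_index(g, 16L, 4L)
    got <- search_seed(idx, seed, 1L, 2L)
    want <- oracle_seed_search(g, seed, 1L, 2L)
    key <- function(hits) {
      df <- do.call(rbind, lapply(hits, function(h)
        data.frame(pos = h$positions, bm = h$n_bm, nbm = h$n_nbm)))
      if (is.null(df)) return("")
      df <- df[order(df$pos), ]
      paste(df$pos, df$bm, df$nbm, collapse = ";")
    }
    expect_equal(key(got), key(want), info = paste(k, seed))
  }
})

test_that("seed hits grow monotonically with the mismatch budgets", {
  set.seed(707)
  for (k in 1:25) {
    g <- rand_seq(sample(300:2000, 1))
    l <- sample(10:30, 1)
    s0 <- sample(nchar(g) - l, 1)
    sv <- strsplit(substr(g, s0, s0 + l - 1), "")[[1]]
    for (p in sample(l, sample(0:2, 1)))
      sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1)
    seed <- paste(sv, collapse = "")
    idx <- make_index(g, 16L, 4L)
    h00 <- flatten_hits(search_seed(idx, seed, 0L, 0L))
    h10 <- flatten_hits(search_seed(idx, seed, 1L, 0L))
    h12 <- flatten_hits(search_seed(idx, seed, 1L, 2L))
    expect_true(all(h00 %in% h10))
    expect_true(all(h10 %in% h12))
  }
})

test_that("every reported position verifies textually with no indels", {
  set.seed(808)
  g <- rand_seq(3000)
  idx <- make_index(g, 16L, 4L)
  for (k in 1:20) {
    l <- sample(12:30, 1)
    s0 <- sample(nchar(g) - l, 1)
    sv <- strsplit(substr(g, s0, s0 + l - 1), "")[[1]]
    for (p in sample(l, sample(0:2, 1)))
      sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1)
    seed <- paste(sv, collapse = "")
    for (h in search_seed(idx, seed, 1L, 2L)) {
      for (p in h$positions) {
        there <- substr(g, p + 1, p + l)
        nm <- sum(strsplit(there, "")[[1]] != strsplit(seed, "")[[1]])
        expect_equal(nm, h$n_bm + h$n_nbm)
      }
    }
  }
})

test_that("a round nominates the true locus for a clean unique read", {
  set.seed(909)
  g <- rand_seq(5000)
  idx <- make_index(g, 64L, 8L)
  start <- 1217L
  read <- substr(g, start + 1L, start + 150L)
  cands <- run_round(idx, read, round_config(140L, 0L, 1000L))
  fwd <- cands[cands$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$est_start, start)
  expect_lte(fwd$window_start, start - 1L)
  expect_gte(fwd$window_end, start + 150L)
  # reverse-complement read found on the minus strand
  cr <- run_round(idx, revcomp(read), round_config(140L, 0L, 1000L))
  expect_true(any(cr$strand == "-" & cr$est_start == start))
  # round skipped for short reads
  expect_equal(nrow(run_round(idx, substr(read, 1, 100),
                              round_config(140L, 0L, 1000L))), 0L)
})

test_that("repetitive seeds overflowing the candidate limit are dropped", {
  g <- paste0(strrep("ACGTACGTTG", 50), rand_seq(200))
  idx <- make_index(g, 16L, 4L)
  read <- strrep("ACGTACGTTG", 5)       # 50 bp from the tandem repeat
  cands <- run_round(idx, read, round_config(40L, 0L, 10L))
  expect_equal(nrow(cands), 0L)
  # generous limit keeps them
  cands2 <- run_round(idx, read, round_config(40L, 0L, 1000L))
  expect_gt(nrow(cands2), 0L)
})

test_that("multi-round descent stops at the first productive round", {
  set.seed(1010)
  g <- rand_seq(20000)
  idx <- make_index(g, 64L, 8L)
  accept_any <- function(cands, round) if (nrow(cands) > 0L) cands else NULL

  read <- substr(g, 501L, 650L)
  out <- multi_round_candidates(idx, read, default_rounds(), accept_any)
  expect_equal(out$round_used, 0L)

  # a 3 bp insertion mid-read splits every seed of rounds 0 and 1
  broken <- paste0(substr(read, 1, 75), "GGG", substr(read, 76, 147))
  out2 <- multi_round_candidates(idx, broken, default_rounds(), accept_any)
  expect_gte(out2$round_used, 1L)
  expect_error(multi_round_candidates(idx, read, list(), accept_any),
               "non-empty")
})
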