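test_that("cell packing round-trips scores and saturates explicitly", {
  m <- c(0L, 1L, -5L, 65535L, -65535L, 123L)
  i <- c(-65536L, 0L, 7L, -1L, 65535L, -99L)
  d <- c(5L, -65536L, -65536L, 0L, 1L, 20000L)
  u <- cell_unpack(cell_pack(m, i, d))
  expect_equal(u[, "m"], m)
  expect_equal(u[, "i"], i)
  expect_equal(u[, "d"], d)
  expect_warning(cell_pack(70000L, 0L, 0L), "saturated")
  # packed words are exact doubles below 2^51
  expect_lt(max(abs(cell_pack(65535L, 65535L, 65535L))), 2^51)
})

test_that("diagonal flat offsets are a bijection onto the grid", {
  for (dims in list(c(3L, 5L), c(1L, 7L), c(6L, 6L), c(4L, 9L))) {
    m <- dims[1]; n <- dims[2]
    fl <- outer(seq_len(m), seq_len(n),
                Vectorize(function(i, j) diag_offset(i, j, m, n)))
    expect_equal(sort(as.vector(fl)), 0:(m * n - 1L))
    # cells of one diagonal are consecutive
    d <- outer(seq_len(m), seq_len(n), `+`)
    for (dd in unique(as.vector(d))) {
      v <- sort(fl[d == dd])
      if (length(v) > 1) expect_equal(diff(v), rep(1L, length(v) - 1L))
    }
  }
})

test_that("frozen small alignments score and trace as expected", {
  sc <- scoring_scheme(1L, 2L, 3L, 1L)

  # perfect match
  t1 <- fill_antidiagonal("ACGT", "ACGT", sc)
  expect_equal(t1$best_score, 4L)
  a1 <- dp_traceback(t1)
  expect_equal(a1$cigar, "4M")
  expect_equal(a1$n_mismatch, 0L)

  # short read, mid mismatch: clipping the tail beats carrying it
  t2 <- fill_antidiagonal("ACGT", "ACTT", sc)
  a2 <- dp_traceback(t2)
  expect_equal(t2$best_score, 2L)
  expect_equal(a2$cigar, "2M2S")
  expect_equal(a2$n_mismatch, 0L)

  # long flanks: carrying the substitution wins over clipping
  t2b <- fill_antidiagonal("AAAACAAAA", "AAAATAAAA", sc)
  a2b <- dp_traceback(t2b)
  expect_equal(t2b$best_score, 8L - 2L)
  expect_equal(a2b$cigar, "9M")
  expect_equal(a2b$n_mismatch, 1L)

  # read with extra base vs window: clipping beats a gap here
  t3 <- fill_antidiagonal("ACGT", "ACGAT", sc)
  expect_equal(t3$best_score, 3L)
  expect_equal(dp_traceback(t3)$cigar, "3M1S")

  # a deletion is worth opening when the flanks are long enough
  t4 <- fill_antidiagonal("AACCGGTT", "AACCTGGTT", sc)
  a4 <- dp_traceback(t4)
  expect_equal(t4$best_score, 8L - 4L)                 # 8 match - (open+ext)
  expect_equal(a4$cigar, "4M1D4M")
  expect_equal(a4$n_indel, 1L)

  # insertion in the read
  t5 <- fill_antidiagonal("AACCTGGTT", "AACCGGTTAA", sc)
  a5 <- dp_traceback(t5)
  expect_equal(a5$cigar, "4M1I4M")
  expect_equal(t5$best_score, 4L)

  # nothing aligns: all mismatches from position one
  t6 <- fill_antidiagonal("AAAA", "CCCC", sc)
  expect_false(dp_traceback(t6)$aligned)

  # N never matches, even against N
  t7 <- fill_antidiagonal("ANT", "ANT", sc)
  expect_lt(t7$best_score, 3L)
})

test_that("wavefront fill equals the row-major Gotoh oracle on random instances", {
  set.seed(111)
  for (k in 1:100) {
    m <- sample(1:60, 1)
    n <- m + sample(0:40, 1)
    read <- rand_seq(m)
    window <- rand_seq(n)
    sc <- scoring_scheme(sample(1:3, 1), sample(1:4, 1),
                         sample(2:5, 1), sample(1:2, 1))
    tab <- fill_antidiagonal(read, window, sc)
    want <- gotoh_row_major(read, window, sc$match, sc$mismatch,
                            sc$gap_open, sc$gap_extend)
    expect_equal(tab$best_score, as.integer(want$best), info = k)
    # full M matrix agreement, not just the optimum
    got <- unpack_table(tab)
    expect_true(all(pmax(got$M, -1e6) == pmax(want$M, -1e6) |
                      (got$M <= -65536 & want$M <= -1e8)), info = k)
  }
})

test_that("lane width never changes the packed table", {
  set.seed(222)
  for (k in 1:20) {
    read <- rand_seq(sample(5:80, 1))
    window <- rand_seq(nchar(read) + sample(0:60, 1))
    t1 <- fill_antidiagonal(read, window, lane_width = 1L)
    t4 <- fill_antidiagonal(read, window, lane_width = 4L)
    t16 <- fill_antidiagonal(read, window, lane_width = 16L)
    expect_identical(t1$cells, t4$cells)
    expect_identical(t4$cells, t16$cells)
    expect_identical(t1$best_score, t16$best_score)
    expect_identical(c(t1$best_i, t1$best_j), c(t16$best_i, t16$best_j))
  }
})

test_that("traceback CIGARs re-score to the reported optimum", {
  set.seed(333)
  for (k in 1:60) {
    read <- rand_seq(sample(10:80, 1))
    window <- rand_seq(nchar(read) + sample(0:50, 1))
    sc <- scoring_scheme(sample(1:2, 1), 2L, 3L, 1L)
    tab <- fill_antidiagonal(read, window, sc)
    aln <- dp_traceback(tab)
    if (!aln$aligned) {
      expect_lte(tab$best_score, 0L)
      next
    }
    expect_equal(rescore(aln$cigar, read, window, aln$win_start, sc),
                 aln$score)
    # CIGAR accounts for the whole read
    expect_equal(micalite:::cigar_read_span(aln$cigar), nchar(read))
    # no leading/trailing deletions and no adjacent I/D
    expect_false(grepl("^[0-9]+D|D$", gsub("[0-9]+S", "", aln$cigar)))
    expect_false(grepl("D[0-9]+I|I[0-9]+D", aln$cigar))
  }
})

test_that("input guards reject malformed problems", {
  expect_error(fill_antidiagonal("ACGT", "AC"), "shorter")
  expect_error(fill_antidiagonal(strrep("A", 2000), strrep("A", 2000)),
               "max_read_length")
  expect_error(scoring_scheme(match = 0), "positive")
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_open")
})

test_that("candidate alignment maps window-local hits to global coordinates", {
  set.seed(444)
  g <- rand_seq(4000)
  ref <- reference(c(chrA = g))
  start <- 1500L
  read <- substr(g, start + 1L, start + 100L)
  region <- list(window_start = start - 20L, window_end = start + 120L,
                 strand = "+")
  aln <- align_candidate(read, region, ref)
  expect_true(aln$mapped && aln$accepted)
  expect_equal(aln$ref_start, start)
  expect_equal(aln$cigar, "100M")

  # reverse-strand candidate
  regm <- list(window_start = start - 20L, window_end = start + 120L,
               strand = "-")
  alnm <- align_candidate(revcomp(read), regm, ref)
  expect_true(alnm$mapped)
  expect_equal(alnm$ref_start, start)
  expect_equal(alnm$strand, "-")
})
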