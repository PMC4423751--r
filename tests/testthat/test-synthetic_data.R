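test_that("genome generation is seed-deterministic with controlled GC", {
  g1 <- generate_genome(5000L, rng_seed = 11L)
  g2 <- generate_genome(5000L, rng_seed = 11L)
  g3 <- generate_genome(5000L, rng_seed = 12L)
  expect_identical(g1$text, g2$text)
  expect_false(identical(g1$text, g3$text))
  # GC fraction within binomial noise of the target (0.41 +/- ~0.03)
  gc <- mean(g1$text %in% c(1L, 2L))
  expect_lt(abs(gc - 0.41), 0.03)
  gh <- generate_genome(20000L, gc = 0.7, rng_seed = 13L)
  expect_lt(abs(mean(gh$text %in% c(1L, 2L)) - 0.7), 0.02)
  # contig split covers the requested length
  gm <- generate_genome(10001L, n_contigs = 3L, rng_seed = 14L)
  expect_equal(sum(gm$contigs$length), 10001L)
  expect_equal(nrow(gm$contigs), 3L)
})

test_that("donor mutation records every variant with an exact lift-over", {
  ref <- generate_genome(20000L, rng_seed = 21L)
  don <- mutate_genome(ref, snp_rate = 0.002, ins_rate = 0.0005,
                       del_rate = 0.0005, rng_seed = 22L)
  v <- don$variants
  expect_gt(nrow(v), 0L)
  # SNP count close to Poisson(L * rate): within 4 standard deviations
  n_snp <- sum(v$type == "snp")
  lam <- 20000 * 0.002
  expect_lt(abs(n_snp - lam), 4 * sqrt(lam) + 1)
  # donor length = ref length + inserted - deleted bases
  delta <- sum(nchar(v$alt_allele[v$type == "ins"])) -
    sum(nchar(v$ref_allele[v$type == "del"]))
  expect_equal(don$donor$total_length, ref$total_length + delta)
  # each SNP is planted verbatim at its recorded coordinates
  for (k in which(v$type == "snp")[1:5]) {
    expect_equal(decode_bases(don$donor$text[v$donor_pos[k] + 1L]),
                 v$alt_allele[k])
    expect_equal(decode_bases(ref$text[v$ref_pos[k] + 1L]), v$ref_allele[k])
  }
  # lift-over inverts the edit shifts exactly at copy positions
  for (k in which(v$type == "snp")[1:5])
    expect_equal(lift_to_ref(don, v$contig[k], v$donor_pos[k]), v$ref_pos[k])
  expect_error(mutate_genome(ref, snp_rate = 0.5), "0.1")
})

test_that("a single deletion shifts downstream lifted coordinates by its length", {
  ref <- reference(c(c1 = strrep("ACGT", 100)))
  # deterministic search for a seed planting exactly one deletion
  don <- NULL
  for (s in 1:200) {
    d <- mutate_genome(ref, del_rate = 0.002, rng_seed = s)
    if (nrow(d$variants) == 1L && d$variants$type == "del") { don <- d; break }
  }
  expect_false(is.null(don))
  v <- don$variants
  l <- nchar(v$ref_allele)
  expect_equal(don$donor$total_length, 400L - l)
  # before the deletion: identity; after: shifted by the deleted length
  expect_equal(lift_to_ref(don, "c1", v$donor_pos - 1L), v$ref_pos - 1L)
  expect_equal(lift_to_ref(don, "c1", v$donor_pos + 5L), v$ref_pos + l + 5L)
})

test_that("simulated pairs follow the FR layout and the insert model", {
  ref <- generate_genome(30000L, rng_seed = 31L)
  sim <- simulate_read_pairs(ref, 400L, read_len = 150L, insert_mean = 500,
                             insert_sd = 25, subst_error_rate = 0,
                             rng_seed = 32L)
  tr <- sim$truth
  expect_equal(nrow(tr), 400L)
  expect_true(all(tr$strand1 == "+"))
  expect_true(all(tr$strand2 == "-"))
  expect_equal(tr$start2 - tr$start1 + 150L, tr$insert)
  # CLT bound on the empirical insert mean: 500 +/- 4 * 25/sqrt(400)
  expect_lt(abs(mean(tr$insert) - 500), 5)
  expect_lt(abs(sd(tr$insert) - 25), 6)
  # reads are verbatim genome slices when the error rate is zero
  b <- read_batches(sim$fastq_1, sim$fastq_2)[[1]]
  for (k in 1:10) {
    off <- ref$contigs$offset[match(tr$contig[k], ref$contigs$name)]
    expect_equal(b$reads1$seq[k],
                 decode_bases(ref$text[(off + tr$start1[k] + 1L):
                                         (off + tr$start1[k] + 150L)]))
    expect_equal(b$reads2$seq[k],
                 revcomp(decode_bases(ref$text[(off + tr$start2[k] + 1L):
                                                 (off + tr$start2[k] + 150L)])))
  }
  # determinism
  sim2 <- simulate_read_pairs(ref, 400L, read_len = 150L, insert_mean = 500,
                              insert_sd = 25, subst_error_rate = 0,
                              rng_seed = 32L)
  expect_identical(sim2$truth, tr)
  expect_error(simulate_read_pairs(ref, 10L, read_len = 150L,
                                   insert_mean = 100), "insert_mean")
  expect_error(simulate_read_pairs(generate_genome(400L, rng_seed = 1L), 5L),
               "insert band")
})

test_that("substitution errors appear at close to the requested rate", {
  ref <- generate_genome(30000L, rng_seed = 41L)
  sim <- simulate_read_pairs(ref, 300L, subst_error_rate = 0.005,
                             rng_seed = 42L)
  b <- read_batches(sim$fastq_1, sim$fastq_2)[[1]]
  tr <- sim$truth
  nerr <- 0L
  for (k in seq_len(nrow(tr))) {
    off <- ref$contigs$offset[match(tr$contig[k], ref$contigs$name)]
    true1 <- decode_bases(ref$text[(off + tr$start1[k] + 1L):
                                     (off + tr$start1[k] + 150L)])
    nerr <- nerr + sum(strsplit(b$reads1$seq[k], "")[[1]] !=
                         strsplit(true1, "")[[1]])
  }
  lam <- 300 * 150 * 0.005
  expect_lt(abs(nerr - lam), 5 * sqrt(lam))
  expect_gt(nerr, 0L)
})

test_that("truth tables round-trip through TSV", {
  ref <- generate_genome(5000L, rng_seed = 51L)
  sim <- simulate_read_pairs(ref, 10L, rng_seed = 52L)
  p <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, p)
  expect_equal(read_truth(p), sim$truth)
})

test_that("the evaluator computes sensitivity and FDR by definition", {
  ref <- reference(c(chr = strrep("ACGT", 300)))
  truth <- data.frame(id = c("r1", "r2", "r3"), contig = "chr",
                      start1 = c(100L, 200L, 300L), strand1 = "+",
                      start2 = c(450L, 550L, 650L), strand2 = "-",
                      insert = 500L, stringsAsFactors = FALSE)
  # hand-built SAM: r1 both ends correct+proper; r2 end1 wrong position,
  # end2 unmapped; r3 end1 correct within tolerance, end2 wrong strand
  recs <- data.frame(
    qname = c("r1", "r1", "r2", "r2", "r3", "r3"),
    flag = c(99L, 147L, 65L, 133L, 73L, 137L),
    rname = c("chr", "chr", "chr", "*", "chr", "chr"),
    pos = c(101L, 451L, 701L, 0L, 304L, 651L),
    mapq = 60L, cigar = c("150M", "150M", "150M", "*", "150M", "150M"),
    rnext = c("=", "=", "*", "*", "=", "="),
    pnext = c(451L, 101L, 0L, 0L, 651L, 304L),
    tlen = c(500L, -500L, 0L, 0L, 0L, 0L),
    seq = strrep("A", 10), qual = strrep("I", 10),
    as = 150L, nm = 0L, round = 0L, stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".sam")
  write_sam(recs, ref, p)
  ev <- evaluate_alignments(p, truth, tolerance = 5L)
  expect_equal(ev$n_reads, 6L)
  expect_equal(ev$aligned, 5L)
  expect_equal(ev$properly_paired, 2L)
  # correct: r1 both ends, r3 end1 (304-1-300 <= 5); incorrect: r2 end1
  # (wrong position) and r3 end2 (flag 137 reports + but truth is -)
  expect_equal(ev$incorrectly_aligned, 2L)
  expect_equal(ev$sensitivity, 3 / 6)
  expect_equal(ev$fdr, 2 / 5)
  # unknown read ids are an error, not silently dropped
  bad <- recs; bad$qname[1] <- "ghost"
  pb <- tempfile(fileext = ".sam")
  write_sam(bad, ref, pb)
  expect_error(evaluate_alignments(pb, truth), "ghost")
})
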