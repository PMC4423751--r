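#' Aligner configuration
#'
#' Bundles the round schedule, mismatch budgets, scoring, insert model and
#' the pipeline knobs into one object consumed by [align_batch()] and the
#' CLI.
#'
#' @param rounds list of [round_config()] (default [default_rounds()])
#' @param max_bm,max_nbm seed mismatch budgets
#' @param scoring a [scoring_scheme()]
#' @param insert an [insert_model()]
#' @param min_score_frac DP acceptance threshold fraction
#' @param merge_tol,indel_margin candidate-region geometry (bases)
#' @param quality_floor seed-shifting quality floor (0 disables)
#' @param max_pairs_dp maximum candidate pairs verified per round
#' @param max_single_dp maximum single-end candidates verified per round
#' @param lane_width DP wavefront batch width
#' @return an `aligner_config`
#' @export
aligner_config <- function(rounds = default_rounds(), max_bm = 1L,
                           max_nbm = 2L, scoring = scoring_scheme(),
                           insert = insert_model(), min_score_frac = 0.3,
                           merge_tol = 8L, indel_margin = 16L,
                           quality_floor = 0L, max_pairs_dp = 32L,
                           max_single_dp = 8L, lane_width = 16L) {
  structure(list(rounds = rounds, max_bm = as.integer(max_bm),
                 max_nbm = as.integer(max_nbm), scoring = scoring,
                 insert = insert, min_score_frac = min_score_frac,
                 merge_tol = as.integer(merge_tol),
                 indel_margin = as.integer(indel_margin),
                 quality_floor = as.integer(quality_floor),
                 max_pairs_dp = as.integer(max_pairs_dp),
                 max_single_dp = as.integer(max_single_dp),
                 lane_width = as.integer(lane_width)),
            class = "aligner_config")
}

# DP-verify region `k` of `cands`, memoized in environment `cache`
.verify_region <- function(k, cands, read, index, cfg, cache) {
  key <- as.character(k)
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- align_candidate(read, cands[k, ], index$reference, cfg$scoring,
                         min_score_frac = cfg$min_score_frac,
                         lane_width = cfg$lane_width)
  cache[[key]] <- res
  res
}

# mapping quality from the accepted alignments DP produced for one end:
# 60 * (best - second_best) / best over distinct loci, clamped to [0, 60]
.mapq_of <- function(best, all_res) {
  if (!isTRUE(best$accepted)) return(0L)
  second <- 0L
  for (r in all_res) {
    if (!isTRUE(r$mapped)) next
    same <- identical(r$contig, best$contig) &&
      identical(r$strand, best$strand) &&
      abs(r$ref_start - best$ref_start) <= 5L
    if (same) next
    if (r$score > second) second <- r$score
  }
  if (second >= best$score) return(0L)
  max(0L, min(60L, as.integer(round(60 * (best$score - second) / best$score))))
}

#' Align one read pair through the multi-round pipeline
#'
#' For each round: run seeding on both ends, pair the candidate regions
#' under the insert model, verify paired regions by DP and accept the first
#' round that yields a proper pair; failing pairing, verify the strongest
#' single-end candidates and attempt mate rescue by windowed DP. After the
#' last round the best single-end acceptances are emitted.
#'
#' @param index an `fm_index`
#' @param read1,read2 base strings
#' @param qual1,qual2 optional integer quality vectors
#' @param cfg an [aligner_config()]
#' @return list with `aln1`, `aln2` (`alignment_result`), `proper`, `tlen`,
#'   `round_used` (0-based; NA when unmapped), `mapq1`, `mapq2`
#' @export
align_read_pair <- function(index, read1, read2, qual1 = NULL, qual2 = NULL,
                            cfg = aligner_config()) {
  rl <- c(nchar(read1), nchar(read2))
  fallback <- NULL
  for (r in seq_along(cfg$rounds)) {
    rc <- cfg$rounds[[r]]
    c1 <- run_round(index, read1, rc, cfg$max_bm, cfg$max_nbm,
                    qual1, cfg$quality_floor, cfg$merge_tol, cfg$indel_margin)
    c2 <- run_round(index, read2, rc, cfg$max_bm, cfg$max_nbm,
                    qual2, cfg$quality_floor, cfg$merge_tol, cfg$indel_margin)
    if (nrow(c1) == 0L && nrow(c2) == 0L) next
    cache1 <- new.env(parent = emptyenv())
    cache2 <- new.env(parent = emptyenv())
    prs <- pair_candidates(c1, c2, cfg$insert, rl)
    scored <- list()
    if (nrow(prs) > 0L) {
      for (k in seq_len(min(nrow(prs), cfg$max_pairs_dp))) {
        a1 <- .verify_region(prs$idx1[k], c1, read1, index, cfg, cache1)
        a2 <- .verify_region(prs$idx2[k], c2, read2, index, cfg, cache2)
        if (isTRUE(a1$accepted) && isTRUE(a2$accepted))
          scored[[length(scored) + 1L]] <- list(aln1 = a1, aln2 = a2)
      }
    }
    fin <- select_final(scored, cfg$insert)
    if (!is.null(fin) && isTRUE(fin$proper)) {
      all1 <- as.list(cache1); all2 <- as.list(cache2)
      return(list(aln1 = fin$aln1, aln2 = fin$aln2, proper = TRUE,
                  tlen = fin$tlen, round_used = r - 1L,
                  mapq1 = .mapq_of(fin$aln1, all1),
                  mapq2 = .mapq_of(fin$aln2, all2)))
    }
    # pairing failed: verify strongest single-end candidates, rescue mate
    best1 <- .best_single(c1, read1, index, cfg, cache1)
    best2 <- .best_single(c2, read2, index, cfg, cache2)
    anchor <- NULL; mate_read <- NULL; which_anchor <- 0L
    if (isTRUE(best1$accepted) &&
        (!isTRUE(best2$accepted) || best1$score >= best2$score)) {
      anchor <- best1; mate_read <- read2; which_anchor <- 1L
    } else if (isTRUE(best2$accepted)) {
      anchor <- best2; mate_read <- read1; which_anchor <- 2L
    }
    if (!is.null(anchor)) {
      resc <- mate_rescue(anchor, mate_read, index$reference, cfg$insert,
                          cfg$scoring, cfg$min_score_frac)
      a1 <- if (which_anchor == 1L) anchor else resc
      a2 <- if (which_anchor == 1L) resc else anchor
      pg <- pair_geometry(a1, a2, cfg$insert)
      if (isTRUE(pg$proper)) {
        all1 <- as.list(cache1); all2 <- as.list(cache2)
        return(list(aln1 = a1, aln2 = a2, proper = TRUE, tlen = pg$tlen,
                    round_used = r - 1L,
                    mapq1 = if (which_anchor == 1L)
                      .mapq_of(a1, all1) else 60L,
                    mapq2 = if (which_anchor == 2L)
                      .mapq_of(a2, all2) else 60L))
      }
      # keep best non-proper effort from the deepest productive round
      fallback <- list(aln1 = a1, aln2 = a2, proper = FALSE,
                       tlen = pg$tlen, round_used = r - 1L,
                       mapq1 = if (isTRUE(a1$accepted))
                         .mapq_of(a1, as.list(cache1)) else 0L,
                       mapq2 = if (isTRUE(a2$accepted))
                         .mapq_of(a2, as.list(cache2)) else 0L)
    }
  }
  if (!is.null(fallback)) {
    fallback$aln1 <- .or_unmapped(fallback$aln1, rl[1L])
    fallback$aln2 <- .or_unmapped(fallback$aln2, rl[2L])
    return(fallback)
  }
  list(aln1 = unmapped_result(rl[1L]), aln2 = unmapped_result(rl[2L]),
       proper = FALSE, tlen = NA_real_, round_used = NA_integer_,
       mapq1 = 0L, mapq2 = 0L)
}

.best_single <- function(cands, read, index, cfg, cache) {
  if (nrow(cands) == 0L) return(unmapped_result(nchar(read)))
  ord <- order(-cands$n_support)
  best <- unmapped_result(nchar(read))
  for (k in ord[seq_len(min(length(ord), cfg$max_single_dp))]) {
    res <- .verify_region(k, cands, read, index, cfg, cache)
    if (isTRUE(res$accepted) && res$score > best$score) best <- res
  }
  best
}

.or_unmapped <- function(aln, rl) {
  if (isTRUE(aln$accepted)) aln else unmapped_result(rl)
}

# ---------------------------------------------------------------------------
# FASTQ batching
# ---------------------------------------------------------------------------

#' Read paired (or single-end) FASTQ into batches
#'
#' Whole files are parsed via Biostrings and split into batches of at most
#' `batch_size` pairs (or reads); output order is preserved within and
#' across batches. The default batch size follows the aligner's
#' million-reads-per-feed design; tests and desk-scale runs use small
#' batches.
#'
#' @param fastq_1 path to the first-end FASTQ
#' @param fastq_2 optional path to the second-end FASTQ
#' @param batch_size maximum pairs per batch
#' @return list of batches; each batch is a list with `reads1`, `reads2`
#'   (data.frames of `id`, `seq`, `qual`; `reads2` NULL for single-end) and
#'   `ordinal`
#' @export
read_batches <- function(fastq_1, fastq_2 = NULL, batch_size = 1000000L) {
  r1 <- .read_fastq_df(fastq_1)
  r2 <- if (!is.null(fastq_2)) .read_fastq_df(fastq_2) else NULL
  if (!is.null(r2) && nrow(r1) != nrow(r2))
    stop(sprintf("mate record-count mismatch at pair %d (%d vs %d records)",
                 min(nrow(r1), nrow(r2)) + 1L, nrow(r1), nrow(r2)))
  n <- nrow(r1)
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = batch_size)
  lapply(seq_along(starts), function(b) {
    idx <- starts[b]:min(starts[b] + batch_size - 1L, n)
    list(reads1 = r1[idx, , drop = FALSE],
         reads2 = if (is.null(r2)) NULL else r2[idx, , drop = FALSE],
         ordinal = b)
  })
}

.read_fastq_df <- function(path) {
  is_fasta <- grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)
  if (is_fasta) {
    ss <- Biostrings::readDNAStringSet(path)
    qual <- vapply(Biostrings::width(ss),
                   function(w) strrep("I", w), character(1))
  } else {
    ss <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop(sprintf("malformed FASTQ '%s': %s", path,
                                       conditionMessage(e)), call. = FALSE))
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  }
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  ids <- sub("/[12]$", "", ids)
  data.frame(id = ids, seq = as.character(ss), qual = qual,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Batch alignment
# ---------------------------------------------------------------------------

#' Align a batch of read pairs
#'
#' Reads are independent work items: the batch is split into `workers`
#' chunks aligned in parallel and merged in input order, so results are
#' identical for any worker count.
#'
#' @param batch a batch from [read_batches()]
#' @param index an `fm_index`
#' @param cfg an [aligner_config()]
#' @param workers process count (forked; 1 = serial)
#' @param verbose emit per-batch progress (reads/sec, per-round counts)
#' @return data.frame of SAM records (see [write_sam()])
#' @export
align_batch <- function(batch, index, cfg = aligner_config(), workers = 1L,
                        verbose = FALSE) {
  n <- nrow(batch$reads1)
  paired <- !is.null(batch$reads2)
  t0 <- proc.time()[["elapsed"]]
  one <- function(i) {
    if (paired) {
      res <- align_read_pair(index, batch$reads1$seq[i], batch$reads2$seq[i],
                             .qual_to_int(batch$reads1$qual[i]),
                             .qual_to_int(batch$reads2$qual[i]), cfg)
      sam_records_pair(batch$reads1$id[i], res,
                       batch$reads1$seq[i], batch$reads1$qual[i],
                       batch$reads2$seq[i], batch$reads2$qual[i])
    } else {
      res <- align_read_single(index, batch$reads1$seq[i],
                               .qual_to_int(batch$reads1$qual[i]), cfg)
      sam_record_single(batch$reads1$id[i], res,
                        batch$reads1$seq[i], batch$reads1$qual[i])
    }
  }
  recs <- if (workers > 1L) {
    parallel::mclapply(seq_len(n), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), one)
  }
  out <- do.call(rbind, recs)
  if (verbose) {
    dt <- max(proc.time()[["elapsed"]] - t0, 1e-6)
    rounds <- out$round[!is.na(out$round)]
    cnt <- table(factor(rounds, levels = 0:(length(cfg$rounds) - 1L)))
    message(sprintf("batch %d: %d %s, %.0f reads/sec; per-round resolution: %s",
                    batch$ordinal, n, if (paired) "pairs" else "reads",
                    nrow(out) / dt,
                    paste(sprintf("r%s=%d", names(cnt), as.integer(cnt)),
                          collapse = " ")))
  }
  out
}

#' Align a single-end read
#'
#' Multi-round seeding with best-accepted-alignment stop rule; no pairing.
#'
#' @inheritParams align_read_pair
#' @param read base string
#' @param qual integer qualities or NULL
#' @return list with `aln`, `round_used`, `mapq`
#' @export
align_read_single <- function(index, read, qual = NULL,
                              cfg = aligner_config()) {
  for (r in seq_along(cfg$rounds)) {
    cands <- run_round(index, read, cfg$rounds[[r]], cfg$max_bm, cfg$max_nbm,
                       qual, cfg$quality_floor, cfg$merge_tol,
                       cfg$indel_margin)
    if (nrow(cands) == 0L) next
    cache <- new.env(parent = emptyenv())
    best <- .best_single(cands, read, index, cfg, cache)
    if (isTRUE(best$accepted))
      return(list(aln = best, round_used = r - 1L,
                  mapq = .mapq_of(best, as.list(cache))))
  }
  list(aln = unmapped_result(nchar(read)), round_used = NA_integer_,
       mapq = 0L)
}

#' Run the full pipeline: FASTQ in, SAM out
#'
#' @param index an `fm_index`
#' @param fastq_1,fastq_2 input FASTQ paths (`fastq_2` NULL for single-end)
#' @param out_sam output SAM path
#' @param cfg an [aligner_config()]
#' @param batch_size pairs per batch
#' @param workers worker count
#' @param verbose per-batch progress lines
#' @return invisibly, the output path
#' @export
align_files <- function(index, fastq_1, fastq_2 = NULL, out_sam,
                        cfg = aligner_config(), batch_size = 1000000L,
                        workers = 1L, verbose = FALSE) {
  batches <- read_batches(fastq_1, fastq_2, batch_size)
  recs <- lapply(batches, align_batch, index = index, cfg = cfg,
                 workers = workers, verbose = verbose)
  recs <- if (length(recs)) do.call(rbind, recs) else NULL
  write_sam(recs, index$reference, out_sam)
}
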