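# Fixture generator and evaluator: synthetic genomes, mutated donors,
# error-bearing paired reads with known truth, and alignment metrics.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with GC content `gc`; reproducible for a fixed
#' seed.
#'
#' @param length total genome length in bases
#' @param n_contigs number of contigs (length split evenly)
#' @param gc GC fraction in `[0, 1]`
#' @param rng_seed integer seed (NULL uses the current RNG state)
#' @return a [reference()] object
#' @export
generate_genome <- function(length, n_contigs = 1L, gc = 0.41,
                            rng_seed = NULL) {
  if (length < n_contigs) stop("length must be >= n_contigs")
  .with_seed(rng_seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    lens <- rep(length %/% n_contigs, n_contigs)
    lens[n_contigs] <- lens[n_contigs] + length %% n_contigs
    seqs <- vapply(lens, function(l)
      paste(sample(names(p), l, replace = TRUE, prob = p), collapse = ""),
      character(1))
    names(seqs) <- sprintf("contig%d", seq_len(n_contigs))
    reference(seqs)
  })
}

#' Mutate a reference into a donor genome with recorded variants
#'
#' Plants SNPs, short insertions and deletions (lengths 1-3) at the given
#' per-base rates; overlapping edits are skipped. Every variant is recorded
#' with reference and donor coordinates and the donor-to-reference
#' coordinate lift-over is exact.
#'
#' @param reference a [reference()] object
#' @param snp_rate,ins_rate,del_rate per-base event rates in `[0, 0.1]`
#' @param rng_seed integer seed
#' @return a `mica_donor`: `donor` (a [reference()]), `variants`
#'   (data.frame: contig, ref_pos, donor_pos, type, ref_allele, alt_allele),
#'   and the per-contig lift-over segments
#' @export
mutate_genome <- function(reference, snp_rate = 0, ins_rate = 0,
                          del_rate = 0, rng_seed = NULL) {
  rates <- c(snp_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.1)) stop("rates must be in [0, 0.1]")
  .with_seed(rng_seed, {
    ct <- reference$contigs
    donors <- character(nrow(ct))
    vlist <- list()
    lift <- vector("list", nrow(ct))
    for (i in seq_len(nrow(ct))) {
      L <- ct$length[i]
      refseq <- ref_fetch(reference, ct$offset[i], ct$offset[i] + L)
      u <- runif(L)
      ev <- integer(L)                       # 0 none, 1 snp, 2 ins, 3 del
      ev[u < snp_rate] <- 1L
      ev[u >= snp_rate & u < snp_rate + ins_rate] <- 2L
      ev[u >= snp_rate + ins_rate & u < snp_rate + ins_rate + del_rate] <- 3L
      pos <- which(ev > 0L)
      pieces <- list(); piece_n <- 0L
      seg_d <- integer(0); seg_r <- integer(0); seg_copy <- logical(0)
      cur_ref <- 0L                          # 0-based ref cursor
      cur_don <- 0L
      add_copy <- function(from, to) {       # ref [from, to), 0-based
        if (to <= from) return(invisible())
        piece_n <<- piece_n + 1L
        pieces[[piece_n]] <<- refseq[(from + 1L):to]
        seg_d <<- c(seg_d, cur_don); seg_r <<- c(seg_r, from)
        seg_copy <<- c(seg_copy, TRUE)
        cur_don <<- cur_don + (to - from)
      }
      for (p in pos) {
        p0 <- p - 1L                         # 0-based event position
        if (p0 < cur_ref) next               # overlaps a previous edit
        add_copy(cur_ref, p0)
        if (ev[p] == 1L) {                   # SNP
          old <- refseq[p]
          alt <- if (old >= 4L) old else sample(setdiff(0:3, old), 1L)
          piece_n <- piece_n + 1L
          pieces[[piece_n]] <- alt
          seg_d <- c(seg_d, cur_don); seg_r <- c(seg_r, p0)
          seg_copy <- c(seg_copy, TRUE)
          vlist[[length(vlist) + 1L]] <- data.frame(
            contig = ct$name[i], ref_pos = p0, donor_pos = cur_don,
            type = "snp", ref_allele = .BASE_CHARS[old + 1L],
            alt_allele = .BASE_CHARS[alt + 1L], stringsAsFactors = FALSE)
          cur_don <- cur_don + 1L
          cur_ref <- p0 + 1L
        } else if (ev[p] == 2L) {            # insertion before ref base p0
          l <- sample(1:3, 1L)
          ins <- sample(0:3, l, replace = TRUE)
          piece_n <- piece_n + 1L
          pieces[[piece_n]] <- ins
          seg_d <- c(seg_d, cur_don); seg_r <- c(seg_r, p0)
          seg_copy <- c(seg_copy, FALSE)
          vlist[[length(vlist) + 1L]] <- data.frame(
            contig = ct$name[i], ref_pos = p0, donor_pos = cur_don,
            type = "ins", ref_allele = "",
            alt_allele = decode_bases(ins), stringsAsFactors = FALSE)
          cur_don <- cur_don + l
          cur_ref <- p0
        } else {                             # deletion of ref [p0, p0+l)
          l <- min(sample(1:3, 1L), L - p0)
          vlist[[length(vlist) + 1L]] <- data.frame(
            contig = ct$name[i], ref_pos = p0, donor_pos = cur_don,
            type = "del",
            ref_allele = decode_bases(refseq[(p0 + 1L):(p0 + l)]),
            alt_allele = "", stringsAsFactors = FALSE)
          cur_ref <- p0 + l
        }
      }
      add_copy(cur_ref, L)
      donors[i] <- decode_bases(unlist(pieces[seq_len(piece_n)],
                                       use.names = FALSE))
      lift[[i]] <- list(donor_start = seg_d, ref_start = seg_r,
                        is_copy = seg_copy)
    }
    names(donors) <- ct$name
    variants <- if (length(vlist)) do.call(rbind, vlist) else
      data.frame(contig = character(0), ref_pos = integer(0),
                 donor_pos = integer(0), type = character(0),
                 ref_allele = character(0), alt_allele = character(0),
                 stringsAsFactors = FALSE)
    names(lift) <- ct$name
    structure(list(donor = reference(donors), variants = variants,
                   lift = lift, reference = reference),
              class = "mica_donor")
  })
}

#' Lift a donor coordinate to the reference
#'
#' @param donor a `mica_donor` from [mutate_genome()]
#' @param contig contig name
#' @param dpos donor 0-based position(s)
#' @return reference 0-based position(s); positions inside an insertion
#'   project to the attachment point
#' @export
lift_to_ref <- function(donor, contig, dpos) {
  lf <- donor$lift[[contig]]
  if (is.null(lf)) stop("unknown contig: ", contig)
  i <- findInterval(dpos, lf$donor_start)
  ifelse(lf$is_copy[i], lf$ref_start[i] + (dpos - lf$donor_start[i]),
         lf$ref_start[i])
}

#' Simulate error-bearing paired-end reads with truth
#'
#' FR orientation: the first mate is the forward prefix of the fragment and
#' the second mate the reverse complement of its suffix. Per-base
#' substitution errors at `subst_error_rate`; base qualities are constant
#' Q30 with a `low_q_frac` fraction of Q10 positions. Truth carries the
#' reference-projected start and strand of each mate.
#'
#' @param donor a `mica_donor` from [mutate_genome()], or a plain
#'   [reference()] (treated as an unmutated donor)
#' @param n_pairs number of pairs
#' @param read_len read length
#' @param insert_mean,insert_sd insert-size distribution (bases)
#' @param subst_error_rate per-base substitution error rate
#' @param low_q_frac fraction of positions given quality Q10
#' @param rng_seed integer seed
#' @param fastq_1,fastq_2 output FASTQ paths
#' @return invisibly, a list with `truth` (data.frame: id, contig, start1,
#'   strand1, start2, strand2, insert) and the two paths
#' @export
simulate_read_pairs <- function(donor, n_pairs, read_len = 150L,
                                insert_mean = 500, insert_sd = 25,
                                subst_error_rate = 0.005, low_q_frac = 0,
                                rng_seed = NULL,
                                fastq_1 = tempfile(fileext = "_1.fq"),
                                fastq_2 = tempfile(fileext = "_2.fq")) {
  if (inherits(donor, "mica_reference")) {
    identity_lift <- lapply(seq_len(nrow(donor$contigs)), function(i)
      list(donor_start = 0L, ref_start = 0L, is_copy = TRUE))
    names(identity_lift) <- donor$contigs$name
    donor <- structure(list(donor = donor, lift = identity_lift,
                            reference = donor,
                            variants = NULL), class = "mica_donor")
  }
  dref <- donor$donor
  if (insert_mean < read_len) stop("insert_mean must be >= read_len")
  band_hi <- insert_mean + 4 * insert_sd
  if (min(dref$contigs$length) < band_hi)
    stop("donor contig shorter than the insert band")
  .with_seed(rng_seed, {
    ct <- dref$contigs
    ci <- sample.int(nrow(ct), n_pairs, replace = TRUE, prob = ct$length)
    inserts <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                         read_len), ct$length[ci])
    starts <- floor(runif(n_pairs) * (ct$length[ci] - inserts + 1))
    ids <- sprintf("sim_%06d", seq_len(n_pairs))
    s1 <- character(n_pairs); s2 <- character(n_pairs)
    q1 <- character(n_pairs); q2 <- character(n_pairs)
    t1 <- integer(n_pairs); t2 <- integer(n_pairs)
    add_errors <- function(x) {
      hit <- which(runif(length(x)) < subst_error_rate & x < 4L)
      for (h in hit) x[h] <- sample(setdiff(0:3, x[h]), 1L)
      x
    }
    mk_qual <- function(l) {
      q <- rep(30L, l)
      if (low_q_frac > 0) q[runif(l) < low_q_frac] <- 10L
      .int_to_qual(q)
    }
    for (k in seq_len(n_pairs)) {
      off <- ct$offset[ci[k]]
      frag <- dref$text[(off + starts[k] + 1L):(off + starts[k] + inserts[k])]
      r1 <- add_errors(frag[seq_len(read_len)])
      r2 <- add_errors(revcomp_int(frag[(inserts[k] - read_len + 1L):inserts[k]]))
      s1[k] <- decode_bases(r1); s2[k] <- decode_bases(r2)
      q1[k] <- mk_qual(read_len); q2[k] <- mk_qual(read_len)
      t1[k] <- lift_to_ref(donor, ct$name[ci[k]], starts[k])
      t2[k] <- lift_to_ref(donor, ct$name[ci[k]],
                           starts[k] + inserts[k] - read_len)
    }
    .write_fastq(fastq_1, ids, s1, q1)
    .write_fastq(fastq_2, ids, s2, q2)
    truth <- data.frame(id = ids, contig = ct$name[ci],
                        start1 = t1, strand1 = "+",
                        start2 = t2, strand2 = "-",
                        insert = inserts, stringsAsFactors = FALSE)
    invisible(list(truth = truth, fastq_1 = fastq_1, fastq_2 = fastq_2))
  })
}

.write_fastq <- function(path, ids, seqs, quals) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write / read a truth table as TSV
#' @param truth data.frame from [simulate_read_pairs()]
#' @param path TSV path
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Evaluate alignments against simulation truth
#'
#' A mapped read is correct iff it reports the true contig and strand and
#' its leftmost position is within `tolerance` bases of the truth.
#' Sensitivity is correct reads over all simulated reads; FDR is incorrect
#' reads over mapped reads; unmapped reads count against sensitivity only.
#'
#' @param sam_path SAM file produced by the aligner
#' @param truth truth data.frame (or TSV path) from [simulate_read_pairs()]
#' @param tolerance position tolerance in bases (default 5)
#' @return an `eval_report`: `n_reads`, `aligned`, `properly_paired`,
#'   `incorrectly_aligned`, `sensitivity`, `fdr`
#' @export
evaluate_alignments <- function(sam_path, truth, tolerance = 5L) {
  if (is.character(truth)) truth <- read_truth(truth)
  sam <- read_sam(sam_path)
  if (nrow(sam) == 0L)
    return(structure(list(n_reads = 0L, aligned = 0L, properly_paired = 0L,
                          incorrectly_aligned = 0L, sensitivity = NA_real_,
                          fdr = NA_real_), class = "eval_report"))
  ti <- match(sam$qname, truth$id)
  if (anyNA(ti))
    stop("read id absent from truth: ", sam$qname[which(is.na(ti))[1L]])
  second <- bitwAnd(sam$flag, 128L) > 0L
  true_start <- ifelse(second, truth$start2[ti], truth$start1[ti])
  true_strand <- ifelse(second, truth$strand2[ti], truth$strand1[ti])
  mapped <- bitwAnd(sam$flag, 4L) == 0L
  strand <- ifelse(bitwAnd(sam$flag, 16L) > 0L, "-", "+")
  correct <- mapped & sam$rname == truth$contig[ti] &
    strand == true_strand & abs(sam$pos - 1L - true_start) <= tolerance
  aligned <- sum(mapped)
  incorrect <- sum(mapped & !correct)
  structure(list(
    n_reads = nrow(sam),
    aligned = aligned,
    properly_paired = sum(bitwAnd(sam$flag, 2L) > 0L),
    incorrectly_aligned = incorrect,
    sensitivity = sum(correct) / nrow(sam),
    fdr = if (aligned > 0L) incorrect / aligned else 0
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d reads\n",
                     "  aligned:             %d\n",
                     "  properly paired:     %d\n",
                     "  incorrectly aligned: %d\n",
                     "  sensitivity:         %.4f\n",
                     "  FDR:                 %.4f\n"),
              x$n_reads, x$aligned, x$properly_paired,
              x$incorrectly_aligned, x$sensitivity, x$fdr))
  invisible(x)
}
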