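#' Insert-size model for paired-end data
#'
#' The acceptance band is `[mean - n_sd * sd, mean + n_sd * sd]`, floored at
#' zero, in FR orientation (forward-strand mate leftmost).
#'
#' @param mean insert (template) length mean in bases
#' @param sd standard deviation in bases
#' @param n_sd band half-width in standard deviations
#' @param orientation only "FR" is supported
#' @return an `insert_model`
#' @export
insert_model <- function(mean = 500L, sd = 25L, n_sd = 4L,
                         orientation = "FR") {
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (!identical(orientation, "FR")) stop("only FR orientation is supported")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n_sd = as.numeric(n_sd), orientation = orientation,
                 lo = max(0, mean - n_sd * sd), hi = mean + n_sd * sd),
            class = "insert_model")
}

#' Pair candidate regions from the two ends before DP
#'
#' Forms all cross pairs of candidate regions lying on the same contig, on
#' opposite strands in FR layout, whose implied template length falls inside
#' the insert band. Pairing before verification avoids running DP on loci
#' that cannot form a proper pair. Results are sorted by combined seed
#' support, then by leftmost coordinate.
#'
#' @param cands_1,cands_2 candidate data.frames from [run_round()] for each end
#' @param model an [insert_model()]
#' @param read_lengths integer vector of length 2
#' @return data.frame with `idx1`, `idx2` (row indices into the inputs),
#'   `implied_tlen`, `support`, `left_start`
#' @export
pair_candidates <- function(cands_1, cands_2, model, read_lengths) {
  empty <- data.frame(idx1 = integer(0), idx2 = integer(0),
                      implied_tlen = numeric(0), support = integer(0),
                      left_start = integer(0))
  if (nrow(cands_1) == 0L || nrow(cands_2) == 0L) return(empty)
  out <- empty
  for (a in seq_len(nrow(cands_1))) for (b in seq_len(nrow(cands_2))) {
    r1 <- cands_1[a, ]; r2 <- cands_2[b, ]
    if (r1$contig != r2$contig || r1$strand == r2$strand) next
    if (r1$strand == "+") {
      fs <- r1$est_start; re <- r2$est_start + read_lengths[2L]
    } else {
      fs <- r2$est_start; re <- r1$est_start + read_lengths[1L]
    }
    tlen <- re - fs
    if (tlen < model$lo || tlen > model$hi) next
    out <- rbind(out, data.frame(
      idx1 = a, idx2 = b, implied_tlen = tlen,
      support = r1$n_support + r2$n_support,
      left_start = min(r1$est_start, r2$est_start)))
  }
  out[order(-out$support, out$left_start), , drop = FALSE]
}

#' Rescue an unpaired mate by windowed DP
#'
#' Aligns the mate (oriented per FR) against the reference window implied by
#' the anchored alignment and the insert band; returns an unmapped result
#' when the best alignment falls below the acceptance threshold or the
#' window leaves the anchored contig.
#'
#' @param anchored an accepted `alignment_result`
#' @param mate_read base string (original orientation)
#' @param reference a [reference()] object
#' @param model an [insert_model()]
#' @param scoring a [scoring_scheme()]
#' @param min_score_frac acceptance threshold fraction
#' @return an `alignment_result` for the mate
#' @export
mate_rescue <- function(anchored, mate_read, reference, model,
                        scoring = scoring_scheme(), min_score_frac = 0.3) {
  if (!isTRUE(anchored$accepted)) stop("anchor alignment not accepted")
  mlen <- nchar(mate_read)
  if (anchored$strand == "+") {
    ws <- anchored$ref_start + model$lo - mlen
    we <- anchored$ref_start + model$hi
    strand <- "-"
  } else {
    aend <- anchored$ref_start + cigar_ref_span(anchored$cigar)
    ws <- aend - model$hi
    we <- aend - model$lo + mlen
    strand <- "+"
  }
  region <- list(window_start = floor(ws), window_end = ceiling(we),
                 strand = strand)
  # clamp to the anchored contig
  ci <- match(anchored$contig, reference$contigs$name)
  clo <- reference$contigs$offset[ci]
  chi <- clo + reference$contigs$length[ci]
  region$window_start <- max(region$window_start, clo)
  region$window_end <- min(region$window_end, chi)
  if (region$window_end - region$window_start < mlen)
    return(unmapped_result(mlen))
  res <- align_candidate(mate_read, region, reference, scoring,
                         min_score_frac = min_score_frac)
  if (!isTRUE(res$accepted)) return(unmapped_result(mlen))
  res
}

#' Select the final pair among scored candidates
#'
#' Picks the pair maximizing the summed alignment score; the proper-pair
#' flag requires both ends accepted, same contig, FR orientation and
#' template length inside the band. Ties break by leftmost coordinate, then
#' forward-strand-first on end one.
#'
#' @param pairs_scored list of `list(aln1 =, aln2 =)` `alignment_result` pairs
#' @param model an [insert_model()]
#' @return list with `aln1`, `aln2`, `proper`, `tlen` (NA when no pair
#'   qualifies), or NULL when the input is empty
#' @export
select_final <- function(pairs_scored, model) {
  if (length(pairs_scored) == 0L) return(NULL)
  score <- vapply(pairs_scored, function(p)
    (if (isTRUE(p$aln1$accepted)) p$aln1$score else 0L) +
    (if (isTRUE(p$aln2$accepted)) p$aln2$score else 0L), numeric(1))
  lm <- vapply(pairs_scored, function(p)
    min(p$aln1$ref_start, p$aln2$ref_start, na.rm = TRUE), numeric(1))
  fwd1 <- vapply(pairs_scored, function(p)
    identical(p$aln1$strand, "+"), logical(1))
  ord <- order(-score, lm, !fwd1)
  best <- pairs_scored[[ord[1L]]]
  pr <- pair_geometry(best$aln1, best$aln2, model)
  list(aln1 = best$aln1, aln2 = best$aln2,
       proper = pr$proper, tlen = pr$tlen)
}

#' Proper-pair geometry of two alignments under an insert model
#' @keywords internal
pair_geometry <- function(aln1, aln2, model) {
  if (!isTRUE(aln1$accepted) || !isTRUE(aln2$accepted) ||
      !identical(aln1$contig, aln2$contig) ||
      identical(aln1$strand, aln2$strand))
    return(list(proper = FALSE, tlen = NA_real_))
  fwd <- if (aln1$strand == "+") aln1 else aln2
  rev <- if (aln1$strand == "+") aln2 else aln1
  tlen <- (rev$ref_start + cigar_ref_span(rev$cigar)) - fwd$ref_start
  proper <- tlen >= model$lo && tlen <= model$hi &&
    fwd$ref_start <= rev$ref_start + cigar_ref_span(rev$cigar)
  list(proper = proper, tlen = tlen)
}
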