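# SAM flag bits
.F_PAIRED <- 1L; .F_PROPER <- 2L; .F_UNMAP <- 4L; .F_MUNMAP <- 8L
.F_REV <- 16L; .F_MREV <- 32L; .F_FIRST <- 64L; .F_SECOND <- 128L

.sam_cols <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), as = integer(0),
             nm = integer(0), round = integer(0), stringsAsFactors = FALSE)
}

.orient_seq <- function(seq, qual, strand) {
  if (identical(strand, "-")) list(seq = revcomp(seq),
                                   qual = paste(rev(strsplit(qual, "")[[1]]),
                                                collapse = ""))
  else list(seq = seq, qual = qual)
}

#' Build the two SAM records of an aligned pair
#' @keywords internal
sam_records_pair <- function(id, res, seq1, qual1, seq2, qual2) {
  a1 <- res$aln1; a2 <- res$aln2
  m1 <- isTRUE(a1$accepted); m2 <- isTRUE(a2$accepted)
  f1 <- .F_PAIRED + .F_FIRST; f2 <- .F_PAIRED + .F_SECOND
  if (isTRUE(res$proper)) { f1 <- f1 + .F_PROPER; f2 <- f2 + .F_PROPER }
  if (!m1) { f1 <- f1 + .F_UNMAP; f2 <- f2 + .F_MUNMAP }
  if (!m2) { f2 <- f2 + .F_UNMAP; f1 <- f1 + .F_MUNMAP }
  if (m1 && identical(a1$strand, "-")) { f1 <- f1 + .F_REV; f2 <- f2 + .F_MREV }
  if (m2 && identical(a2$strand, "-")) { f2 <- f2 + .F_REV; f1 <- f1 + .F_MREV }
  # TLEN, leftmost convention: leftmost segment positive, other negative
  t1 <- t2 <- 0L
  if (m1 && m2 && identical(a1$contig, a2$contig) && !is.na(res$tlen)) {
    tl <- as.integer(res$tlen)
    if (a1$ref_start <= a2$ref_start) { t1 <- tl; t2 <- -tl }
    else { t1 <- -tl; t2 <- tl }
  }
  o1 <- .orient_seq(seq1, qual1, if (m1) a1$strand else "+")
  o2 <- .orient_seq(seq2, qual2, if (m2) a2$strand else "+")
  rn1 <- if (m1) a1$contig else "*"
  rn2 <- if (m2) a2$contig else "*"
  rnext1 <- if (!m2) "*" else if (identical(rn1, rn2)) "=" else rn2
  rnext2 <- if (!m1) "*" else if (identical(rn1, rn2)) "=" else rn1
  rbind(
    data.frame(qname = id, flag = f1, rname = rn1,
               pos = if (m1) a1$local_start + 1L else 0L,
               mapq = if (m1) res$mapq1 else 0L,
               cigar = if (m1) a1$cigar else "*",
               rnext = rnext1, pnext = if (m2) a2$local_start + 1L else 0L,
               tlen = t1, seq = o1$seq, qual = o1$qual,
               as = if (m1) a1$score else 0L,
               nm = if (m1) a1$n_mismatch + a1$n_indel else NA_integer_,
               round = res$round_used, stringsAsFactors = FALSE),
    data.frame(qname = id, flag = f2, rname = rn2,
               pos = if (m2) a2$local_start + 1L else 0L,
               mapq = if (m2) res$mapq2 else 0L,
               cigar = if (m2) a2$cigar else "*",
               rnext = rnext2, pnext = if (m1) a1$local_start + 1L else 0L,
               tlen = t2, seq = o2$seq, qual = o2$qual,
               as = if (m2) a2$score else 0L,
               nm = if (m2) a2$n_mismatch + a2$n_indel else NA_integer_,
               round = res$round_used, stringsAsFactors = FALSE))
}

#' @keywords internal
sam_record_single <- function(id, res, seq, qual) {
  a <- res$aln
  m <- isTRUE(a$accepted)
  f <- if (m) { if (identical(a$strand, "-")) .F_REV else 0L } else .F_UNMAP
  o <- .orient_seq(seq, qual, if (m) a$strand else "+")
  data.frame(qname = id, flag = f, rname = if (m) a$contig else "*",
             pos = if (m) a$local_start + 1L else 0L,
             mapq = if (m) res$mapq else 0L,
             cigar = if (m) a$cigar else "*",
             rnext = "*", pnext = 0L, tlen = 0L,
             seq = o$seq, qual = o$qual,
             as = if (m) a$score else 0L,
             nm = if (m) a$n_mismatch + a$n_indel else NA_integer_,
             round = res$round_used, stringsAsFactors = FALSE)
}

#' Write SAM records to a file
#'
#' Emits an @HD/@SQ/@PG header (one @SQ per reference contig with exact
#' lengths) followed by the 11 mandatory fields plus AS (alignment score),
#' NM (edit distance) and XR (seeding round used) tags.
#'
#' @param records data.frame from [align_batch()] (NULL writes a valid
#'   header-only file)
#' @param reference a [reference()] object (for the @SQ lines)
#' @param path output path ("-" for stdout)
#' @param pg_cl command line recorded in the @PG line
#' @return invisibly, the path
#' @export
write_sam <- function(records, reference, path, pg_cl = "micalite") {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d",
                   reference$contigs$name, reference$contigs$length),
           sprintf("@PG\tID:micalite\tPN:micalite\tVN:0.1.0\tCL:%s", pg_cl))
  body <- character(0)
  if (!is.null(records) && nrow(records) > 0L) {
    tags <- sprintf("AS:i:%d", records$as)
    tags <- paste0(tags, ifelse(is.na(records$nm), "",
                                sprintf("\tNM:i:%d", records$nm)))
    tags <- paste0(tags, ifelse(is.na(records$round), "",
                                sprintf("\tXR:i:%d", records$round)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
                    records$qname, records$flag, records$rname, records$pos,
                    records$mapq, records$cigar, records$rnext,
                    records$pnext, records$tlen, records$seq, records$qual,
                    tags)
  }
  con <- if (identical(path, "-")) stdout() else file(path, "w")
  if (!identical(path, "-")) on.exit(close(con))
  tryCatch(writeLines(c(hdr, body), con),
           error = function(e) stop(sprintf("cannot write SAM to '%s': %s",
                                            path, conditionMessage(e)),
                                    call. = FALSE))
  invisible(path)
}

#' Parse a SAM file into a data.frame
#'
#' Mandatory 11 fields plus raw tag strings; header lines are returned as an
#' attribute.
#'
#' @param path SAM path
#' @return data.frame with the mandatory fields (`pos` kept 1-based)
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    out <- .sam_cols()
    attr(out, "header") <- hdr
    return(out)
  }
  parts <- strsplit(body, "\t")
  get <- function(i) vapply(parts, `[[`, "", i)
  out <- data.frame(
    qname = get(1L), flag = as.integer(get(2L)), rname = get(3L),
    pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
    cigar = get(6L), rnext = get(7L), pnext = as.integer(get(8L)),
    tlen = as.integer(get(9L)), seq = get(10L), qual = get(11L),
    tags = vapply(parts, function(p)
      paste(p[-(1:11)], collapse = "\t"), ""),
    stringsAsFactors = FALSE)
  attr(out, "header") <- hdr
  out
}
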