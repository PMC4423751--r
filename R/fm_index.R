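#' Build an FM-index over a reference
#'
#' Constructs the suffix array (prefix doubling), the Burrows-Wheeler
#' transform, the cumulative character counts, occurrence checkpoints every
#' `occ_rate` positions and suffix-array samples every `sa_rate` rows, over
#' the concatenated contigs plus a terminal sentinel. N bases are carried in
#' the text under a code that no query base matches, so seeds never match
#' through N runs; candidate windows overlapping N remain alignable by DP
#' with N scoring as a mismatch.
#'
#' @param reference a [reference()] object
#' @param occ_rate occurrence checkpoint spacing (positions)
#' @param sa_rate suffix-array sampling rate (rows)
#' @return an object of class `fm_index`
#' @examples
#' idx <- build_fm_index(reference(c(chr1 = "GATTACA")))
#' locate(idx, pattern_interval(idx, "TA"))
#' @export
build_fm_index <- function(reference, occ_rate = 64L, sa_rate = 8L) {
  if (!inherits(reference, "mica_reference")) stop("not a mica_reference")
  occ_rate <- as.integer(occ_rate); sa_rate <- as.integer(sa_rate)
  if (occ_rate < 1L || sa_rate < 1L) stop("rates must be positive")
  sa <- sa_build_cpp(reference$text)
  bwt <- bwt_from_sa_cpp(reference$text, sa)
  n <- length(bwt)
  # cumulative counts in sort order $ < A < C < G < T < N:
  # count[k+1] = number of bwt characters with order < k (k = 0..5)
  tab <- tabulate(bwt + 1L, nbins = 6L)        # counts for A,C,G,T,N,$
  ordered <- c(tab[6L], tab[1:5])              # $,A,C,G,T,N
  cnt <- as.integer(cumsum(c(0L, ordered[1:5])))
  structure(list(
    bwt = bwt,
    count = cnt,
    occ = occ_build_cpp(bwt, occ_rate),
    occ_rate = occ_rate,
    sa_samples = sa[seq(1L, n, by = sa_rate)],
    sa_rate = sa_rate,
    n = n,
    reference = reference
  ), class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("<fm_index> %d bp + sentinel, occ_rate=%d, sa_rate=%d\n",
              x$n - 1L, x$occ_rate, x$sa_rate))
  print(x$reference)
  invisible(x)
}

#' Suffix-array interval
#'
#' Half-open row range `[low, high)`; its width is the occurrence count of
#' the represented pattern.
#'
#' @param low,high row bounds, 0-based, `0 <= low <= high`
#' @return an object of class `sa_interval`
#' @export
sa_interval <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (low < 0L || high < low) stop("invalid interval")
  structure(list(low = low, high = high), class = "sa_interval")
}

#' Interval of the empty pattern (all rows)
#' @param index an `fm_index`
#' @export
full_interval <- function(index) sa_interval(0L, index$n)

#' Width (occurrence count) of an interval
#' @param interval an `sa_interval`
#' @export
interval_width <- function(interval) interval$high - interval$low

#' Backward-extend an interval by one base
#'
#' Prepends `base` to the represented pattern; the returned interval's width
#' equals the occurrence count of the extended pattern (empty when the
#' extension does not occur in the reference).
#'
#' @param index an `fm_index`
#' @param interval current `sa_interval`
#' @param base single character in A/C/G/T
#' @return the refined `sa_interval`
#' @export
backward_extend <- function(index, interval, base) {
  if (interval$high > index$n) stop("invalid interval")
  b <- match(toupper(base), c("A", "C", "G", "T")) - 1L
  if (is.na(b)) stop("base must be one of A/C/G/T")
  r <- backward_extend_cpp(index$bwt, index$occ, index$count, index$occ_rate,
                           interval$low, interval$high, b)
  sa_interval(r[1L], r[2L])
}

#' Exact backward search of a pattern
#'
#' @param index an `fm_index`
#' @param pattern base string over A/C/G/T (a pattern containing N matches
#'   nothing and yields an empty interval)
#' @return the `sa_interval` of the pattern
#' @export
pattern_interval <- function(index, pattern) {
  p <- encode_bases(pattern)
  if (any(p == 4L)) return(sa_interval(0L, 0L))
  iv <- full_interval(index)
  for (k in rev(seq_along(p))) {
    r <- backward_extend_cpp(index$bwt, index$occ, index$count, index$occ_rate,
                             iv$low, iv$high, p[k])
    iv <- sa_interval(r[1L], r[2L])
    if (interval_width(iv) == 0L) break
  }
  iv
}

#' Locate the text positions of an interval
#'
#' Walks the LF-mapping from each row to the nearest sampled suffix-array
#' row. When the interval is wider than `limit` a distinguished overflow
#' marker is returned instead of positions (this implements the per-seed
#' occurrence limit of the round table).
#'
#' @param index an `fm_index`
#' @param interval an `sa_interval`
#' @param limit maximum occurrence count to report
#' @return sorted integer vector of global 0-based positions, or an
#'   overflow marker (test with [is_overflow()])
#' @export
locate <- function(index, interval, limit = Inf) {
  w <- interval_width(interval)
  if (w == 0L) return(integer(0))
  if (w > limit) return(structure(list(width = w), class = "mica_overflow"))
  sort(locate_cpp(index$bwt, index$occ, index$count, index$occ_rate,
                  index$sa_samples, index$sa_rate,
                  interval$low, interval$high))
}

#' Test for the locate/seed overflow marker
#' @param x object returned by [locate()] or carried by a seed hit
#' @export
is_overflow <- function(x) inherits(x, "mica_overflow")

# ---------------------------------------------------------------------------
# Serialization: binary index file with magic, version, rates, contig table.
# ---------------------------------------------------------------------------

.IDX_MAGIC <- "MICALIDX"
.IDX_VERSION <- 1L

#' Save an FM-index to a binary file
#' @param index an `fm_index`
#' @param path output path
#' @export
save_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.IDX_MAGIC), con)
  writeBin(c(.IDX_VERSION, index$occ_rate, index$sa_rate, index$n), con,
           size = 4L)
  ct <- index$reference$contigs
  writeBin(nrow(ct), con, size = 4L)
  for (i in seq_len(nrow(ct))) {
    nm <- charToRaw(ct$name[i])
    writeBin(length(nm), con, size = 4L)
    writeBin(nm, con)
    writeBin(c(ct$length[i], ct$offset[i]), con, size = 4L)
  }
  writeBin(length(index$reference$text), con, size = 4L)
  writeBin(index$reference$text, con, size = 4L)
  writeBin(index$bwt, con, size = 4L)
  writeBin(index$count, con, size = 4L)
  writeBin(length(index$sa_samples), con, size = 4L)
  writeBin(index$sa_samples, con, size = 4L)
  invisible(path)
}

#' Load an FM-index from a binary file
#'
#' Occurrence checkpoints are rebuilt deterministically from the stored BWT
#' at the stored rate; all other fields are restored verbatim.
#'
#' @param path path written by [save_index()]
#' @return an `fm_index`
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(.IDX_MAGIC)))
  if (!identical(magic, .IDX_MAGIC)) stop("not a micalite index file: ", path)
  hdr <- readBin(con, "integer", n = 4L, size = 4L)
  if (length(hdr) < 4L) stop("truncated index file: ", path)
  if (hdr[1L] != .IDX_VERSION)
    stop(sprintf("index version %d unsupported (expected %d)",
                 hdr[1L], .IDX_VERSION))
  occ_rate <- hdr[2L]; sa_rate <- hdr[3L]; n <- hdr[4L]
  nct <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(nct) != 1L || nct < 1L) stop("truncated index file: ", path)
  nm <- character(nct); len <- integer(nct); off <- integer(nct)
  for (i in seq_len(nct)) {
    l <- readBin(con, "integer", n = 1L, size = 4L)
    if (length(l) != 1L) stop("truncated index file: ", path)
    nm[i] <- rawToChar(readBin(con, "raw", n = l))
    v <- readBin(con, "integer", n = 2L, size = 4L)
    if (length(v) != 2L) stop("truncated index file: ", path)
    len[i] <- v[1L]; off[i] <- v[2L]
  }
  tl <- readBin(con, "integer", n = 1L, size = 4L)
  text <- readBin(con, "integer", n = tl, size = 4L)
  bwt <- readBin(con, "integer", n = n, size = 4L)
  cnt <- readBin(con, "integer", n = 6L, size = 4L)
  nsa <- readBin(con, "integer", n = 1L, size = 4L)
  sa_samples <- readBin(con, "integer", n = nsa, size = 4L)
  if (length(text) != tl || length(bwt) != n || length(cnt) != 6L ||
      length(nsa) != 1L || length(sa_samples) != nsa)
    stop("truncated index file: ", path)
  ref <- structure(list(
    contigs = data.frame(name = nm, length = len, offset = off,
                         stringsAsFactors = FALSE),
    text = text, total_length = tl
  ), class = "mica_reference")
  structure(list(
    bwt = bwt, count = cnt,
    occ = occ_build_cpp(bwt, occ_rate), occ_rate = occ_rate,
    sa_samples = sa_samples, sa_rate = sa_rate,
    n = n, reference = ref
  ), class = "fm_index")
}
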