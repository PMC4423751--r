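#' Affine-gap scoring scheme
#'
#' Penalties are stored as positive magnitudes. A gap of length g costs
#' `gap_open + g * gap_extend` (open plus extend on the first gap base).
#' N scores as a mismatch against anything, including N.
#'
#' @param match match score (> 0)
#' @param mismatch mismatch penalty (> 0)
#' @param gap_open gap-open penalty (>= gap_extend)
#' @param gap_extend gap-extension penalty (> 0)
#' @return a `scoring_scheme` object
#' @export
scoring_scheme <- function(match = 1L, mismatch = 2L, gap_open = 3L,
                           gap_extend = 1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match must be positive")
  if (mismatch <= 0L || gap_open <= 0L || gap_extend <= 0L)
    stop("penalties must be positive")
  if (gap_open < gap_extend) stop("need gap_open >= gap_extend")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Pack M/I/D scores into single cell words
#'
#' Three biased 17-bit fields co-resident in one 64-bit word (carried as an
#' exact double). Values outside the representable range saturate explicitly
#' and raise a warning; there is no silent wraparound.
#'
#' @param m,i,d integer score vectors of equal length
#' @return numeric vector of packed cell words
#' @export
cell_pack <- function(m, i, d) {
  out <- cell_pack_cpp(as.integer(m), as.integer(i), as.integer(d))
  if (isTRUE(attr(out, "saturated")))
    warning("cell score saturated at representation bound")
  attr(out, "saturated") <- NULL
  out
}

#' Unpack cell words into M/I/D scores
#' @param x numeric vector of packed cell words
#' @return integer matrix with columns `m`, `i`, `d`
#' @export
cell_unpack <- function(x) cell_unpack_cpp(as.numeric(x))

#' Fill the alignment table in anti-diagonal (wavefront) order
#'
#' All three affine matrices are computed cell by cell in diagonal order and
#' stored packed in a single array; every cell on a diagonal depends only on
#' the two previous diagonals, so each wavefront is filled as a sequence of
#' batched lane computations of up to `lane_width` cells. Results are
#' identical for any lane width. The alignment is local over the read (free
#' soft clips at both ends) with free reference flanks.
#'
#' @param read base string or encoded integer vector (the query)
#' @param window base string or encoded integer vector (reference window,
#'   at least as long as the read)
#' @param scoring a [scoring_scheme()]
#' @param lane_width wavefront batch width (default 16)
#' @param max_read_length guard on the query length (default 1024)
#' @return a `dp_table` object: packed `cells` in diagonal order, dimensions
#'   `m` (read) and `n` (window), the best score and its cell
#' @export
fill_antidiagonal <- function(read, window, scoring = scoring_scheme(),
                              lane_width = 16L, max_read_length = 1024L) {
  r <- if (is.character(read)) encode_bases(read) else as.integer(read)
  w <- if (is.character(window)) encode_bases(window) else as.integer(window)
  if (length(r) > max_read_length)
    stop("read longer than max_read_length")
  if (length(w) < length(r)) stop("window shorter than read")
  ft <- dp_fill_cpp(r, w, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend,
                    as.integer(lane_width))
  if (isTRUE(ft$saturated))
    warning("DP cell score saturated at representation bound")
  structure(list(cells = ft$cells, m = ft$m, n = ft$n,
                 best_score = ft$best_score,
                 best_i = ft$best_i, best_j = ft$best_j,
                 read = r, window = w, scoring = scoring,
                 lane_width = as.integer(lane_width)),
            class = "dp_table")
}

#' Flat diagonal-order offset of cell (i, j)
#'
#' The mapping is a bijection from the `m x n` grid onto `[0, m*n)`;
#' diagonal `i + j` cells are consecutive, ordered by decreasing read index.
#'
#' @param i read index (1-based), `j` window index (1-based)
#' @param j window index
#' @param m,n table dimensions
#' @return 0-based flat offset
#' @export
diag_offset <- function(i, j, m, n) diag_flat_cpp(i, j, m, n)

#' Unpack a dp_table into the three score matrices
#' @param table a `dp_table`
#' @return list of integer matrices `M`, `I`, `D` (read rows, window columns)
#' @export
unpack_table <- function(table) {
  u <- cell_unpack_cpp(table$cells)
  m <- table$m; n <- table$n
  M <- matrix(NA_integer_, m, n); I <- M; D <- M
  for (i in seq_len(m)) {
    js <- seq_len(n)
    fl <- vapply(js, function(j) diag_flat_cpp(i, j, m, n), 1L) + 1L
    M[i, ] <- u[fl, 1L]; I[i, ] <- u[fl, 2L]; D[i, ] <- u[fl, 3L]
  }
  list(M = M, I = I, D = D)
}

#' Trace back the best alignment from a filled table
#'
#' Unaligned read prefix/suffix is emitted as soft clips (S, unpenalized);
#' ties prefer a match step over a deletion over an insertion, and among
#' equal-scoring end cells the cell aligning more of the read, then the
#' smallest window coordinate. A non-positive best score yields an unaligned
#' result.
#'
#' @param table a `dp_table` from [fill_antidiagonal()]
#' @return a `dp_alignment`: `aligned`, `score`, `cigar` (over M/I/D/S),
#'   `read_start`/`read_end` and `win_start`/`win_end` (1-based, inclusive),
#'   `n_mismatch`, `n_indel` (gap bases)
#' @export
dp_traceback <- function(table) {
  if (table$best_score <= 0L)
    return(structure(list(aligned = FALSE, score = 0L, cigar = "*",
                          read_start = NA_integer_, read_end = NA_integer_,
                          win_start = NA_integer_, win_end = NA_integer_,
                          n_mismatch = NA_integer_, n_indel = NA_integer_),
                     class = "dp_alignment"))
  s <- table$scoring
  tb <- dp_traceback_cpp(table$cells, table$m, table$n, table$read,
                         table$window, s$match, s$mismatch, s$gap_open,
                         s$gap_extend, table$best_i, table$best_j)
  ops <- c("M", "I", "D")[tb$ops + 1L]
  lead <- tb$read_start - 1L
  trail <- table$m - tb$read_end
  if (lead > 0L) ops <- c(rep("S", lead), ops)
  if (trail > 0L) ops <- c(ops, rep("S", trail))
  structure(list(aligned = TRUE, score = table$best_score,
                 cigar = compress_cigar(ops),
                 read_start = tb$read_start, read_end = tb$read_end,
                 win_start = tb$win_start, win_end = tb$win_end,
                 n_mismatch = tb$n_mismatch, n_indel = tb$n_indel),
            class = "dp_alignment")
}

#' @keywords internal
compress_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Parse a CIGAR string into ops and lengths
#' @keywords internal
parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Re-score a CIGAR against read and window texts
#'
#' Independent consistency check: soft clips are free, each aligned column
#' scores match/mismatch, each gap run costs open plus extend per base.
#'
#' @param cigar CIGAR string over M/I/D/S
#' @param read,window encoded integer vectors
#' @param win_start 1-based window column of the first aligned base
#' @param scoring a [scoring_scheme()]
#' @return the alignment score implied by the CIGAR
#' @export
rescore_cigar <- function(cigar, read, window, win_start, scoring) {
  cg <- parse_cigar(cigar)
  i <- 1L; j <- win_start
  score <- 0L
  for (k in seq_len(nrow(cg))) {
    l <- cg$len[k]
    switch(cg$op[k],
      S = { i <- i + l },
      M = {
        for (t in seq_len(l)) {
          ri <- read[i]; wj <- window[j]
          score <- score + if (ri < 4L && wj < 4L && ri == wj)
            scoring$match else -scoring$mismatch
          i <- i + 1L; j <- j + 1L
        }
      },
      I = { score <- score - scoring$gap_open - l * scoring$gap_extend
            i <- i + l },
      D = { score <- score - scoring$gap_open - l * scoring$gap_extend
            j <- j + l })
  }
  score
}

#' Align a read against a candidate region
#'
#' Extracts the (clamped) reference window, orients the read by the region
#' strand, runs the wavefront fill and traceback, and converts window-local
#' coordinates to global ones. The acceptance threshold is
#' `match * read_length * min_score_frac`.
#'
#' @param read base string (original orientation)
#' @param region one row of a [run_round()] data.frame (list or row)
#' @param reference a [reference()] object
#' @param scoring a [scoring_scheme()]
#' @param min_score_frac acceptance threshold fraction (default 0.3)
#' @param lane_width wavefront batch width
#' @return an `alignment_result`: `mapped`, `contig`, `ref_start` (global
#'   0-based), `local_start` (contig-local 0-based), `strand`, `score`,
#'   `accepted`, `cigar`, `n_mismatch`, `n_indel`
#' @export
align_candidate <- function(read, region, reference,
                            scoring = scoring_scheme(),
                            min_score_frac = 0.3, lane_width = 16L) {
  rl <- nchar(read)
  ws <- max(0L, as.integer(region$window_start))
  we <- min(reference$total_length, as.integer(region$window_end))
  # keep the window inside one contig and at least read-sized
  ci <- contig_of(reference, ws)
  clo <- reference$contigs$offset[ci]
  chi <- clo + reference$contigs$length[ci]
  ws <- max(ws, clo); we <- min(we, chi)
  if (we - ws < rl) {
    ws <- max(clo, we - rl); we <- min(chi, ws + max(rl, we - ws))
  }
  if (we - ws < rl) return(unmapped_result())
  enc <- encode_bases(read)
  if (identical(region$strand, "-")) enc <- revcomp_int(enc)
  tab <- fill_antidiagonal(enc, ref_fetch(reference, ws, we), scoring,
                           lane_width = lane_width)
  aln <- dp_traceback(tab)
  if (!aln$aligned) return(unmapped_result())
  gstart <- ws + aln$win_start - 1L
  structure(list(
    mapped = TRUE,
    contig = reference$contigs$name[ci],
    ref_start = gstart,
    local_start = gstart - clo,
    strand = if (identical(region$strand, "-")) "-" else "+",
    score = aln$score,
    accepted = aln$score >= scoring$match * rl * min_score_frac,
    cigar = aln$cigar,
    n_mismatch = aln$n_mismatch,
    n_indel = aln$n_indel,
    read_length = rl
  ), class = "alignment_result")
}

#' @keywords internal
unmapped_result <- function(read_length = NA_integer_) {
  structure(list(mapped = FALSE, contig = NA_character_,
                 ref_start = NA_integer_, local_start = NA_integer_,
                 strand = NA_character_, score = 0L, accepted = FALSE,
                 cigar = "*", n_mismatch = NA_integer_,
                 n_indel = NA_integer_, read_length = read_length),
            class = "alignment_result")
}

#' Reference span consumed by a CIGAR (M + D lengths)
#' @keywords internal
cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

#' Read bases accounted for by a CIGAR (M + I + S lengths)
#' @keywords internal
cigar_read_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S")])
}
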