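#' Per-round seeding configuration
#'
#' @param seed_length seed length in bases
#' @param seed_overlap overlap between consecutive seeds (0 <= overlap < length)
#' @param candidate_limit maximum occurrence count per seed; a seed whose
#'   total occurrence count exceeds the limit is discarded as repetitive for
#'   the round
#' @return a `round_config` object
#' @export
round_config <- function(seed_length, seed_overlap = 0L, candidate_limit = 1000L) {
  seed_length <- as.integer(seed_length)
  seed_overlap <- as.integer(seed_overlap)
  candidate_limit <- as.integer(candidate_limit)
  if (seed_length <= 0L) stop("seed_length must be positive")
  if (seed_overlap < 0L || seed_overlap >= seed_length)
    stop("need 0 <= seed_overlap < seed_length")
  if (candidate_limit <= 0L) stop("candidate_limit must be positive")
  structure(list(seed_length = seed_length, seed_overlap = seed_overlap,
                 candidate_limit = candidate_limit), class = "round_config")
}

#' Default multi-round seeding schedule
#'
#' Three rounds of decreasing seed length: 140/0/1000, 80/0/1000, 46/0/100
#' (length / overlap / occurrence limit). Long seeds in the early rounds keep
#' the candidate count low; the short-seed final round buys sensitivity for
#' reads the early rounds cannot place.
#'
#' @return list of [round_config()] objects
#' @export
default_rounds <- function() {
  list(round_config(140L, 0L, 1000L),
       round_config(80L, 0L, 1000L),
       round_config(46L, 0L, 100L))
}

#' Tile seed windows over a read
#'
#' Seeds start at the 5' end and advance by `seed_length - seed_overlap`,
#' with one final seed anchored flush at the 3' end when the last regular
#' tile would leave a tail uncovered. A round whose seed length exceeds the
#' read length is skipped (empty tiling). When base qualities are supplied,
#' a seed spanning a base below `quality_floor` (a suspected sequencing
#' error or variant) is shifted so the suspect base falls outside the seed
#' when such a shift exists; otherwise the seed is kept as tiled.
#'
#' @param read_length read length in bases
#' @param config a [round_config()]
#' @param qualities optional integer Phred qualities (length `read_length`)
#' @param quality_floor quality threshold for the shifting heuristic; 0
#'   disables it
#' @return data.frame with columns `offset` (0-based) and `length`
#' @export
tile_seeds <- function(read_length, config, qualities = NULL,
                       quality_floor = 0L) {
  L <- config$seed_length
  if (L > read_length)
    return(data.frame(offset = integer(0), length = integer(0)))
  step <- L - config$seed_overlap
  offs <- seq.int(0L, read_length - L, by = step)
  if (offs[length(offs)] + L < read_length)
    offs <- c(offs, read_length - L)
  if (!is.null(qualities) && quality_floor > 0L && any(qualities < quality_floor)) {
    low <- which(qualities < quality_floor)        # 1-based positions
    offs <- vapply(offs, function(o) {
      span <- (o + 1L):(o + L)
      if (!any(low %in% span)) return(o)
      cand <- 0L:(read_length - L)
      ok <- cand[vapply(cand, function(s) !any(low > s & low <= s + L),
                        logical(1))]
      if (length(ok) == 0L) return(o)
      ok[which.min(abs(ok - o))]
    }, integer(1))
    offs <- sort(unique(offs))
  }
  data.frame(offset = as.integer(offs), length = L)
}

#' Search one seed in the FM-index with branching/non-branching mismatches
#'
#' Depth-first backward search, extending right to left. A mismatching base
#' that still extends the interval costs one branching mismatch (BM) when at
#' least two bases extend; when the read base fails and exactly one base
#' extends, the forced correction costs one non-branching mismatch (NBM) and
#' does not fork the search. Paths exceeding the budgets are pruned.
#'
#' @param index an `fm_index`
#' @param seed base string (a seed containing N yields no hits)
#' @param max_bm branching-mismatch budget (default 1)
#' @param max_nbm non-branching-mismatch budget (default 2)
#' @param candidate_limit per-hit occurrence limit; wider hits carry an
#'   overflow marker instead of positions
#' @return list of seed hits, each a list with `low`, `high`, `width`,
#'   `n_bm`, `n_nbm`, `positions` (sorted global positions, boundary-crossing
#'   occurrences removed, or an overflow marker); hits are deduplicated by
#'   position, fewest mismatches first
#' @export
search_seed <- function(index, seed, max_bm = 1L, max_nbm = 2L,
                        candidate_limit = Inf) {
  s <- if (is.character(seed)) encode_bases(seed) else as.integer(seed)
  if (any(s == 4L)) return(list())
  if (max_bm < 0L || max_nbm < 0L) stop("budgets must be >= 0")
  hm <- seed_search_cpp(index$bwt, index$occ, index$count, index$occ_rate,
                        s, as.integer(max_bm), as.integer(max_nbm))
  if (nrow(hm) == 0L) return(list())
  ord <- order(hm[, "n_bm"] + hm[, "n_nbm"])
  hm <- hm[ord, , drop = FALSE]
  seen <- integer(0)
  hits <- vector("list", nrow(hm))
  ref <- index$reference
  L <- length(s)
  for (k in seq_len(nrow(hm))) {
    w <- hm[k, "high"] - hm[k, "low"]
    iv <- sa_interval(hm[k, "low"], hm[k, "high"])
    pos <- locate(index, iv, limit = candidate_limit)
    if (!is_overflow(pos)) {
      # drop occurrences that would cross a contig boundary or run off the text
      keep <- pos + L <= ref$total_length
      keep <- keep & contig_of(ref, pos) == contig_of(ref, pmin(pos + L - 1L,
                                                                ref$total_length - 1L))
      pos <- pos[keep]
      pos <- setdiff(pos, seen)
      if (length(pos) == 0L) next
      seen <- c(seen, pos)
    }
    hits[[k]] <- list(low = iv$low, high = iv$high, width = unname(w),
                      n_bm = unname(hm[k, "n_bm"]),
                      n_nbm = unname(hm[k, "n_nbm"]),
                      positions = pos)
  }
  hits[!vapply(hits, is.null, logical(1))]
}

#' Run one seeding round over a read (both strands)
#'
#' Tiles seeds on the read and on its reverse complement, searches each seed
#' under the mismatch budgets, discards seeds whose total occurrence count
#' exceeds the round's candidate limit (repetitive seeds), and merges
#' positions that land on the same read-projected diagonal (within
#' `merge_tol`) into candidate regions carrying an indel margin.
#'
#' @param index an `fm_index`
#' @param read base string
#' @param config a [round_config()]
#' @param max_bm,max_nbm mismatch budgets
#' @param qualities optional integer qualities for seed shifting
#' @param quality_floor see [tile_seeds()]
#' @param merge_tol diagonal merge tolerance in bases
#' @param indel_margin window margin in bases
#' @return data.frame of candidate regions: `contig`, `window_start`,
#'   `window_end` (global, half-open, clamped to the contig),  `strand`,
#'   `est_start` (projected read start), `n_support`, and a list column
#'   `offsets` of supporting seed offsets; zero rows when the round is
#'   skipped or fails
#' @export
run_round <- function(index, read, config, max_bm = 1L, max_nbm = 2L,
                      qualities = NULL, quality_floor = 0L,
                      merge_tol = 8L, indel_margin = 16L) {
  rl <- nchar(read)
  tiles <- tile_seeds(rl, config, qualities, quality_floor)
  empty <- data.frame(contig = character(0), window_start = integer(0),
                      window_end = integer(0), strand = character(0),
                      est_start = integer(0), n_support = integer(0))
  empty$offsets <- list()
  if (nrow(tiles) == 0L) return(empty)
  enc_f <- encode_bases(read)
  enc_r <- revcomp_int(enc_f)
  ref <- index$reference
  rows <- list()
  for (strand in c("+", "-")) {
    enc <- if (strand == "+") enc_f else enc_r
    q <- qualities
    if (strand == "-" && !is.null(q)) q <- rev(q)
    tl <- tile_seeds(rl, config, q, quality_floor)
    starts <- integer(0); offs <- integer(0)
    for (k in seq_len(nrow(tl))) {
      o <- tl$offset[k]
      hits <- search_seed(index, enc[(o + 1L):(o + tl$length[k])],
                          max_bm, max_nbm, config$candidate_limit)
      if (length(hits) == 0L) next
      total <- sum(vapply(hits, function(h) h$width, numeric(1)))
      if (total > config$candidate_limit ||
          any(vapply(hits, function(h) is_overflow(h$positions), logical(1))))
        next                                    # repetitive seed: drop
      pos <- unlist(lapply(hits, function(h) h$positions), use.names = FALSE)
      starts <- c(starts, pos - o)
      offs <- c(offs, rep.int(o, length(pos)))
    }
    if (length(starts) == 0L) next
    ord <- order(starts)
    starts <- starts[ord]; offs <- offs[ord]
    grp <- cumsum(c(1L, diff(starts) > merge_tol))
    for (g in unique(grp)) {
      ss <- starts[grp == g]; so <- offs[grp == g]
      ci <- contig_of(ref, max(min(ss), 0L))
      if (ci < 1L) next
      clo <- ref$contigs$offset[ci]
      chi <- clo + ref$contigs$length[ci]
      ws <- max(clo, min(ss) - indel_margin)
      we <- min(chi, max(ss) + rl + indel_margin)
      if (we <= ws) next
      rows[[length(rows) + 1L]] <-
        list(contig = ref$contigs$name[ci], window_start = ws, window_end = we,
             strand = strand, est_start = min(ss),
             n_support = length(ss), offsets = unique(so))
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    contig = vapply(rows, `[[`, "", "contig"),
    window_start = vapply(rows, function(r) as.integer(r$window_start), 1L),
    window_end = vapply(rows, function(r) as.integer(r$window_end), 1L),
    strand = vapply(rows, `[[`, "", "strand"),
    est_start = vapply(rows, function(r) as.integer(r$est_start), 1L),
    n_support = vapply(rows, function(r) as.integer(r$n_support), 1L),
    stringsAsFactors = FALSE)
  out$offsets <- lapply(rows, `[[`, "offsets")
  out
}

#' Multi-round candidate discovery with a stop rule
#'
#' Executes the seeding rounds in order and hands the candidates of each
#' round to `stop_rule(candidates, round)`; the first round for which the
#' rule returns a non-NULL acceptance stops the descent. Later rounds are
#' not executed for that read.
#'
#' @param index an `fm_index`
#' @param read base string
#' @param rounds list of [round_config()] (default [default_rounds()])
#' @param stop_rule function(candidates, round_index0) returning an accepted
#'   downstream result or NULL to continue
#' @param ... passed to [run_round()]
#' @return list with `candidates`, `round_used` (0-based; NA when every
#'   round fails), and `result` (the stop rule's acceptance, or NULL)
#' @export
multi_round_candidates <- function(index, read, rounds = default_rounds(),
                                   stop_rule, ...) {
  if (length(rounds) == 0L) stop("rounds must be non-empty")
  for (r in seq_along(rounds)) {
    cands <- run_round(index, read, rounds[[r]], ...)
    if (nrow(cands) == 0L) next
    res <- stop_rule(cands, r - 1L)
    if (!is.null(res))
      return(list(candidates = cands, round_used = r - 1L, result = res))
  }
  list(candidates = run_round(index, read, rounds[[length(rounds)]], ...),
       round_used = NA_integer_, result = NULL)
}
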