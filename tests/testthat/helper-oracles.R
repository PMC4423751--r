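# Independent pure-R oracles used to check the compiled core.
# These deliberately avoid the package's FM-index / wavefront code paths.

# suffix array by direct lexicographic sort of suffix strings (sentinel
# \x01 sorts below every base in byte order); texts kept small by callers
naive_sa <- function(text) {
  s <- paste0(text, "\x01")
  n <- nchar(s)
  suf <- substring(s, 1:n, n)
  order(suf, method = "radix") - 1L
}

# all (overlapping) occurrences of pattern in text, 0-based
naive_search <- function(text, pattern) {
  L <- nchar(text); l <- nchar(pattern)
  if (l > L) return(integer(0))
  starts <- 1:(L - l + 1)
  which(substring(text, starts, starts + l - 1) == pattern) - 1L
}

# text-space recursive seed search applying the same per-step mismatch
# classification as the index search: state = set of text positions where
# the currently matched (right-aligned) suffix of the seed occurs; extending
# left with base c keeps positions whose left neighbour is c.  A mismatching
# base that extends costs a BM when >= 2 bases extend; a forced unique
# correction after the read base fails costs an NBM.
oracle_seed_search <- function(text, seed, max_bm, max_nbm) {
  tx <- strsplit(text, "")[[1]]
  sd <- strsplit(seed, "")[[1]]
  L <- length(tx); k <- length(sd)
  res <- list()
  rec <- function(pos, set, n_bm, n_nbm) {
    if (pos < 1) {
      res[[length(res) + 1L]] <<- list(positions = sort(set) - 1L,
                                       n_bm = n_bm, n_nbm = n_nbm)
      return(invisible())
    }
    sets <- lapply(c("A", "C", "G", "T"), function(c)
      { s <- set[set - 1 >= 1 & tx[pmax(set - 1, 1)] == c]; s - 1 })
    names(sets) <- c("A", "C", "G", "T")
    nonempty <- vapply(sets, length, 1L) > 0
    rc <- sd[pos]
    if (nonempty[rc]) {
      rec(pos - 1, sets[[rc]], n_bm, n_nbm)
      if (sum(nonempty) >= 2 && n_bm < max_bm)
        for (c in names(sets)[nonempty])
          if (c != rc) rec(pos - 1, sets[[c]], n_bm + 1L, n_nbm)
    } else if (sum(nonempty) == 1) {
      if (n_nbm < max_nbm)
        rec(pos - 1, sets[[which(nonempty)]], n_bm, n_nbm + 1L)
    } else if (sum(nonempty) >= 2) {
      if (n_bm < max_bm)
        for (c in names(sets)[nonempty]) rec(pos - 1, sets[[c]], n_bm + 1L, n_nbm)
    }
  }
  # initial state: positions where the rightmost seed char could end, i.e.
  # every position p (1-based) such that [p, p+0) is the empty suffix;
  # matching starts from the full set of end positions 1..L+1 shifted once
  rec(k, seq_len(L) + 1L, 0L, 0L)
  # flatten to unique positions (0-based), minimal-mismatch first
  ord <- order(vapply(res, function(h) h$n_bm + h$n_nbm, 1L))
  seen <- integer(0); out <- list()
  for (h in res[ord]) {
    p <- setdiff(h$positions, seen)
    if (!length(p)) next
    seen <- c(seen, p)
    out[[length(out) + 1L]] <- list(positions = p, n_bm = h$n_bm,
                                    n_nbm = h$n_nbm)
  }
  out
}

# positions (0-based) reported by the package seed search, flattened
flatten_hits <- function(hits) {
  p <- unlist(lapply(hits, function(h)
    if (is_overflow(h$positions)) integer(0) else h$positions))
  if (is.null(p)) return(integer(0))
  sort(unique(p))
}

# textbook row-major three-matrix Gotoh, local over the read with free
# window flanks; first gap base costs open + extend.  Vectorized by rows:
# D along a row is a running max computed with cummax.
gotoh_row_major <- function(read, window, match, mismatch, gap_open,
                            gap_extend) {
  r <- if (is.character(read)) micalite:::encode_bases(read) else read
  w <- if (is.character(window)) micalite:::encode_bases(window) else window
  m <- length(r); n <- length(w)
  NEG <- -1e9
  go <- gap_open + gap_extend
  prevM <- rep(NEG, n + 1); prevI <- prevM; prevD <- prevM
  M <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    sub <- ifelse(w < 4 & r[i] < 4 & w == r[i], match, -mismatch)
    base <- pmax(0, prevM[1:n], prevI[1:n], prevD[1:n])
    Mrow <- c(NEG, sub + base)
    Irow <- c(NEG, pmax(prevM[2:(n + 1)] - go, prevI[2:(n + 1)] - gap_extend))
    # D[j] = -go - ext*(j-1) + cummax over k<j of (M[k] + ext*k), k 0-based
    aug <- Mrow + gap_extend * (0:n)
    Drow <- c(NEG, cummax(aug[1:n]) - gap_extend * (1:n) - gap_open)
    M[i, ] <- Mrow[2:(n + 1)]
    prevM <- Mrow; prevI <- Irow; prevD <- Drow
  }
  list(best = max(0, M), M = M)
}

# random sequence helpers
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_index <- function(text, occ_rate = 4L, sa_rate = 2L, name = "c1") {
  seqs <- setNames(text, name)
  build_fm_index(reference(seqs), occ_rate, sa_rate)
}

# re-scoring helper on character sequences
rescore <- function(cigar, read, window, win_start, scoring) {
  rescore_cigar(cigar, micalite:::encode_bases(read),
                micalite:::encode_bases(window), win_start, scoring)
}
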