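# Base coding shared with the C++ core: A=0, C=1, G=2, T=3, N=4.

.BASE_CHARS <- c("A", "C", "G", "T", "N")

.base_lookup <- local({
  lk <- rep(NA_integer_, 128L)
  lk[utf8ToInt("A")] <- 0L; lk[utf8ToInt("a")] <- 0L
  lk[utf8ToInt("C")] <- 1L; lk[utf8ToInt("c")] <- 1L
  lk[utf8ToInt("G")] <- 2L; lk[utf8ToInt("g")] <- 2L
  lk[utf8ToInt("T")] <- 3L; lk[utf8ToInt("t")] <- 3L
  lk[utf8ToInt("N")] <- 4L; lk[utf8ToInt("n")] <- 4L
  lk
})

#' Encode a base string to integer codes
#'
#' @param s a single character string over A/C/G/T/N (case-insensitive)
#' @return integer vector with A=0, C=1, G=2, T=3, N=4
#' @export
encode_bases <- function(s) {
  if (length(s) != 1L || !is.character(s)) stop("expected a single string")
  codes <- utf8ToInt(s)
  if (any(codes > 127L)) stop("non-ASCII character in sequence")
  out <- .base_lookup[codes]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("invalid base '%s' at position %d", substr(s, bad, bad), bad))
  }
  out
}

#' Decode integer base codes to a string
#'
#' @param x integer vector with A=0, C=1, G=2, T=3, N=4
#' @return a single character string
#' @export
decode_bases <- function(x) {
  paste(.BASE_CHARS[x + 1L], collapse = "")
}

#' Reverse complement of an encoded base vector
#' @keywords internal
revcomp_int <- function(x) {
  comp <- c(3L, 2L, 1L, 0L, 4L)          # A<->T, C<->G, N->N
  rev(comp[x + 1L])
}

#' Reverse complement of a base string
#' @param s a base string over A/C/G/T/N
#' @return the reverse-complemented string
#' @export
revcomp <- function(s) decode_bases(revcomp_int(encode_bases(s)))

# Phred qualities: SAM/FASTQ ASCII offset 33
.qual_to_int <- function(q) utf8ToInt(q) - 33L
.int_to_qual <- function(x) intToUtf8(x + 33L)
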