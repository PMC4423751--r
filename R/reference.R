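#' Reference genome container
#'
#' Holds an ordered set of contigs concatenated into a single encoded text
#' with 0-based global coordinates. Contig names must be unique; offsets are
#' strictly increasing and the global coordinate to (contig, local) mapping
#' is a bijection over `[0, total_length)`.
#'
#' @param sequences named character vector of contig sequences (A/C/G/T/N)
#' @return an object of class `mica_reference` with fields `contigs`
#'   (data.frame of name, length, offset), `text` (encoded integer vector)
#'   and `total_length`
#' @examples
#' ref <- reference(c(chr1 = "ACGTACGT", chr2 = "TTTT"))
#' ref$total_length
#' @export
reference <- function(sequences) {
  if (length(sequences) == 0L) stop("empty reference")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("contig names must be present and unique")
  enc <- lapply(seq_along(sequences), function(i) {
    tryCatch(encode_bases(sequences[[i]]),
             error = function(e) stop(sprintf("contig '%s': %s",
                                              nm[i], conditionMessage(e)),
                                      call. = FALSE))
  })
  lens <- vapply(enc, length, integer(1))
  if (any(lens == 0L)) stop("empty contig sequence")
  offs <- cumsum(c(0L, lens[-length(lens)]))
  structure(list(
    contigs = data.frame(name = nm, length = lens, offset = offs,
                         stringsAsFactors = FALSE),
    text = unlist(enc, use.names = FALSE),
    total_length = sum(lens)
  ), class = "mica_reference")
}

#' Read a reference genome from FASTA
#'
#' Multi-contig, wrapped-line FASTA via Biostrings.
#'
#' @param path path to a FASTA file
#' @return a [reference()] object
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty reference: ", path)
  v <- as.character(seqs)
  # FASTA descriptions: contig name is the first whitespace-delimited token
  names(v) <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, "", 1L)
  reference(v)
}

#' Write a reference to FASTA
#' @param ref a [reference()] object
#' @param path output path
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ref$contigs)),
    function(i) ref_contig_seq(ref, i), character(1)))
  names(seqs) <- ref$contigs$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @keywords internal
ref_contig_seq <- function(ref, i) {
  off <- ref$contigs$offset[i]
  decode_bases(ref$text[(off + 1L):(off + ref$contigs$length[i])])
}

#' Map a global 0-based position to (contig, local)
#' @keywords internal
global_to_local <- function(ref, pos) {
  i <- findInterval(pos, ref$contigs$offset)
  list(contig = ref$contigs$name[i],
       contig_idx = i,
       local = pos - ref$contigs$offset[i])
}

#' Fetch encoded text for a global half-open window
#' @keywords internal
ref_fetch <- function(ref, start, end) {
  ref$text[(start + 1L):end]
}

#' Contig index containing a global position, 0 if out of range
#' @keywords internal
contig_of <- function(ref, pos) {
  findInterval(pos, ref$contigs$offset)
}

#' @export
print.mica_reference <- function(x, ...) {
  cat(sprintf("<mica_reference> %d contig(s), %d bp total\n",
              nrow(x$contigs), x$total_length))
  print(x$contigs, row.names = FALSE)
  invisible(x)
}
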