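# Small shared helpers for sequence handling. All coordinates exposed to
# users follow the GenBank convention: 1-based, inclusive, on the plus
# strand of the stored genome sequence.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around Biostrings so strand handling is centralised in one
#' tested place.
#'
#' @param x a character scalar over A/C/G/T (case-insensitive).
#' @return a character scalar, the reverse complement in upper case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Split a DNA string into codons
#'
#' Returns the non-overlapping in-frame triplet partition. A trailing
#' partial codon (length not a multiple of 3) is dropped.
#'
#' @param x a character scalar.
#' @return character vector of triplets (possibly empty).
#' @export
split_codons <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Extract a 1-based inclusive slice from a genome sequence, wrapping across
# the origin when the genome is circular. `start` may exceed `end` only via
# wrapping (end > length). Returns "" for zero-length requests.
slice_genome <- function(seq, start, end, circular = FALSE) {
  len <- nchar(seq)
  if (end < start) return("")
  if (end <= len) return(substr(seq, start, end))
  if (!circular) {
    stop("slice [", start, ", ", end, "] extends past the end of a linear genome of length ", len)
  }
  over <- end - len
  if (over > len) stop("slice wraps more than once around the genome")
  paste0(substr(seq, start, len), substr(seq, 1L, over))
}

is_codon <- function(x) {
  is.character(x) & nchar(x) == 3L & !grepl("[^ACGT]", x)
}

all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# Minimum Hamming distance from codon `x` to a set of codons.
codon_hamming <- function(x, set) {
  xs <- strsplit(x, "")[[1]]
  min(vapply(strsplit(set, ""), function(s) sum(s != xs), integer(1)))
}
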