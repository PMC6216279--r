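# Independent oracles, written as plainly as possible and kept separate
# from the implementation paths they check.

# Per-codon counting loop.
oracle_count <- function(codons, set) {
  n <- 0L
  for (cod in codons) if (cod %in% set) n <- n + 1L
  n
}

# Brute-force near-cognate enumeration: scan all 64 codons and compute
# Hamming distances to the cognate set character by character.
oracle_hamming_set <- function(cognates) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    cod <- paste0(b1, b2, b3)
    if (cod %in% cognates) next
    dmin <- 3L
    for (cg in cognates) {
      d <- (substr(cod, 1, 1) != substr(cg, 1, 1)) +
           (substr(cod, 2, 2) != substr(cg, 2, 2)) +
           (substr(cod, 3, 3) != substr(cg, 3, 3))
      dmin <- min(dmin, d)
    }
    if (dmin == 1L) out <- c(out, cod)
  }
  sort(out)
}

# Sliding-window stop search over a downstream sequence; returns 0-based
# offsets (relative to the first UTR nt) of stops starting in the given
# frame. `prefix` is sequence borrowed from the CDS for negative frames.
oracle_frame_stops <- function(utr, stops, first_offset, prefix = "") {
  seqs <- paste0(prefix, utr)
  hits <- integer(0)
  i <- 1L
  while (i + 2L <= nchar(seqs)) {
    tri <- substr(seqs, i, i + 2L)
    if (tri %in% stops) hits <- c(hits, first_offset + (i - 1L))
    i <- i + 3L
  }
  hits
}

# Exact algebraic inverse of the incorporation fold change: f is a Moebius
# function of epsilon, so the solve is linear.
oracle_invert_fold_change <- function(f, c_a, nc_a, c_b, nc_b) {
  c_a * c_b * (f - 1) / (c_b * nc_a - f * c_a * nc_b)
}

# Small toy genome used across IO tests: two short CDS, one per strand.
# Layout (1-based): spacer 1-10, geneF 11-22 (+), spacer 23-32,
# geneR 33-44 (-), spacer 45-54.
toy_genome <- function(circular = FALSE) {
  fwd <- "ATGTGTTGCTAA"            # M C C *
  rev_sense <- "ATGAAACCCTAA"      # M K P *
  rev_stored <- mitofidelity::revcomp(rev_sense)
  seqs <- paste0("GGGGGGGGGG", fwd, "CCCCCCCCCC", rev_stored, "TTTTTTTTTT")
  feats <- data.frame(
    gene_id = c("geneF", "geneR"),
    start = c(11L, 33L), end = c(22L, 44L),
    strand = c("+", "-"), transl_table = c(1L, 1L),
    stringsAsFactors = FALSE)
  genome_record(seqs, feats, circular = circular, name = "toy")
}
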