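#' Cognate codon set of an amino acid
#'
#' @param amino_acid standard one-letter amino-acid code.
#' @param code a `genetic_code`.
#' @return character vector of codons mapping to `amino_acid` (stop and
#'   hungry codons are never included).
#' @examples
#' cognate_set("M", genetic_code(2))  # ATA ATG
#' @export
cognate_set <- function(amino_acid, code) {
  stopifnot(is_genetic_code(code), is.character(amino_acid),
            length(amino_acid) == 1L, nchar(amino_acid) == 1L)
  s <- names(code$codon_to_aa)[code$codon_to_aa == amino_acid]
  s <- setdiff(s, c(code$hungry_codons, code$stop_codons))
  if (!length(s)) stop("amino acid '", amino_acid, "' has no codon under table ",
                       code$table_id)
  sort(s)
}

#' Near-cognate codon neighbourhood of an amino acid
#'
#' Enumerates the codons a misreading ribosome can decode as
#' `amino_acid`. Two definitions are supported:
#'
#' * `pairing = "any"`: all codons at minimum Hamming distance exactly 1
#'   from the cognate set -- the geometric neighbourhood, uniform over the
#'   three codon positions.
#' * `pairing = "anticodon"` (the definition used by the reporter
#'   statistic): the single-mismatch neighbours of the codon that pairs
#'   Watson-Crick with the decoding tRNA anticodon, with wobble pairing
#'   itself counted as a mismatch and cognate codons excluded. Misreading
#'   requires the near-cognate codon:anticodon duplex to contain exactly
#'   one non-Watson-Crick pair; a codon already read through a wobble pair
#'   cannot tolerate a second mismatch. For cysteine (tRNA anticodon GCA)
#'   the reference codon is TGC, for methionine (anticodon CAU) it is ATG.
#'
#' Both sets are subsets of the distance-1 shell around the cognate set,
#' so the usual neighbourhood invariants hold for either.
#'
#' @param amino_acid one-letter amino-acid code.
#' @param code a `genetic_code`.
#' @param pairing `"anticodon"` or `"any"`; see above.
#' @param include_stop_neighbors keep codons mapping to STOP under `code`
#'   in the neighbourhood (default `TRUE`; internal sense codons of a CDS
#'   can never be stops, so this only matters for terminal-codon policy).
#' @param reference_codon for `pairing = "anticodon"`: the
#'   Watson-Crick-paired codon (reverse complement of the anticodon).
#'   Defaults to the cognate codon whose wobble base pairs the anticodon
#'   Watson-Crick, chosen by third-base preference C > G > T > A (NNY
#'   boxes are read by G34 anticodons, so e.g. TGC for Cys; AUG for Met's
#'   CAU anticodon).
#' @return a `codon_neighborhood`: list with `amino_acid`, `code`,
#'   `pairing`, `cognate_set`, `near_cognate_set`, `reference_codon` (or
#'   `NA`), and `per_codon_distance` (named integer vector over all 64
#'   codons: minimum Hamming distance to the cognate set).
#' @examples
#' length(codon_neighborhood("C", genetic_code(1), "any")$near_cognate_set)  # 14
#' codon_neighborhood("C", genetic_code(2))$near_cognate_set
#' @export
codon_neighborhood <- function(amino_acid, code,
                               pairing = c("anticodon", "any"),
                               include_stop_neighbors = TRUE,
                               reference_codon = NULL) {
  pairing <- match.arg(pairing)
  cog <- cognate_set(amino_acid, code)
  codons <- all_codons()
  dist <- vapply(codons, codon_hamming, integer(1), set = cog)
  names(dist) <- codons

  ref <- NA_character_
  if (pairing == "any") {
    nc <- codons[dist == 1L]
  } else {
    if (is.null(reference_codon)) {
      third <- substr(cog, 3L, 3L)
      pref <- c("C", "G", "T", "A")
      ref <- cog[order(match(third, pref))][1L]
    } else {
      ref <- toupper(reference_codon)
      if (!ref %in% cog) stop("reference_codon must be a cognate codon of '",
                              amino_acid, "'")
    }
    nc <- hamming1_neighbors(ref)
    nc <- setdiff(nc, cog)
  }
  if (!include_stop_neighbors) nc <- setdiff(nc, code$stop_codons)

  structure(
    list(amino_acid = amino_acid, code = code, pairing = pairing,
         cognate_set = cog, near_cognate_set = sort(nc),
         reference_codon = ref, per_codon_distance = dist),
    class = "codon_neighborhood"
  )
}

hamming1_neighbors <- function(codon) {
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, p, p))) {
      x <- codon
      substr(x, p, p) <- b
      out <- c(out, x)
    }
  }
  out
}

#' @export
print.codon_neighborhood <- function(x, ...) {
  cat("Codon neighbourhood of '", x$amino_acid, "' (table ",
      x$code$table_id, ", pairing = ", x$pairing, ")\n", sep = "")
  cat("  cognate (", length(x$cognate_set), "): ",
      paste(x$cognate_set, collapse = " "), "\n", sep = "")
  cat("  near-cognate (", length(x$near_cognate_set), "): ",
      paste(x$near_cognate_set, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Count cognate and near-cognate codons in a coding sequence
#'
#' @param cds a `coding_sequence`.
#' @param neighborhood a `codon_neighborhood` built under the same genetic
#'   code as `cds`.
#' @param include_terminal also count the terminal stop/hungry codon
#'   (default `FALSE`: the terminal codon is not decoded as a sense codon).
#' @return named integer vector `c(cognate = C_A, near_cognate = NC_A,
#'   counted = <number of codons counted>)`.
#' @export
count_codons <- function(cds, neighborhood, include_terminal = FALSE) {
  stopifnot(inherits(cds, "coding_sequence"),
            inherits(neighborhood, "codon_neighborhood"))
  if (cds$code$table_id != neighborhood$code$table_id) {
    stop("coding sequence (table ", cds$code$table_id,
         ") and neighbourhood (table ", neighborhood$code$table_id,
         ") were built under different genetic codes")
  }
  codons <- sense_codons(cds, include_terminal = include_terminal)
  c(cognate = sum(codons %in% neighborhood$cognate_set),
    near_cognate = sum(codons %in% neighborhood$near_cognate_set),
    counted = length(codons))
}
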