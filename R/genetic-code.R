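#' Load a genetic code table
#'
#' Builds a `genetic_code` object from an NCBI translation-table number.
#' The codon map itself comes from [Biostrings::getGeneticCode()]; on top
#' of it this object records the start-codon set and, for codes that have
#' them, the "hungry" codons: sense-frame triplets that lack an efficiently
#' decoding tRNA and stall the ribosome rather than terminating it. In the
#' vertebrate mitochondrial code (table 2) these are AGA and AGG, which sit
#' at the 3' end of some mtDNA-encoded CDS (e.g. human MT-CO1) and are not
#' recognised by the mitochondrial release factor.
#'
#' @param table_id integer NCBI translation-table number. Tables 1
#'   (standard), 2 (vertebrate mitochondrial) and 11 (bacterial/archaeal)
#'   are guaranteed; any table known to Biostrings is accepted.
#' @param hungry_codons optional character vector of triplets to treat as
#'   hungry. Defaults to `c("AGA", "AGG")` for table 2 and none otherwise.
#' @return an object of class `genetic_code` with fields `name`,
#'   `table_id`, `codon_to_aa` (named character vector of 64 entries,
#'   stops as `"*"`), `start_codons`, `stop_codons` and `hungry_codons`.
#' @examples
#' mito <- genetic_code(2)
#' mito$codon_to_aa[c("ATA", "TGA", "AGA")]  # "M" "W" "*"
#' @export
genetic_code <- function(table_id, hungry_codons = NULL) {
  stopifnot(length(table_id) == 1L)
  tid <- as.integer(table_id)
  tab <- Biostrings::GENETIC_CODE_TABLE
  row <- tab[tab$id == as.character(tid), , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown translation table: ", table_id)
  }
  map <- Biostrings::getGeneticCode(as.character(tid))
  alt <- attr(map, "alt_init_codons")
  codon_to_aa <- stats::setNames(as.character(map), names(map))
  start_codons <- sort(unique(c(names(codon_to_aa)[codon_to_aa == "M"], alt)))
  stop_codons <- names(codon_to_aa)[codon_to_aa == "*"]
  if (is.null(hungry_codons)) {
    hungry_codons <- if (tid == 2L) c("AGA", "AGG") else character(0)
  }
  hungry_codons <- toupper(hungry_codons)
  if (!all(is_codon(hungry_codons))) stop("hungry_codons must be ACGT triplets")
  structure(
    list(
      name = row$name,
      table_id = tid,
      codon_to_aa = codon_to_aa,
      start_codons = start_codons,
      stop_codons = stop_codons,
      hungry_codons = hungry_codons
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code: ", x$name, " (table ", x$table_id, ")\n", sep = "")
  cat("  start codons: ", paste(x$start_codons, collapse = " "), "\n", sep = "")
  cat("  stop codons:  ", paste(x$stop_codons, collapse = " "), "\n", sep = "")
  if (length(x$hungry_codons)) {
    cat("  hungry codons:", paste(x$hungry_codons, collapse = " "), "\n")
  }
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

# Termination stops: stop codons actually recognised by the release factor,
# i.e. the code's stop set minus hungry codons (which stall instead).
termination_stops <- function(code) {
  setdiff(code$stop_codons, code$hungry_codons)
}
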