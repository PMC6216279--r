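#' Extract a strand-resolved coding sequence with its 3' UTR
#'
#' Pulls one CDS feature out of a genome record, reverse-complementing
#' minus-strand features, partitions it into sense codons, classifies the
#' terminal codon and attaches the downstream untranslated region.
#'
#' Several vertebrate mitochondrial CDS are completed to a stop codon only
#' by polyadenylation of the mRNA and are annotated with a 1-2 nt partial
#' stop; the trailing partial triplet is dropped from the codon list and
#' the terminal flag set to `"truncated"`, so all downstream counting
#' operates on full sense codons only.
#'
#' @param genome a `genome_record`.
#' @param feature either a gene id present in `genome$features`, a row
#'   index, or a one-row data.frame with columns `gene_id`, `start`,
#'   `end`, `strand`, `transl_table`.
#' @param code a `genetic_code`; defaults to the feature's
#'   `transl_table`.
#' @param utr3_len length in nt of downstream sequence (sense strand) to
#'   attach as the 3' UTR. Wraps across the origin for circular genomes;
#'   truncated with a warning at the end of a linear genome.
#' @return a `coding_sequence`: list with `gene_id`, `nt_sequence` (body
#'   including the terminal full codon), `codons`, `terminal_codon`,
#'   `terminal_flag` (`"complete_stop"`, `"hungry"` or `"truncated"`),
#'   `utr3`, `utr3_truncated`, `source_coords` (start, end, strand) and
#'   `code`.
#' @examples
#' g <- genome_record("ATGTGTTGCTAAGGGTTT",
#'   data.frame(gene_id = "toy", start = 1, end = 12, strand = "+",
#'              transl_table = 1))
#' cds <- extract_cds(g, "toy", utr3_len = 6)
#' cds$terminal_flag  # "complete_stop"
#' @export
extract_cds <- function(genome, feature, code = NULL, utr3_len = 0L) {
  stopifnot(inherits(genome, "genome_record"), utr3_len >= 0L)
  f <- resolve_feature(genome, feature)
  if (is.null(code)) code <- genetic_code(f$transl_table)
  stopifnot(is_genetic_code(code))

  len <- f$end - f$start + 1L
  if (len < 6L) stop("feature '", f$gene_id, "' is shorter than 6 nt")
  slice <- slice_genome(genome$sequence, f$start, f$end, genome$circular)
  nt <- if (f$strand == "-") revcomp(slice) else slice

  codons <- split_codons(nt)
  partial <- nchar(nt) %% 3L

  last <- codons[length(codons)]
  if (partial > 0L) {
    flag <- "truncated"
  } else if (last %in% code$hungry_codons) {
    flag <- "hungry"
  } else if (last %in% code$stop_codons) {
    flag <- "complete_stop"
  } else {
    flag <- "truncated"
  }

  body <- if (flag == "truncated" && partial == 0L) codons else
    codons[-length(codons)]
  # internal codons must not be stops (hungry codons are stops in table 2)
  internal <- if (flag == "truncated") body else codons[-length(codons)]
  hit <- which(code$codon_to_aa[internal] == "*")
  if (length(hit)) {
    stop("internal stop codon ", internal[hit[1L]], " at codon position ",
         hit[1L], " in '", f$gene_id, "'")
  }

  # 3' UTR: downstream on the sense strand
  utr3 <- ""
  utr3_truncated <- FALSE
  if (utr3_len > 0L) {
    glen <- nchar(genome$sequence)
    if (f$strand == "+") {
      from <- f$end + 1L
      to <- f$end + utr3_len
      if (to > glen && !genome$circular) {
        to <- glen
        utr3_truncated <- TRUE
        warning("3' UTR of '", f$gene_id, "' truncated at linear genome end")
      }
      if (from <= glen || genome$circular) {
        if (from > glen) from <- from - glen  # fully wrapped start
        utr3 <- slice_genome(genome$sequence, from, to, genome$circular)
      }
    } else {
      to <- f$start - 1L
      from <- f$start - utr3_len
      if (from < 1L && !genome$circular) {
        from <- 1L
        utr3_truncated <- TRUE
        warning("3' UTR of '", f$gene_id, "' truncated at linear genome end")
      }
      if (to >= 1L) {
        if (from < 1L) {
          utr3 <- paste0(slice_genome(genome$sequence, glen + from, glen, TRUE),
                         slice_genome(genome$sequence, 1L, to, TRUE))
        } else {
          utr3 <- slice_genome(genome$sequence, from, to, genome$circular)
        }
        utr3 <- revcomp(utr3)
      }
    }
  }

  structure(
    list(
      gene_id = f$gene_id,
      nt_sequence = paste(codons, collapse = ""),
      codons = codons,
      terminal_codon = last,
      terminal_flag = flag,
      utr3 = utr3,
      utr3_truncated = utr3_truncated,
      source_coords = list(start = f$start, end = f$end, strand = f$strand),
      code = code
    ),
    class = "coding_sequence"
  )
}

resolve_feature <- function(genome, feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    return(as.list(read_feature_table(feature)))
  }
  ft <- genome$features
  if (is.character(feature)) {
    i <- match(feature, ft$gene_id)
    if (is.na(i)) stop("no feature named '", feature, "' in genome")
  } else {
    i <- as.integer(feature)
    if (i < 1L || i > nrow(ft)) stop("feature index out of range: ", feature)
  }
  as.list(ft[i, , drop = FALSE])
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("Coding sequence '", x$gene_id, "': ", length(x$codons), " codons, ",
      "terminal ", x$terminal_codon, " (", x$terminal_flag, "), ",
      nchar(x$utr3), " nt 3' UTR [table ", x$code$table_id, "]\n", sep = "")
  invisible(x)
}

# Sense codons that are actually decoded: drop a complete-stop or hungry
# terminal codon (a truncated terminal is already a full sense codon).
sense_codons <- function(cds, include_terminal = FALSE) {
  codons <- cds$codons
  if (!include_terminal && cds$terminal_flag %in% c("complete_stop", "hungry")) {
    codons <- codons[-length(codons)]
  }
  codons
}

#' Translate a coding sequence to protein
#'
#' One letter per sense codon; a terminal stop or hungry codon is excluded.
#' An initiator codon in the code's start set is rendered as Met by default
#' even if its table entry differs (e.g. ATT/ATC starts in the vertebrate
#' mitochondrial code), matching protein-level residue counting.
#'
#' @param cds a `coding_sequence`.
#' @param init_as_met logical; translate a start-set initiator as `M`.
#' @return a character scalar protein sequence.
#' @examples
#' g <- genome_record("ATGTGTTAA")
#' f <- data.frame(gene_id = "x", start = 1, end = 9, strand = "+",
#'                 transl_table = 1)
#' translate_cds(extract_cds(g, f))  # "MC"
#' @export
translate_cds <- function(cds, init_as_met = TRUE) {
  stopifnot(inherits(cds, "coding_sequence"))
  codons <- sense_codons(cds)
  if (!length(codons)) return("")
  aa <- unname(cds$code$codon_to_aa[codons])
  if (init_as_met && codons[1L] %in% cds$code$start_codons) aa[1L] <- "M"
  if (any(aa == "*")) stop("stop codon among sense codons of '", cds$gene_id, "'")
  paste(aa, collapse = "")
}

#' Insert a codon into a coding sequence body
#'
#' Utility for building expression constructs, e.g. inserting an alanine
#' GCG codon immediately after the initiator ATG of MT-CO1 as in cell-free
#' translation constructs.
#'
#' @param cds a `coding_sequence`.
#' @param codon triplet to insert.
#' @param after 1-based codon index after which to insert (default 1:
#'   right after the initiator).
#' @return a modified `coding_sequence` (source coordinates dropped).
#' @export
insert_codon <- function(cds, codon, after = 1L) {
  stopifnot(inherits(cds, "coding_sequence"), is_codon(toupper(codon)))
  codon <- toupper(codon)
  i <- as.integer(after)
  stopifnot(i >= 0L, i <= length(cds$codons))
  cds$codons <- append(cds$codons, codon, after = i)
  cds$nt_sequence <- paste(cds$codons, collapse = "")
  cds$source_coords <- NULL
  cds
}
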