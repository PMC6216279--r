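#' Read an annotated genome
#'
#' Reads a genome sequence plus its protein-coding features, either from a
#' GenBank flat file (sequence and CDS features in one file) or from a
#' FASTA file accompanied by a BED-like tab-separated feature table with
#' columns `gene_id`, `start`, `end`, `strand`, `transl_table`
#' (coordinates 1-based inclusive on the plus strand, as in GenBank).
#'
#' FASTA parsing is done by [Biostrings::readDNAStringSet()]. The GenBank
#' flat-file reader supports single-record files with plain and
#' `complement()` CDS locations; spliced (`join()`) CDS are rejected, as
#' mitochondrial genes are unspliced.
#'
#' @param path path to the genome file.
#' @param format `"auto"` (by extension), `"genbank"`, or `"fasta"`.
#' @param features for FASTA input: a feature table, either a path to a
#'   TSV file or a data.frame. Ignored for GenBank input. May be `NULL`
#'   for a featureless genome.
#' @param circular logical; genome topology for FASTA input (GenBank
#'   records carry their own topology flag on the LOCUS line).
#' @return a `genome_record`: list with `name`, `sequence` (upper-case
#'   character scalar), `features` (data.frame as above), `circular`.
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta"),
                        features = NULL, circular = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "genbank") {
    rec <- parse_genbank(path)
  } else {
    dss <- Biostrings::readDNAStringSet(path)
    if (length(dss) != 1L) stop("expected exactly one sequence in ", path)
    feat <- read_feature_table(features)
    rec <- genome_record(as.character(dss[[1L]]), feat,
                         circular = circular, name = names(dss)[1L])
  }
  rec
}

#' Construct a genome record from in-memory parts
#'
#' @param sequence character scalar DNA sequence.
#' @param features data.frame with columns `gene_id`, `start`, `end`,
#'   `strand`, `transl_table`, or `NULL` for none.
#' @param circular logical topology flag.
#' @param name record name.
#' @return a `genome_record` object.
#' @export
genome_record <- function(sequence, features = NULL, circular = FALSE,
                          name = "genome") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("genome sequence contains non-ACGTN characters")
  features <- read_feature_table(features)
  len <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 1L | features$end > len | features$start > features$end
    if (any(bad)) {
      stop("feature exceeds sequence bounds or is malformed: ",
           paste(features$gene_id[bad], collapse = ", "))
    }
    if (!all(features$strand %in% c("+", "-"))) stop("feature strand must be + or -")
  }
  structure(
    list(name = name, sequence = sequence, features = features,
         circular = isTRUE(circular)),
    class = "genome_record"
  )
}

empty_features <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), transl_table = integer(0),
             stringsAsFactors = FALSE)
}

read_feature_table <- function(features) {
  if (is.null(features)) return(empty_features())
  if (is.character(features) && length(features) == 1L) {
    features <- utils::read.delim(features, stringsAsFactors = FALSE)
  }
  needed <- c("gene_id", "start", "end", "strand", "transl_table")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  features <- features[, needed, drop = FALSE]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$transl_table <- as.integer(features$transl_table)
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat("Genome record '", x$name, "': ", nchar(x$sequence), " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$features), " CDS feature(s)\n", sep = "")
  invisible(x)
}

# --- GenBank flat file ------------------------------------------------------
# Minimal single-record reader: LOCUS (topology), FEATURES/CDS with
# /gene, /locus_tag and /transl_table qualifiers, ORIGIN sequence block.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  circular <- grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("GenBank record has no ORIGIN block: ", path)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1L] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_at)) {
    block <- lines[(feat_at[1L] + 1L):(origin_at[1L] - 1L)]
    # a feature starts at indentation 5 with a key; qualifiers at indentation 21
    starts <- grep("^ {5}\\S", block)
    starts <- c(starts, length(block) + 1L)
    for (i in seq_len(length(starts) - 1L)) {
      chunk <- block[starts[i]:(starts[i + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
      if (key != "CDS") next
      loc <- sub("^ {5}\\S+\\s+", "", chunk[1L])
      # continuation lines of the location (no leading '/')
      j <- 2L
      while (j <= length(chunk) && !grepl("^\\s+/", chunk[j])) {
        loc <- paste0(loc, trimws(chunk[j])); j <- j + 1L
      }
      if (grepl("join|order", loc)) {
        stop("spliced CDS locations are not supported (feature '", loc, "')")
      }
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
      if (length(nums) < 2L) stop("cannot parse CDS location: ", loc)
      quals <- paste(chunk[j:length(chunk)], collapse = " ")
      gene <- qual_value(quals, "gene")
      if (is.na(gene)) gene <- qual_value(quals, "locus_tag")
      if (is.na(gene)) gene <- paste0("CDS_", i)
      tt <- qual_value(quals, "transl_table")
      features <- rbind(features, data.frame(
        gene_id = gene, start = as.integer(nums[1L]), end = as.integer(nums[2L]),
        strand = strand, transl_table = if (is.na(tt)) 1L else as.integer(tt),
        stringsAsFactors = FALSE))
    }
  }
  genome_record(sequence, features, circular = circular, name = name)
}

qual_value <- function(quals, key) {
  m <- regmatches(quals, regexec(paste0("/", key, '="?([^"/ ]+)"?'), quals))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

#' Write a genome record to FASTA plus a TSV feature table
#'
#' @param genome a `genome_record`.
#' @param fasta,tsv output paths. Either may be `NULL` to skip.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta = NULL, tsv = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(genome$sequence)
    names(dss) <- genome$name
    Biostrings::writeXStringSet(dss, fasta, width = 70L)
  }
  if (!is.null(tsv)) {
    utils::write.table(genome$features, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(genome)
}

#' Write a genome record as a minimal GenBank flat file
#'
#' Emits LOCUS (with topology), CDS features with strand and
#' `/transl_table`, and the ORIGIN sequence block; round-trips through
#' [read_genome()].
#'
#' @param genome a `genome_record`.
#' @param path output path.
#' @return invisibly, the genome.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     UNA",
                     genome$name, nchar(genome$sequence), topo), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /gene="%s"', f$gene_id[i]), con)
    writeLines(sprintf("                     /transl_table=%d", f$transl_table[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(genome)
}
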