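#' Discrimination ratio of an amino-acid pair
#'
#' The reporter statistic: with A the misreading-gain label and B the
#' reference label,
#' \deqn{R = (NC_A / C_A) / (NC_B / C_B)}
#' where C and NC are cognate and near-cognate codon counts. A large R
#' marks a protein whose A/B label-incorporation ratio responds strongly
#' to ribosomal misreading; for human MT-CO1 with Cys/Met counts
#' (1, 96, 32, 48) the ratio is 64.0.
#'
#' @param c_a,nc_a,c_b,nc_b non-negative integer counts.
#' @param gene_id optional label carried through to output.
#' @param pair two-letter character vector `c(A, B)`.
#' @return a `reporter_stats` object: list with the four counts, `ratio`
#'   (double; `NA` when undefined, `Inf` when `NC_B = 0` with `C_B > 0`),
#'   `flag` (`"ok"`, `"undefined"` or `"infinite"`), `gene_id`, `pair`.
#'   Human-readable printing rounds to one decimal; the full-precision
#'   value is always retained.
#' @examples
#' reporter_ratio(1, 96, 32, 48)$ratio  # 64
#' @export
reporter_ratio <- function(c_a, nc_a, c_b, nc_b, gene_id = NA_character_,
                           pair = c("A", "B")) {
  stopifnot(c_a >= 0, nc_a >= 0, c_b >= 0, nc_b >= 0)
  if (c_a == 0 || c_b == 0) {
    ratio <- NA_real_; flag <- "undefined"
  } else if (nc_b == 0) {
    ratio <- Inf; flag <- "infinite"
  } else {
    ratio <- (nc_a / c_a) / (nc_b / c_b); flag <- "ok"
  }
  structure(
    list(gene_id = gene_id, pair = pair,
         c_a = as.integer(c_a), nc_a = as.integer(nc_a),
         c_b = as.integer(c_b), nc_b = as.integer(nc_b),
         ratio = ratio, flag = flag),
    class = "reporter_stats"
  )
}

#' @export
print.reporter_stats <- function(x, ...) {
  lab <- if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]")
  cat("Reporter statistic", lab, ": pair ", x$pair[1], "/", x$pair[2], "\n",
      sep = "")
  cat(sprintf("  %s: cognate %d, near-cognate %d\n", x$pair[1], x$c_a, x$nc_a))
  cat(sprintf("  %s: cognate %d, near-cognate %d\n", x$pair[2], x$c_b, x$nc_b))
  cat("  R = ", format_ratio(x$ratio, x$flag), "\n", sep = "")
  invisible(x)
}

format_ratio <- function(ratio, flag) {
  switch(flag,
         ok = sprintf("%.1f", ratio),
         undefined = "undefined (zero cognate count)",
         infinite = "infinite (zero reference near-cognate count)")
}

# Compute reporter stats for one CDS from its code.
cds_reporter_stats <- function(cds, pair, pairing = "anticodon",
                               include_terminal = FALSE) {
  na <- codon_neighborhood(pair[1], cds$code, pairing = pairing)
  nb <- codon_neighborhood(pair[2], cds$code, pairing = pairing)
  ca <- count_codons(cds, na, include_terminal = include_terminal)
  cb <- count_codons(cds, nb, include_terminal = include_terminal)
  reporter_ratio(ca[["cognate"]], ca[["near_cognate"]],
                 cb[["cognate"]], cb[["near_cognate"]],
                 gene_id = cds$gene_id, pair = pair)
}

#' Scan a genome for endogenous misreading reporters
#'
#' Computes the discrimination ratio for every CDS feature of a genome and
#' ranks them: the top-ranked gene is the most sensitive endogenous
#' reporter for the chosen label pair. Applied to the 13 CDS of the human
#' mitochondrial genome with the pair Cys/Met, MT-CO1 ranks first.
#'
#' @param genome a `genome_record` with at least one CDS feature.
#' @param code a `genetic_code` applied to every CDS; defaults to each
#'   feature's own `transl_table`.
#' @param pair two one-letter amino acids `c(A, B)`: A is the
#'   misreading-gain label, B the reference label.
#' @param pairing near-cognate definition, see [codon_neighborhood()].
#' @param utr3_len 3' UTR length passed to [extract_cds()].
#' @return a `reporter_ranking`: list with `table` (data.frame of ranked
#'   defined-ratio genes: rank, gene_id, c_a, nc_a, c_b, nc_b, ratio,
#'   ratio_display, flag), `unranked` (undefined/infinite entries, never
#'   interleaved), `skipped` (genes whose extraction failed, with
#'   messages), and `pair`.
#' @export
scan_genome <- function(genome, code = NULL, pair = c("C", "M"),
                        pairing = c("anticodon", "any"), utr3_len = 0L) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(genome, "genome_record"), nrow(genome$features) >= 1L)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(genome$features))) {
    gid <- genome$features$gene_id[i]
    st <- tryCatch({
      cds <- extract_cds(genome, i, code = code, utr3_len = utr3_len)
      cds_reporter_stats(cds, pair, pairing = pairing)
    }, error = function(e) e)
    if (inherits(st, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gid, message = conditionMessage(st),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- stats_row(st)
    }
  }
  tab <- do.call(rbind, rows)
  defined <- tab[tab$flag == "ok", , drop = FALSE]
  other <- tab[tab$flag != "ok", , drop = FALSE]
  # sort by ratio desc, ties by larger NC_A, then gene_id
  o <- order(-defined$ratio, -defined$nc_a, defined$gene_id)
  defined <- defined[o, , drop = FALSE]
  defined$rank <- seq_len(nrow(defined))
  defined <- defined[, c("rank", setdiff(names(defined), "rank"))]
  rownames(defined) <- NULL
  rownames(other) <- NULL
  structure(
    list(table = defined, unranked = other,
         skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
         pair = pair, pairing = pairing),
    class = "reporter_ranking"
  )
}

stats_row <- function(st) {
  data.frame(gene_id = st$gene_id, c_a = st$c_a, nc_a = st$nc_a,
             c_b = st$c_b, nc_b = st$nc_b, ratio = st$ratio,
             ratio_display = if (st$flag == "ok") sprintf("%.1f", st$ratio)
                             else st$flag,
             flag = st$flag, stringsAsFactors = FALSE)
}

#' @export
print.reporter_ranking <- function(x, ...) {
  cat("Reporter scan, pair ", x$pair[1], "/", x$pair[2],
      " (pairing = ", x$pairing, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  if (nrow(x$unranked)) {
    cat("Unranked (undefined or infinite ratio):\n")
    print(x$unranked[, c("gene_id", "c_a", "nc_a", "c_b", "nc_b", "flag")],
          row.names = FALSE)
  }
  if (!is.null(x$skipped)) {
    cat("Skipped genes:\n"); print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' Reporter statistics over all ordered amino-acid pairs of one CDS
#'
#' Generalises the Cys/Met choice: one entry per ordered pair (A, B),
#' A != B, over the 20 standard amino acids. Entries with defined ratio
#' are sorted descending; undefined/infinite entries follow.
#'
#' @param cds a `coding_sequence`.
#' @param pairing near-cognate definition, see [codon_neighborhood()].
#' @return a data.frame with columns `a`, `b`, `c_a`, `nc_a`, `c_b`,
#'   `nc_b`, `ratio`, `flag`.
#' @export
scan_pairs <- function(cds, pairing = c("anticodon", "any")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(cds, "coding_sequence"))
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  aas <- Filter(function(a) {
    length(names(cds$code$codon_to_aa)[cds$code$codon_to_aa == a]) > 0
  }, aas)
  counts <- lapply(aas, function(a) {
    count_codons(cds, codon_neighborhood(a, cds$code, pairing = pairing))
  })
  names(counts) <- aas
  grid <- expand.grid(a = aas, b = aas, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$a[i]; b <- grid$b[i]
    st <- reporter_ratio(counts[[a]][["cognate"]], counts[[a]][["near_cognate"]],
                         counts[[b]][["cognate"]], counts[[b]][["near_cognate"]],
                         pair = c(a, b))
    data.frame(a = a, b = b, c_a = st$c_a, nc_a = st$nc_a, c_b = st$c_b,
               nc_b = st$nc_b, ratio = st$ratio, flag = st$flag,
               stringsAsFactors = FALSE)
  }))
  ok <- out[out$flag == "ok", , drop = FALSE]
  ok <- ok[order(-ok$ratio, ok$a, ok$b), , drop = FALSE]
  out <- rbind(ok, out[out$flag != "ok", , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write a reporter ranking as TSV
#'
#' Columns: rank, gene_id, c_a, nc_a, c_b, nc_b, ratio (full precision),
#' ratio_display (one decimal), flag; unranked entries appended with
#' empty rank.
#'
#' @param ranking a `reporter_ranking`.
#' @param path output path.
#' @return invisibly, the ranking.
#' @export
write_reporter_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "reporter_ranking"))
  tab <- ranking$table
  if (nrow(ranking$unranked)) {
    un <- ranking$unranked
    un$rank <- NA_integer_
    tab <- rbind(tab, un[, names(tab)])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ranking)
}
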