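# Synthetic-data generators. These produce genomes, CDS and replicate
# assay tables with the exact statistical structure the analysis modules
# assume, so every stage of the pipeline is testable without any external
# data. Planted codon compositions are exact by construction: reporter
# counts computed on a planted gene equal the requested counts.

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification for a synthetic multi-CDS genome
#'
#' @param n_genes number of CDS.
#' @param len_range two integers: range of CDS lengths in sense codons
#'   (including the initiator, excluding the terminal stop).
#' @param table_id NCBI translation table for all genes.
#' @param codon_usage optional named non-negative weights over codons used
#'   when drawing filler/background codons; defaults to uniform over
#'   non-stop, non-hungry codons.
#' @param strand_mix fraction of genes placed on the reverse strand.
#' @param terminal `"stop"` (complete stop codon) or `"hungry"` (terminal
#'   hungry codon, table permitting).
#' @param planted optional list of plantings, each a list with fields
#'   `gene` (index), `pair` (two amino acids), `c_a`, `nc_a`, `c_b`,
#'   `nc_b`; the generated gene reproduces these reporter counts exactly.
#' @param pairing near-cognate definition used for planting, see
#'   [codon_neighborhood()].
#' @param circular topology of the generated genome.
#' @param seed integer seed; all generation is deterministic given it.
#' @return a `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_genes = 5L, len_range = c(100L, 300L),
                                  table_id = 2L, codon_usage = NULL,
                                  strand_mix = 0, terminal = c("stop", "hungry"),
                                  planted = NULL,
                                  pairing = c("anticodon", "any"),
                                  circular = FALSE, seed = 1L) {
  terminal <- match.arg(terminal)
  pairing <- match.arg(pairing)
  stopifnot(n_genes >= 1L, length(len_range) == 2L,
            len_range[1] >= 3L, len_range[2] >= len_range[1],
            strand_mix >= 0, strand_mix <= 1)
  if (!is.null(planted)) {
    for (p in planted) {
      stopifnot(is.list(p), all(c("gene", "pair", "c_a", "nc_a", "c_b", "nc_b")
                                %in% names(p)))
      if (p$gene < 1L || p$gene > n_genes) stop("planted gene index out of range")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), len_range = as.integer(len_range),
         table_id = as.integer(table_id), codon_usage = codon_usage,
         strand_mix = strand_mix, terminal = terminal, planted = planted,
         pairing = pairing, circular = circular, seed = as.integer(seed)),
    class = "synthetic_genome_spec"
  )
}

sense_pool <- function(code, codon_usage = NULL) {
  pool <- setdiff(all_codons(), c(code$stop_codons, code$hungry_codons))
  w <- rep(1, length(pool))
  if (!is.null(codon_usage)) {
    w <- ifelse(pool %in% names(codon_usage), codon_usage[pool], 0)
    w[is.na(w)] <- 0
    if (all(w == 0)) stop("codon_usage assigns zero weight to every sense codon")
  }
  list(codons = pool, weights = as.numeric(w))
}

planting_for <- function(spec, gene_index) {
  if (is.null(spec$planted)) return(NULL)
  for (p in spec$planted) if (p$gene == gene_index) return(p)
  NULL
}

# Build the codon list for one synthetic gene (deterministic given spec).
build_codons <- function(spec, gene_index, code) {
  plant <- planting_for(spec, gene_index)
  pool <- sense_pool(code, spec$codon_usage)
  len <- if (spec$len_range[1] == spec$len_range[2]) spec$len_range[1] else
    sample(spec$len_range[1]:spec$len_range[2], 1L)

  terminal <- if (spec$terminal == "hungry") {
    if (!length(code$hungry_codons)) stop("table ", code$table_id,
                                          " has no hungry codons")
    code$hungry_codons[1L]
  } else {
    termination_stops(code)[1L]
  }

  if (is.null(plant)) {
    start <- "ATG"
    body <- if (len > 1L) sample(pool$codons, len - 1L, replace = TRUE,
                                 prob = pool$weights) else character(0)
    return(c(start, body, terminal))
  }

  a <- plant$pair[1]; b <- plant$pair[2]
  sa <- cognate_set(a, code)
  sb <- cognate_set(b, code)
  na <- codon_neighborhood(a, code, pairing = spec$pairing)$near_cognate_set
  nb <- codon_neighborhood(b, code, pairing = spec$pairing)$near_cognate_set
  drop <- c(code$stop_codons, code$hungry_codons)
  # disjoint placement pools so each planted codon contributes to exactly
  # one of the four counts
  pool_sa <- setdiff(sa, c(sb, nb, drop))
  pool_na <- setdiff(na, c(sb, nb, sa, drop))
  pool_sb <- setdiff(sb, c(sa, na, drop))
  pool_nb <- setdiff(nb, c(sa, na, sb, drop))

  need <- c(sa = plant$c_a, na = plant$nc_a, sb = plant$c_b, nb = plant$nc_b)

  # the initiator contributes to whatever category it falls in; pick a
  # start codon compatible with the requested composition
  start <- NA_character_
  for (cand in intersect(c("ATG", code$start_codons), code$start_codons)) {
    hit <- category_of(cand, pool_sa, pool_na, pool_sb, pool_nb)
    if (is.na(hit)) { start <- cand; break }
    if (need[[hit]] >= 1L) { start <- cand; need[[hit]] <- need[[hit]] - 1L; break }
  }
  if (is.na(start)) {
    stop("infeasible planting: every start codon of table ", code$table_id,
         " would overshoot a requested count of zero")
  }

  for (nm in names(need)) {
    pl <- switch(nm, sa = pool_sa, na = pool_na, sb = pool_sb, nb = pool_nb)
    if (need[[nm]] > 0L && !length(pl)) {
      stop("infeasible planting: no codon can realise the '", nm,
           "' requirement without disturbing the other counts")
    }
  }
  planted_codons <- c(
    sample_n(pool_sa, need[["sa"]]), sample_n(pool_na, need[["na"]]),
    sample_n(pool_sb, need[["sb"]]), sample_n(pool_nb, need[["nb"]]))

  # filler at Hamming distance >= 2 from both cognate sets, so the planted
  # counts stay exact
  filler_pool <- Filter(function(cod) {
    codon_hamming(cod, sa) >= 2L && codon_hamming(cod, sb) >= 2L
  }, setdiff(pool$codons, drop))
  n_fill <- len - 1L - length(planted_codons)
  if (n_fill < 0L) {
    stop("infeasible planting: requested counts need ",
         length(planted_codons) + 1L, " codons but length is ", len)
  }
  if (n_fill > 0L && !length(filler_pool)) {
    stop("infeasible planting: no filler codon at distance >= 2 from both cognate sets")
  }
  w <- sense_pool(code, spec$codon_usage)
  fw <- w$weights[match(filler_pool, w$codons)]
  if (all(fw == 0)) fw <- rep(1, length(filler_pool))
  filler <- if (n_fill > 0L) sample(filler_pool, n_fill, replace = TRUE,
                                    prob = fw) else character(0)
  body <- sample(c(planted_codons, filler))
  c(start, body, terminal)
}

category_of <- function(codon, pool_sa, pool_na, pool_sb, pool_nb) {
  if (codon %in% pool_sa) return("sa")
  if (codon %in% pool_na) return("na")
  if (codon %in% pool_sb) return("sb")
  if (codon %in% pool_nb) return("nb")
  NA_character_
}

sample_n <- function(pool, n) {
  if (n == 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

#' Generate one synthetic coding sequence
#'
#' Deterministic given `spec$seed` and `gene_index`. The CDS starts with a
#' start codon, contains no internal stop, and ends with a complete stop
#' (or a hungry codon when the spec requests it). When a planting is
#' attached to the gene, the realised reporter counts equal the planted
#' values exactly.
#'
#' @param spec a `synthetic_genome_spec`.
#' @param gene_index index of the gene within the spec.
#' @param utr3_len length of a generated 3' UTR, free of termination stops
#'   in frames 0 and -1 (emulating the MT-CO1 UTR property).
#' @return a `coding_sequence`.
#' @export
gen_cds <- function(spec, gene_index = 1L, utr3_len = 0L) {
  stopifnot(inherits(spec, "synthetic_genome_spec"),
            gene_index >= 1L, gene_index <= spec$n_genes)
  code <- genetic_code(spec$table_id)
  with_seed(spec$seed + 7919L * as.integer(gene_index), {
    codons <- build_codons(spec, gene_index, code)
    utr <- if (utr3_len > 0L) gen_stopfree_utr(utr3_len, code,
                                               last_nt = substr(codons[length(codons)], 3L, 3L))
           else ""
    synthetic_cds(codons, code, paste0("synth_", gene_index), utr)
  })
}

# Wrap a codon vector as a coding_sequence (no genome provenance).
synthetic_cds <- function(codons, code, gene_id, utr3 = "") {
  last <- codons[length(codons)]
  flag <- if (last %in% code$hungry_codons) "hungry"
          else if (last %in% code$stop_codons) "complete_stop"
          else "truncated"
  structure(
    list(gene_id = gene_id, nt_sequence = paste(codons, collapse = ""),
         codons = codons, terminal_codon = last, terminal_flag = flag,
         utr3 = utr3, utr3_truncated = FALSE, source_coords = NULL,
         code = code),
    class = "coding_sequence"
  )
}

# Random UTR with no termination stop in frame 0 or -1 over its window.
gen_stopfree_utr <- function(len, code, last_nt = "A", max_tries = 1000L) {
  stops <- termination_stops(code)
  for (i in seq_len(max_tries)) {
    utr <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    f0 <- split_codons(utr)
    fm1 <- split_codons(paste0(last_nt, utr))
    if (!any(f0 %in% stops) && !any(fm1 %in% stops)) return(utr)
  }
  stop("could not generate a stop-free UTR of length ", len)
}

#' Generate a synthetic annotated genome
#'
#' Concatenates the spec's genes with random intergenic spacers;
#' reverse-strand genes are stored reverse-complemented with the correct
#' feature strand, so the genome round-trips losslessly through
#' [extract_cds()].
#'
#' @param spec a `synthetic_genome_spec`.
#' @param spacer_range two integers: intergenic spacer length range in nt.
#' @return a `genome_record` with one CDS feature per gene.
#' @export
gen_genome <- function(spec, spacer_range = c(20L, 60L)) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  genes <- lapply(seq_len(spec$n_genes), function(i) gen_cds(spec, i))
  code <- genetic_code(spec$table_id)
  with_seed(spec$seed, {
    n <- spec$n_genes
    strands <- ifelse(stats::runif(n) < spec$strand_mix, "-", "+")
    spacers <- vapply(seq_len(n + 1L), function(i) {
      paste(sample(DNA_BASES, sample(spacer_range[1]:spacer_range[2], 1L),
                   replace = TRUE), collapse = "")
    }, character(1))
    seq <- spacers[1L]
    feats <- empty_features()
    for (i in seq_len(n)) {
      nt <- paste(genes[[i]]$codons, collapse = "")
      start <- nchar(seq) + 1L
      insert <- if (strands[i] == "-") revcomp(nt) else nt
      seq <- paste0(seq, insert, spacers[i + 1L])
      feats <- rbind(feats, data.frame(
        gene_id = genes[[i]]$gene_id, start = start,
        end = start + nchar(nt) - 1L, strand = strands[i],
        transl_table = spec$table_id, stringsAsFactors = FALSE))
    }
    genome_record(seq, feats, circular = spec$circular,
                  name = sprintf("synthetic_genome_seed%d", spec$seed))
  })
}

#' Generate synthetic dual-reporter assay replicates
#'
#' Reference replicates have a test/reference signal ratio of 1 and test
#' replicates a ratio of `fold_change_true`, each multiplied by
#' independent log-normal noise with the stated coefficient of variation
#' (mean-1 noise, so expectations are unbiased). Signals are positive and
#' ratio-scaled, matching luciferase-style readouts.
#'
#' @param fold_change_true generative fold change (> 0).
#' @param n_replicates replicates per group.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 for noiseless).
#' @param seed integer seed.
#' @param base_signal reference-channel signal scale.
#' @return list with data.frames `test` and `reference`, each with
#'   columns `group`, `test_signal`, `reference_signal`.
#' @export
gen_assay <- function(fold_change_true, n_replicates = 3L, noise_cv = 0,
                      seed = 1L, base_signal = 1e5) {
  stopifnot(fold_change_true > 0, n_replicates >= 1L, noise_cv >= 0)
  with_seed(seed, {
    sigma <- sqrt(log(1 + noise_cv^2))
    noise <- function(n) if (sigma == 0) rep(1, n) else
      exp(stats::rnorm(n, -sigma^2 / 2, sigma))
    mk <- function(group, fold) {
      data.frame(group = group,
                 test_signal = base_signal * fold * noise(n_replicates),
                 reference_signal = base_signal,
                 stringsAsFactors = FALSE)
    }
    list(test = mk("test", fold_change_true), reference = mk("reference", 1))
  })
}
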