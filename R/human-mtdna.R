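#' Load the human mitochondrial genome with its 13 protein-coding genes
#'
#' Returns the complete human mtDNA sequence as a circular
#' `genome_record` annotated with the 13 mtDNA-encoded CDS. The sequence
#' is the complete human mitochondrial reference record NC_001807.4
#' (16,571 bp) shipped as plain FASTA inside the seqinr package; the CDS
#' coordinate table travels with this package (coordinates on that record
#' are those of the revised Cambridge reference sequence plus one). The
#' two reference records differ at a small number of mostly synonymous
#' sites; MT-CO1 codon composition is identical between them, MT-CO2
#' differs at one synonymous site (see the package vignette).
#'
#' @param fasta optional path to an alternative human mtDNA FASTA (e.g. a
#'   downloaded copy of NC_012920 / J01415.2); the bundled coordinate
#'   table assumes NC_001807 numbering, so supply `features` as well when
#'   overriding.
#' @param features optional alternative feature table (path or
#'   data.frame).
#' @return a circular `genome_record` with 13 CDS features under
#'   translation table 2.
#' @examples
#' \donttest{
#' g <- human_mtdna_genome()
#' co1 <- extract_cds(g, "MT-CO1", utr3_len = 69)
#' }
#' @export
human_mtdna_genome <- function(fasta = NULL, features = NULL) {
  if (is.null(fasta)) {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("the bundled human mtDNA sequence is read from the seqinr package; ",
           "install seqinr or supply `fasta`")
    }
    fasta <- system.file("sequences", "humanMito.fasta", package = "seqinr")
    if (!nzchar(fasta)) stop("seqinr does not provide sequences/humanMito.fasta")
  }
  if (is.null(features)) {
    features <- system.file("extdata", "human_mtdna_cds.tsv",
                            package = "mitofidelity")
  }
  g <- read_genome(fasta, format = "fasta", features = features,
                   circular = TRUE)
  g$name <- "human mtDNA (NC_001807.4)"
  g
}
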