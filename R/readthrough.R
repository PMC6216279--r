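#' Stop-codon context of a coding sequence
#'
#' Scans the 3' UTR for stop codons in the continuation frame (0), after a
#' -1 frameshift, and after a +1 frameshift, and tests whether a -1 shift
#' at the terminal codon itself exposes a stop. At the human MT-CO1
#' terminus the hungry AGA codon stalls the mitoribosome and a -1 shift
#' creates a UAG recognised by the release factor; the 69-nt UTR contains
#' no stop in frame 0 or -1, so a ribosome that reads through instead
#' translates the UTR and the polyA tail.
#'
#' Positions are 0-based nt offsets of the first base of each stop codon
#' from the first nt of the 3' UTR; frame -1 codons start at offsets
#' -1, 2, 5, ... (the -1 codon borrows the last nt of the terminal codon).
#' Only termination stops (the decoding code's stop set minus its hungry
#' codons, which stall rather than terminate) are listed as stops; hungry
#' codon positions are reported separately per frame.
#'
#' @param cds a `coding_sequence` carrying a 3' UTR.
#' @param window scan width in nt; defaults to the full UTR. If the UTR is
#'   shorter than `window` the scan is truncated and flagged.
#' @param decode_code genetic code of the downstream (possibly
#'   read-through) ribosome; defaults to the CDS's own code.
#' @return a `stop_context`: list with `gene_id`, `terminal_codon`,
#'   `terminal_hungry` flag, `frame_stops` (named list `"0"`, `"-1"`,
#'   `"+1"` of integer offsets), `frame_hungry` (same shape),
#'   `minus1_stop_at_terminus`, `minus1_terminal_triplet`, `window`,
#'   `truncated`.
#' @export
stop_context <- function(cds, window = nchar(cds$utr3), decode_code = NULL) {
  stopifnot(inherits(cds, "coding_sequence"), window >= 0L)
  if (is.null(decode_code)) decode_code <- cds$code
  stopifnot(is_genetic_code(decode_code))
  stops <- termination_stops(decode_code)
  hungry <- decode_code$hungry_codons

  utr <- cds$utr3
  truncated <- nchar(utr) < window
  if (truncated) window <- nchar(utr)
  utr <- substr(utr, 1L, window)

  scan_frame <- function(seq0, first_offset) {
    # seq0 scanned in consecutive triplets; first triplet begins at
    # `first_offset` relative to the UTR start
    cods <- split_codons(seq0)
    offs <- first_offset + 3L * (seq_along(cods) - 1L)
    list(stops = offs[cods %in% stops], hungry = offs[cods %in% hungry])
  }

  f0 <- scan_frame(utr, 0L)
  fp1 <- scan_frame(substr(utr, 2L, window), 1L)
  last_nt <- substr(cds$terminal_codon, 3L, 3L)
  fm1 <- scan_frame(paste0(last_nt, utr), -1L)

  penult <- if (length(cds$codons) >= 2L) cds$codons[length(cds$codons) - 1L] else NA
  m1trip <- if (is.na(penult)) NA_character_ else
    paste0(substr(penult, 3L, 3L), substr(cds$terminal_codon, 1L, 2L))

  structure(
    list(gene_id = cds$gene_id,
         terminal_codon = cds$terminal_codon,
         terminal_hungry = cds$terminal_flag == "hungry",
         frame_stops = list(`0` = f0$stops, `-1` = fm1$stops, `+1` = fp1$stops),
         frame_hungry = list(`0` = f0$hungry, `-1` = fm1$hungry, `+1` = fp1$hungry),
         minus1_stop_at_terminus = !is.na(m1trip) && m1trip %in% stops,
         minus1_terminal_triplet = m1trip,
         window = window, truncated = truncated),
    class = "stop_context"
  )
}

#' @export
print.stop_context <- function(x, ...) {
  cat("Stop context of '", x$gene_id, "' (window ", x$window, " nt",
      if (x$truncated) ", truncated", ")\n", sep = "")
  cat("  terminal codon ", x$terminal_codon,
      if (x$terminal_hungry) " (hungry)", "\n", sep = "")
  cat("  -1 shift at terminus -> ", x$minus1_terminal_triplet,
      if (x$minus1_stop_at_terminus) " (stop exposed)" else " (no stop)",
      "\n", sep = "")
  for (f in c("0", "-1", "+1")) {
    s <- x$frame_stops[[f]]
    cat("  frame ", formatC(f, width = 2), ": ",
        if (length(s)) paste0("stop at ", paste(s, collapse = ", ")) else "no stop",
        "\n", sep = "")
  }
  invisible(x)
}

#' Predict the read-through product of a polyadenylated message
#'
#' Models cell-free translation of a construct `CDS body + terminal codon
#' + 3' UTR + polyA tail`. Under `terminal_policy = "decode"` the terminal
#' codon is decoded as a sense codon under `decode_code` (e.g. AGA
#' becomes Arg under the standard/bacterial code, the situation of the
#' MT-CO1-AGA construct on bacterial ribosomes); decoding then continues
#' codon by codon through the UTR and the polyA tail until a termination
#' stop of `decode_code` or the end of the message. A trailing partial
#' codon is not decoded. AAA is Lys under all supported tables, so a
#' polyA tail of length 3k appends k lysines.
#'
#' If the terminal codon is a termination stop under `decode_code` (the
#' MT-CO1-TGA construct), the extension is empty unless `suppress_stop`
#' forces read-through, in which case the stop decodes as
#' `suppression_aa`.
#'
#' @param cds a `coding_sequence` (carrying the construct's 3' UTR).
#' @param polyA_len polyA tail length in nt.
#' @param decode_code genetic code of the translating ribosome; defaults
#'   to the CDS's own code.
#' @param terminal_policy `"decode"` (decode terminal codon as sense) or
#'   `"skip"` (do not decode it; continue in frame after it).
#' @param suppress_stop force read-through of a terminal stop.
#' @param suppression_aa residue inserted at a suppressed stop (default
#'   Trp, the dominant UGA read-through identity).
#' @param mass_set passed to [protein_mw()].
#' @param init_as_met passed to [translate_cds()].
#' @return an `extension_result`: list with `gene_id`, `native_protein`,
#'   `extension_peptide`, `extended_protein`, `polyK_length`,
#'   `native_mw`, `extended_mw` (Da), `termination_reason`
#'   (`"stop-in-utr"`, `"end-of-message"` or `"stop-at-terminus"`).
#' @export
predict_readthrough <- function(cds, polyA_len = 0L, decode_code = NULL,
                                terminal_policy = c("decode", "skip"),
                                suppress_stop = FALSE, suppression_aa = "W",
                                mass_set = "average", init_as_met = TRUE) {
  terminal_policy <- match.arg(terminal_policy)
  stopifnot(inherits(cds, "coding_sequence"), polyA_len >= 0L)
  if (is.null(decode_code)) decode_code <- cds$code
  stops <- termination_stops(decode_code)

  native <- translate_cds(cds, init_as_met = init_as_met)
  ext <- character(0)
  reason <- "end-of-message"

  terminal_decoded <- TRUE
  if (cds$terminal_flag %in% c("complete_stop", "hungry")) {
    if (terminal_policy == "decode") {
      aa <- unname(decode_code$codon_to_aa[cds$terminal_codon])
      if (aa == "*") {
        if (suppress_stop) {
          ext <- suppression_aa
        } else {
          terminal_decoded <- FALSE
          reason <- "stop-at-terminus"
        }
      } else {
        ext <- aa
      }
    }
  }

  if (terminal_decoded) {
    tail_codons <- split_codons(paste0(cds$utr3, strrep("A", polyA_len)))
    for (cod in tail_codons) {
      if (cod %in% stops) { reason <- "stop-in-utr"; break }
      aa <- unname(decode_code$codon_to_aa[cod])
      if (aa == "*") { reason <- "stop-in-utr"; break }  # hungry under decode code
      ext <- c(ext, aa)
    }
  }

  extension <- paste(ext, collapse = "")
  extended <- paste0(native, extension)
  polyk <- attr(regexpr("K*$", extended), "match.length")

  structure(
    list(gene_id = cds$gene_id,
         native_protein = native,
         extension_peptide = extension,
         extended_protein = extended,
         polyK_length = as.integer(polyk),
         native_mw = protein_mw(native, mass_set),
         extended_mw = protein_mw(extended, mass_set),
         termination_reason = reason),
    class = "extension_result"
  )
}

#' @export
print.extension_result <- function(x, ...) {
  cat("Read-through prediction for '", x$gene_id, "'\n", sep = "")
  cat(sprintf("  native:   %d aa, %.1f kDa\n",
              nchar(x$native_protein), x$native_mw / 1000))
  cat(sprintf("  extended: %d aa, %.1f kDa (+%d aa, poly-Lys tract %d)\n",
              nchar(x$extended_protein), x$extended_mw / 1000,
              nchar(x$extension_peptide), x$polyK_length))
  cat("  termination:", x$termination_reason, "\n")
  invisible(x)
}
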