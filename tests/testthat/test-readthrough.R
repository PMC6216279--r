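test_that("stop context finds frame stops where the oracle does", {
  mito <- genetic_code(2)
  cds <- mitofidelity:::synthetic_cds(c("ATG", "CCT", "TAA"), mito, "x",
                                      utr3 = "TAAAAAAAA")
  ctx <- stop_context(cds)
  expect_equal(ctx$frame_stops[["0"]], 0L)  # TAA right at the UTR start

  stops <- mitofidelity:::termination_stops(mito)
  set.seed(17)
  for (i in 1:25) {
    utr <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    cds_i <- mitofidelity:::synthetic_cds(c("ATG", "CCT", "TAA"), mito, "r",
                                          utr3 = utr)
    ctx_i <- stop_context(cds_i)
    expect_equal(ctx_i$frame_stops[["0"]],
                 oracle_frame_stops(utr, stops, 0L))
    expect_equal(ctx_i$frame_stops[["-1"]],
                 oracle_frame_stops(utr, stops, -1L, prefix = "A"))
    expect_equal(ctx_i$frame_stops[["+1"]],
                 oracle_frame_stops(substr(utr, 2, 30), stops, 1L))
  }
})

test_that("the -1 shift at the terminus is read from the penultimate/terminal junction", {
  mito <- genetic_code(2)
  # ...TCT AGA: -1 triplet is T + AG = TAG, a stop
  cds <- mitofidelity:::synthetic_cds(c("ATG", "TCT", "AGA"), mito, "y",
                                      utr3 = "CCCCCC")
  ctx <- stop_context(cds)
  expect_equal(ctx$minus1_terminal_triplet, "TAG")
  expect_true(ctx$minus1_stop_at_terminus)
  expect_true(ctx$terminal_hungry)
  # ...CCT AGA: -1 triplet TAG again; ...CCA AGA gives AAG, no stop
  cds2 <- mitofidelity:::synthetic_cds(c("ATG", "CCA", "AGA"), mito, "z",
                                       utr3 = "CCCCCC")
  expect_false(stop_context(cds2)$minus1_stop_at_terminus)
})

test_that("hungry codons appear in the hungry track, not the stop track", {
  mito <- genetic_code(2)
  cds <- mitofidelity:::synthetic_cds(c("ATG", "CCT", "TAA"), mito, "h",
                                      utr3 = "AGACCCTAA")
  ctx <- stop_context(cds)
  expect_equal(ctx$frame_hungry[["0"]], 0L)   # AGA stalls
  expect_equal(ctx$frame_stops[["0"]], 6L)    # TAA terminates
})

test_that("protein_mw matches hand-computed masses and is additive", {
  expect_equal(protein_mw(""), 18.02, tolerance = 0.005)
  expect_equal(protein_mw("GG"), 132.12, tolerance = 0.01)
  expect_equal(protein_mw("", "monoisotopic"), 18.010565, tolerance = 1e-6)
  expect_error(protein_mw("GXG"), "position 2")
  set.seed(23)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:10) {
    p <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    q <- paste(sample(aas, 7, replace = TRUE), collapse = "")
    expect_equal(protein_mw(paste0(p, q)),
                 protein_mw(p) + protein_mw(q) - protein_mw(""),
                 tolerance = 1e-6)
  }
  expect_identical(protein_mw("MKWVTF"), protein_mw("MKWVTF"))
})

test_that("read-through decodes terminal codon, UTR and polyA until a stop or message end", {
  mito <- genetic_code(2)
  std <- genetic_code(1)
  # hungry AGA terminal decoded as Arg under the standard code, then a
  # stop-free UTR and the polyA tail: 51 nt of polyA give 17 lysines
  utr <- mitofidelity:::with_seed(3L, mitofidelity:::gen_stopfree_utr(9L, std))
  cds <- mitofidelity:::synthetic_cds(c("ATG", "GGT", "AGA"), mito, "aga",
                                      utr3 = utr)
  rt <- predict_readthrough(cds, polyA_len = 51L, decode_code = std)
  expect_equal(rt$polyK_length, 17L)
  expect_equal(rt$termination_reason, "end-of-message")
  expect_equal(substr(rt$extension_peptide, 1, 1), "R")
  expect_equal(nchar(rt$extension_peptide), 1 + 3 + 17)

  # +3 nt of polyA adds exactly one lysine while the message end terminates
  rt2 <- predict_readthrough(cds, polyA_len = 54L, decode_code = std)
  expect_equal(rt2$polyK_length, rt$polyK_length + 1L)

  # a trailing partial codon is not decoded
  rt_part <- predict_readthrough(cds, polyA_len = 52L, decode_code = std)
  expect_equal(rt_part$polyK_length, rt$polyK_length)

  # TGA construct: no read-through without suppression
  tga <- mitofidelity:::synthetic_cds(c("ATG", "GGT", "TGA"), std, "tga",
                                      utr3 = "TAACCC")
  no <- predict_readthrough(tga, polyA_len = 0L, decode_code = std)
  expect_equal(no$extension_peptide, "")
  expect_equal(no$termination_reason, "stop-at-terminus")
  # suppression forces read-through; the next in-frame TAA terminates
  yes <- predict_readthrough(tga, polyA_len = 9L, decode_code = std,
                             suppress_stop = TRUE)
  expect_equal(yes$extension_peptide, "W")
  expect_equal(yes$termination_reason, "stop-in-utr")
})

test_that("extension mass equals the extended-native difference and ignores the body", {
  mito <- genetic_code(2)
  std <- genetic_code(1)
  utr <- "CATCGGCAC"
  short <- mitofidelity:::synthetic_cds(c("ATG", "AGA"), mito, "s", utr3 = utr)
  long <- mitofidelity:::synthetic_cds(c("ATG", "GGT", "CCT", "AGA"), mito,
                                       "l", utr3 = utr)
  rs <- predict_readthrough(short, polyA_len = 6L, decode_code = std)
  rl <- predict_readthrough(long, polyA_len = 6L, decode_code = std)
  expect_equal(rs$extension_peptide, rl$extension_peptide)
  ext_mass <- protein_mw(rs$extension_peptide) - protein_mw("")
  expect_equal(rs$extended_mw - rs$native_mw, ext_mass, tolerance = 1e-6)
  expect_equal(rl$extended_mw - rl$native_mw, ext_mass, tolerance = 1e-6)
  expect_gt(rs$extended_mw, rs$native_mw)
})
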