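test_that("cognate sets match the code tables and reject absent amino acids", {
  expect_setequal(cognate_set("C", genetic_code(1)), c("TGT", "TGC"))
  expect_setequal(cognate_set("M", genetic_code(2)), c("ATG", "ATA"))
  expect_equal(cognate_set("M", genetic_code(1)), "ATG")
  # selenocysteine has no codon in these tables
  expect_error(cognate_set("U", genetic_code(1)), "no codon")
  # hungry codons never count as cognate: AGA/AGG are not Arg in table 2
  expect_false(any(c("AGA", "AGG") %in% cognate_set("R", genetic_code(2))))
})

test_that("Hamming neighbourhoods equal the brute-force oracle for all amino acids and tables", {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (tid in c(1L, 2L, 11L)) {
    code <- genetic_code(tid)
    for (aa in aas) {
      nb <- codon_neighborhood(aa, code, pairing = "any")
      expect_identical(nb$near_cognate_set, oracle_hamming_set(nb$cognate_set),
                       info = sprintf("aa %s table %d", aa, tid))
      # partition of the 64 codons by distance
      d <- nb$per_codon_distance
      expect_identical(length(nb$cognate_set) + length(nb$near_cognate_set) +
                         sum(d >= 2L), 64L)
      expect_length(intersect(nb$cognate_set, nb$near_cognate_set), 0)
    }
  }
  # the sizes behind the Cys/Met contrast
  expect_length(codon_neighborhood("C", genetic_code(1), "any")$near_cognate_set, 14)
  expect_length(codon_neighborhood("M", genetic_code(1), "any")$near_cognate_set, 9)
  expect_length(codon_neighborhood("M", genetic_code(2), "any")$near_cognate_set, 14)
})

test_that("anticodon neighbourhoods are the mismatch-1 shell of the Watson-Crick codon", {
  mito <- genetic_code(2)
  nc <- codon_neighborhood("C", mito, pairing = "anticodon")
  expect_equal(nc$reference_codon, "TGC")  # anticodon GCA
  expect_setequal(nc$near_cognate_set,
                  c("AGC", "CGC", "GGC", "TAC", "TCC", "TTC", "TGA", "TGG"))
  nm <- codon_neighborhood("M", mito, pairing = "anticodon")
  expect_equal(nm$reference_codon, "ATG")  # anticodon CAU
  expect_setequal(nm$near_cognate_set,
                  c("AAG", "ACG", "AGG", "ATC", "ATT", "CTG", "GTG", "TTG"))
  # always a subset of the distance-1 shell around the cognate set
  for (aa in c("C", "M", "K", "L", "S")) {
    any_nb <- codon_neighborhood(aa, mito, pairing = "any")
    ac_nb <- codon_neighborhood(aa, mito, pairing = "anticodon")
    expect_true(all(ac_nb$near_cognate_set %in% any_nb$near_cognate_set))
    expect_length(intersect(ac_nb$near_cognate_set, ac_nb$cognate_set), 0)
  }
  # explicit reference codon override
  nm2 <- codon_neighborhood("M", mito, pairing = "anticodon",
                            reference_codon = "ATA")
  expect_true("ACA" %in% nm2$near_cognate_set)
  expect_error(codon_neighborhood("M", mito, reference_codon = "TTT"),
               "cognate")
})

test_that("stop neighbours can be excluded from the neighbourhood", {
  mito <- genetic_code(2)
  with_stops <- codon_neighborhood("C", mito, "any")$near_cognate_set
  without <- codon_neighborhood("C", mito, "any",
                                include_stop_neighbors = FALSE)$near_cognate_set
  expect_setequal(setdiff(with_stops, without),
                  intersect(with_stops, mito$stop_codons))
})

test_that("codon counting matches an independent per-codon loop and its invariants", {
  mito <- genetic_code(2)
  nb <- codon_neighborhood("C", mito, pairing = "anticodon")

  # planted 20-codon CDS: 3 cognate, 4 near-cognate by construction
  codons <- c("ATG", "TGT", "TGC", "TGT", "TCC", "TTC", "GGC", "TAC",
              rep("CCC", 11), "TAA")
  cds <- mitofidelity:::synthetic_cds(codons, mito, "planted")
  got <- count_codons(cds, nb)
  sense <- codons[-length(codons)]
  expect_identical(unname(got["cognate"]), oracle_count(sense, nb$cognate_set))
  expect_identical(unname(got["near_cognate"]),
                   oracle_count(sense, nb$near_cognate_set))
  expect_identical(unname(got[c("cognate", "near_cognate")]), c(3L, 4L))

  # permutation invariance of the body
  set.seed(42)
  perm <- c(codons[1], sample(codons[2:19]), codons[20])
  got_p <- count_codons(mitofidelity:::synthetic_cds(perm, mito, "perm"), nb)
  expect_identical(got_p, got)

  # monotonicity: appending one codon moves counts by at most one unit
  for (extra in c("TGT", "TCC", "CCC")) {
    grown <- mitofidelity:::synthetic_cds(
      c(codons[-length(codons)], extra, "TAA"), mito, "grown")
    delta <- count_codons(grown, nb)[1:2] - got[1:2]
    expect_true(sum(delta) <= 1 && all(delta >= 0))
  }

  # empty codon list
  empty <- mitofidelity:::synthetic_cds(c("TAA"), mito, "empty")
  expect_identical(unname(count_codons(empty, nb)[1:2]), c(0L, 0L))

  # include_terminal counts the hungry codon (AGA is a Met-ATA neighbour
  # under Hamming pairing)
  nmh <- codon_neighborhood("M", mito, pairing = "any")
  hung <- mitofidelity:::synthetic_cds(c("ATG", "CCC", "AGA"), mito, "h")
  expect_equal(unname(count_codons(hung, nmh)["near_cognate"]), 0L)
  expect_equal(unname(count_codons(hung, nmh, include_terminal = TRUE)["near_cognate"]), 1L)

  # code mismatch is an error
  std_nb <- codon_neighborhood("C", genetic_code(1))
  expect_error(count_codons(cds, std_nb), "different genetic codes")
})

test_that("Met near-cognate counts relate across codes as the table structure implies", {
  # table 1 Met neighbourhood is the table 2 neighbourhood minus the
  # members that exist only because ATA is cognate in table 2, plus ATA
  n1 <- codon_neighborhood("M", genetic_code(1), "any")$near_cognate_set
  n2 <- codon_neighborhood("M", genetic_code(2), "any")$near_cognate_set
  only2 <- setdiff(n2, n1)
  set.seed(7)
  pool <- mitofidelity:::all_codons()
  for (i in 1:20) {
    cods <- sample(pool, 60, replace = TRUE)
    c1 <- oracle_count(cods, n1)
    c2 <- oracle_count(cods, n2)
    expect_lte(c1, c2 + oracle_count(cods, setdiff(n1, n2)))
  }
})
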