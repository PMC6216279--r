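test_that("generated CDS satisfy the coding-sequence invariants", {
  for (seed in c(1L, 2L, 3L)) {
    spec <- synthetic_genome_spec(n_genes = 3L, len_range = c(30L, 80L),
                                  table_id = 2L, seed = seed)
    code <- genetic_code(2)
    for (i in 1:3) {
      cds <- gen_cds(spec, i)
      expect_true(cds$codons[1] %in% code$start_codons)
      body <- cds$codons[-length(cds$codons)]
      expect_false(any(code$codon_to_aa[body] == "*"))
      expect_equal(cds$terminal_flag, "complete_stop")
      expect_equal(nchar(cds$nt_sequence) %% 3, 0)
    }
  }
  hung <- synthetic_genome_spec(n_genes = 1L, len_range = c(20L, 20L),
                                table_id = 2L, terminal = "hungry", seed = 4L)
  expect_equal(gen_cds(hung, 1L)$terminal_flag, "hungry")
})

test_that("planted compositions are reproduced exactly across many random specs", {
  set.seed(100)
  pairs <- list(c("C", "M"), c("W", "F"), c("H", "K"))
  for (rep in 1:40) {
    pair <- pairs[[sample(3, 1)]]
    counts <- sample(0:8, 4, replace = TRUE)
    counts[3] <- counts[3] + 1L  # keep the start-codon budget feasible
    len <- sum(counts) + sample(30:60, 1)
    spec <- synthetic_genome_spec(
      n_genes = 1L, len_range = c(len, len), table_id = 2L,
      seed = sample(1e6, 1),
      planted = list(list(gene = 1L, pair = pair, c_a = counts[1],
                          nc_a = counts[2], c_b = counts[3], nc_b = counts[4])))
    cds <- gen_cds(spec, 1L)
    code <- genetic_code(2)
    na <- codon_neighborhood(pair[1], code)
    nb <- codon_neighborhood(pair[2], code)
    sense <- mitofidelity:::sense_codons(cds)
    expect_identical(oracle_count(sense, na$cognate_set), counts[1])
    expect_identical(oracle_count(sense, na$near_cognate_set), counts[2])
    expect_identical(oracle_count(sense, nb$cognate_set), counts[3])
    expect_identical(oracle_count(sense, nb$near_cognate_set), counts[4])
    expect_length(sense, len)
  }
})

test_that("infeasible plantings fail with a named constraint", {
  # requested codons exceed the CDS length
  spec <- synthetic_genome_spec(
    n_genes = 1L, len_range = c(10L, 10L), table_id = 2L, seed = 1L,
    planted = list(list(gene = 1L, pair = c("C", "M"), c_a = 20L, nc_a = 0L,
                        c_b = 1L, nc_b = 0L)))
  expect_error(gen_cds(spec, 1L), "infeasible planting")
  expect_error(synthetic_genome_spec(n_genes = 1L,
                                     planted = list(list(gene = 5L,
                                                         pair = c("C", "M"),
                                                         c_a = 1, nc_a = 1,
                                                         c_b = 1, nc_b = 1))),
               "out of range")
})

test_that("generation is deterministic given the seed", {
  spec <- synthetic_genome_spec(n_genes = 2L, len_range = c(40L, 90L),
                                table_id = 2L, strand_mix = 0.5, seed = 77L)
  expect_identical(gen_cds(spec, 1L)$nt_sequence, gen_cds(spec, 1L)$nt_sequence)
  g1 <- gen_genome(spec)
  g2 <- gen_genome(spec)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  a1 <- gen_assay(1.4, 5, 0.2, seed = 12)
  a2 <- gen_assay(1.4, 5, 0.2, seed = 12)
  expect_identical(a1, a2)
})

test_that("generated genomes round-trip losslessly through extraction", {
  one <- synthetic_genome_spec(n_genes = 1L, len_range = c(50L, 50L),
                               table_id = 2L, seed = 31L)
  g <- gen_genome(one)
  back <- extract_cds(g, "synth_1")
  expect_identical(back$nt_sequence, gen_cds(one, 1L)$nt_sequence)

  rev_spec <- synthetic_genome_spec(n_genes = 3L, len_range = c(30L, 60L),
                                    table_id = 2L, strand_mix = 1, seed = 32L)
  gr <- gen_genome(rev_spec)
  expect_true(all(gr$features$strand == "-"))
  for (i in 1:3) {
    back_i <- extract_cds(gr, paste0("synth_", i))
    expect_identical(back_i$nt_sequence, gen_cds(rev_spec, i)$nt_sequence)
    # strand oracle: forward extraction on the globally reverse-complemented
    # genome with mirrored coordinates gives the same CDS
    len <- nchar(gr$sequence)
    f <- gr$features[i, ]
    mirror <- genome_record(revcomp(gr$sequence),
                            data.frame(gene_id = f$gene_id,
                                       start = len - f$end + 1L,
                                       end = len - f$start + 1L,
                                       strand = "+", transl_table = 2L))
    expect_identical(extract_cds(mirror, f$gene_id)$nt_sequence,
                     back_i$nt_sequence)
  }
})

test_that("assay generation has the stated noise structure", {
  exact <- gen_assay(1.5, 3, noise_cv = 0, seed = 1)
  n <- normalize_dual_reporter(exact$test, exact$reference)
  expect_identical(n$fold_change, 1.5)

  null <- gen_assay(1, 1000, noise_cv = 0.3, seed = 6)
  nn <- normalize_dual_reporter(null$test, null$reference)
  sem <- nn$groups$sem[nn$groups$group == "test"]
  expect_lt(abs(nn$fold_change - 1), 3 * sem)
})
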