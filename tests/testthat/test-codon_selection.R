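test_that("codon site counts match exhaustive single-base enumeration", {
  expect_equal(codon_site_counts("TTT")[["syn"]], 1 / 3, tolerance = 1e-12)
  expect_equal(codon_site_counts("ATG")[["syn"]], 0)
  expect_equal(codon_site_counts("GGG")[["syn"]], 1)  # fully degenerate 3rd pos

  # independent enumeration oracle (ignoring the stop-exclusion refinement
  # where no stop is reachable)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cod in sample(sense, 15)) {
    sc <- codon_site_counts(cod)
    expect_equal(sc[["syn"]] + sc[["nonsyn"]], 3, tolerance = 1e-12)
    syn_oracle <- 0
    for (pos in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))
      muts <- vapply(alts, function(b) { m <- cod; substr(m, pos, pos) <- b; m },
                     character(1))
      keep <- code[muts] != "*"
      if (any(keep)) {
        syn_oracle <- syn_oracle + sum(code[muts[keep]] == code[cod]) / sum(keep)
      }
    }
    expect_equal(sc[["syn"]], unname(syn_oracle), tolerance = 1e-12)
  }
  expect_error(codon_site_counts("TAA"), "stop")
  expect_error(codon_site_counts("ANT"), "ambiguity")
})

test_that("pairwise codon differences average over stop-free pathways", {
  expect_equal(as.numeric(pairwise_codon_differences("TTT", "TTT")), c(0, 0))
  expect_equal(as.numeric(pairwise_codon_differences("TTT", "TTA")), c(0, 1))
  expect_equal(as.numeric(pairwise_codon_differences("TTT", "GTA")), c(0.5, 1.5))
  # symmetry over random codon pairs
  withr::local_seed(11)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (r in 1:20) {
    pair <- sample(sense, 2)
    expect_equal(pairwise_codon_differences(pair[1], pair[2]),
                 pairwise_codon_differences(pair[2], pair[1]))
  }
  # a pair whose k differences always sum: syn + nonsyn = hamming
  d <- pairwise_codon_differences("AAA", "GGG")
  expect_equal(sum(d), 3, tolerance = 1e-12)
})

test_that("Nei-Gojobori distances behave on boundary alignments", {
  part <- codon_partition(1L, 2L)
  ident <- make_aln(rep("TTTGGG", 4))
  d <- nei_gojobori_distances(ident, part, "all")
  expect_equal(d$dN, 0); expect_equal(d$dS, 0)

  # one nonsynonymous difference inside the PBR codon, nothing elsewhere
  aln <- make_aln(c("TTTGGG", "TTTGGG", "CTTGGG", "CTTGGG"))
  dp <- nei_gojobori_distances(aln, part, "pbr")
  expect_equal(dp$dS, 0)
  expect_gt(dp$dN, 0)
  expect_true(is.na(dp$ratio))
  dn <- nei_gojobori_distances(aln, part, "nonpbr")
  expect_equal(dn$dN, 0); expect_equal(dn$dS, 0)
})

test_that("PBR and non-PBR subsets jointly reproduce the all-codon analysis", {
  withr::local_seed(31)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  seqs <- replicate(8, paste(sample(sense, 6, replace = TRUE), collapse = ""))
  aln <- make_aln(seqs)
  part <- codon_partition(c(1, 3, 5), 6)
  all_d <- nei_gojobori_distances(aln, part, "all")
  union_part <- codon_partition(1:6, 6)
  union_d <- nei_gojobori_distances(aln, union_part, "pbr")
  expect_equal(all_d$dN, union_d$dN, tolerance = 1e-12)
  expect_equal(all_d$dS, union_d$dS, tolerance = 1e-12)
})

test_that("bootstrap z-test is seeded, stable and flags monomorphic subsets", {
  withr::local_seed(5)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  seqs <- replicate(10, paste(sample(sense, 8, replace = TRUE), collapse = ""))
  aln <- make_aln(seqs)
  part <- codon_partition(1:4, 8)

  r1 <- selection_z_test(aln, part, "all", n_bootstrap = 200, seed = 42)
  r2 <- selection_z_test(aln, part, "all", n_bootstrap = 200, seed = 42)
  expect_identical(r1$z, r2$z)
  expect_true(r1$p >= 0 && r1$p <= 1)
  expect_gte(r1$dN_se, 0); expect_gte(r1$dS_se, 0)

  # doubling the bootstrap changes z by only a few percent
  r4 <- selection_z_test(aln, part, "all", n_bootstrap = 800, seed = 43)
  expect_lt(abs(r4$z - r1$z) / abs(r1$z), 0.05)

  mono <- selection_z_test(make_aln(rep("TTTGGGAAACCC", 4)),
                           codon_partition(1:2, 4), "all",
                           n_bootstrap = 100, seed = 1)
  expect_false(mono$applicable)

  # mutations placed only at synonymous positions leave dN at zero
  syn_aln <- make_aln(c("GGAGGA", "GGAGGA", "GGGGGA", "GGGGGA"))
  ds <- nei_gojobori_distances(syn_aln, codon_partition(1L, 2L), "all")
  expect_equal(ds$dN, 0)
  expect_gt(ds$dS, 0)
})

test_that("PBR variable-site tally classifies columns by codon membership", {
  part <- codon_partition(1L, 2L)
  none <- pbr_variable_site_tally(make_aln(rep("TTTGGG", 4)), part)
  expect_equal(none$variable_sites_total, 0L)

  one <- pbr_variable_site_tally(make_aln(c("TTTGGG", "TTTGGG",
                                            "TTAGGG", "TTAGGG")), part)
  expect_equal(one$variable_sites_in_pbr, 1L)
  expect_equal(one$variable_sites_total, 1L)

  both <- pbr_variable_site_tally(make_aln(c("TTTGGG", "TTTGGG",
                                             "TTAGGA", "TTAGGA")), part)
  expect_equal(both$variable_sites_in_pbr, 1L)
  expect_equal(both$variable_sites_total, 2L)
})
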