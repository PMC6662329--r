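test_that("haplotype pools are distinct, stop-free and respect placement weights", {
  cfg <- scenario_config("paper_like", seed = 5)
  pool <- generate_haplotype_pool(cfg, "A")
  expect_equal(length(pool$haplotypes), cfg$populations$A$n_haplotypes)
  expect_equal(length(unique(pool$haplotypes)), length(pool$haplotypes))
  expect_equal(sum(pool$freqs), 1, tolerance = 1e-12)
  # no stop codons anywhere in frame
  off <- cfg$amplicon$frame_offset
  for (h in pool$haplotypes) {
    cods <- substring(h, off + seq(1, 3 * 56, by = 3), off + seq(3, 3 * 56, by = 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  }

  # weights (1,0,0): every variable site is PBR-nonsynonymous
  cfg2 <- scenario_config("paper_like", seed = 6)
  cfg2$populations$A$placement_weights <-
    c(pbr_nonsyn = 1, pbr_syn = 0, nonpbr = 0)
  pool2 <- generate_haplotype_pool(cfg2, "A")
  expect_true(all(pool2$sites$class == "pbr_nonsyn"))
  sim2 <- simulate_population(cfg2, "A", pool = pool2)
  tl <- pbr_variable_site_tally(sim2$alignment, pool2$partition)
  expect_equal(tl$variable_sites_in_pbr, tl$variable_sites_total)

  # K = 1: monomorphic pool, downstream pi = 0
  cfg3 <- scenario_config("paper_like", seed = 7)
  cfg3$populations$B$n_haplotypes <- 1L
  sim3 <- simulate_population(cfg3, "B")
  expect_equal(diversity_summary(sim3$alignment)$pi, 0)
})

test_that("PBR placement weight sweep moves the PBR variable-site fraction up", {
  fracs <- vapply(c(0.2, 0.6, 0.95), function(wp) {
    cfg <- scenario_config("paper_like", seed = 40)
    cfg$populations$A$placement_weights <-
      c(pbr_nonsyn = wp, pbr_syn = 0.0, nonpbr = 1 - wp)
    pool <- generate_haplotype_pool(cfg, "A")
    mean(pool$sites$class != "nonpbr")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("simulated populations are reproducible and near HWE", {
  cfg <- scenario_config("paper_like", seed = 9)
  s1 <- simulate_population(cfg, "B")
  s2 <- simulate_population(cfg, "B")
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)
  expect_identical(s1$metadata, s2$metadata)

  # individual heterozygosity matches 1 - sum(p^2) of the pool
  pool <- generate_haplotype_pool(cfg, "B")
  cfg$populations$B$n_individuals <- 1000L
  sim <- simulate_population(cfg, "B", pool = pool, seed = 42)
  ids <- matrix(match(sim$alignment$sequences, pool$haplotypes), ncol = 2,
                byrow = TRUE)
  het_obs <- mean(ids[, 1] != ids[, 2])
  het_exp <- 1 - sum(pool$freqs^2)
  expect_lt(abs(het_obs - het_exp), 0.04)

  # demographic composition recovered within multinomial error
  comp <- composition_of(sim$metadata)
  expect_lt(abs(comp$age_class[["adult"]] / 1000 - 38 / 55), 0.05)
  expect_lt(abs(comp$sex[["male"]] / 1000 - 32 / 55), 0.05)
})

test_that("msat simulation honours missing rate, F knob and shared frequencies", {
  cfg <- scenario_config("paper_like", seed = 15)
  cfg$msat$missing_rate <- 0
  ds <- simulate_msat(cfg, "B")
  expect_equal(sum(is.na(ds$allele1)), 0L)

  # strong inbreeding knob flags HWE at n = 500
  cfg2 <- scenario_config("paper_like", seed = 16)
  cfg2$populations$A$n_individuals <- 500L
  cfg2$msat$inbreeding_f <- 0.5
  cfg2$msat$missing_rate <- 0
  ds2 <- simulate_msat(cfg2, "A")
  ps <- vapply(ds2$loci[1:10], function(l) hwe_test(ds2, l, "A")$p, numeric(1))
  expect_true(all(ps < 1e-4, na.rm = TRUE))

  # one frequency realisation shared between the populations
  freqs <- divcompare:::.msat_frequencies(cfg, derive_seed(cfg$seed, 410L))
  da <- simulate_msat(cfg, "A", freqs = freqs)
  db <- simulate_msat(cfg, "B", freqs = freqs)
  expect_equal(length(da$loci), length(db$loci))
})

test_that("scenario bundles round-trip through the readers with a manifest", {
  cfg <- scenario_config("paper_like", seed = 33)
  cfg$populations$A$n_individuals <- 30L
  cfg$populations$B$n_individuals <- 20L
  out <- withr::local_tempdir()
  manifest <- generate_scenario(cfg, out)
  expect_setequal(manifest$files,
                  c("alignment.fasta", "genotypes.csv", "metadata.csv",
                    "pbr_partition.json"))
  md <- read_metadata_csv(file.path(out, "metadata.csv"))
  aln <- read_phased_fasta(file.path(out, "alignment.fasta"),
                           frame_offset = cfg$amplicon$frame_offset,
                           population = stats::setNames(md$population, md$id))
  ds <- read_genotype_csv(file.path(out, "genotypes.csv"))
  part <- read_codon_partition(file.path(out, "pbr_partition.json"),
                               manifest$amplicon$total_codons)
  expect_equal(length(aln$sequences), manifest$n_sequences)
  expect_equal(length(ds$individuals), manifest$n_msat_individuals)
  expect_equal(length(ds$loci), manifest$n_loci)
  expect_equal(length(part$pbr_codons), cfg$amplicon$n_pbr)

  # determinism: regenerating with the same config reproduces the files
  out2 <- withr::local_tempdir()
  generate_scenario(cfg, out2)
  expect_identical(readLines(file.path(out, "alignment.fasta")),
                   readLines(file.path(out2, "alignment.fasta")))
  expect_identical(readLines(file.path(out, "genotypes.csv")),
                   readLines(file.path(out2, "genotypes.csv")))
})
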