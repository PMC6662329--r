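test_that("segregating sites and Eta count multi-allelic columns once per extra allele", {
  aln <- make_aln(c("AAAAAAAAAA", "AAAAAAAAAA", "TAAAAAAAAA", "TAAAAAAAAA"))
  se <- segregating_sites_and_eta(aln)
  expect_equal(se$S, 1L); expect_equal(se$eta, 1L)

  tri <- make_aln(c("AAAAAAAAAA", "CAAAAAAAAA", "TAAAAAAAAA", "TAAAAAAAAA"))
  se2 <- segregating_sites_and_eta(tri)
  expect_equal(se2$S, 1L); expect_equal(se2$eta, 2L)

  mono <- make_aln(rep("ACGTACGTAC", 4))
  se3 <- segregating_sites_and_eta(mono)
  expect_equal(se3$S, 0L); expect_equal(se3$eta, 0L)

  gapped <- make_aln(c("A-GTACGTAC", "ACGTACGTAC"))
  expect_equal(segregating_sites_and_eta(gapped)$L, 9L)
  all_gap <- make_aln(c("---", "---"))
  expect_error(segregating_sites_and_eta(all_gap), "degenerate")
})

test_that("pi, Hd and theta reproduce hand-computed values", {
  base <- strrep("A", 100)
  s2 <- base; substr(s2, 1, 2) <- "CC"
  aln <- make_aln(c(base, base, s2, s2))
  d <- diversity_summary(aln)
  expect_equal(d$pi, 4 * 0.02 / 6, tolerance = 1e-12)
  expect_equal(d$Hd, (4 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(d$theta_w, 2 / ((1 + 1/2 + 1/3) * 100), tolerance = 1e-12)
  expect_equal(d$theta_w, d$theta_eta)  # both sites biallelic

  two <- make_aln(c("AAAAAAAAAA", "TAAAAAAAAA"))
  expect_equal(nucleotide_diversity(two)$pi, 0.1, tolerance = 1e-12)

  th <- theta_estimators(S = 3, eta = 3, n = 2, L = 100)
  expect_equal(th$theta_w, 0.03, tolerance = 1e-12)

  mono <- diversity_summary(make_aln(rep(strrep("ACGT", 5), 4)))
  expect_equal(mono$pi, 0); expect_equal(mono$Hd, 0)
  expect_equal(mono$theta_w, 0); expect_equal(mono$theta_eta, 0)

  single <- phased_alignment(c("ACGTAC", "ACGTAC"), c("i1", "i1"), 1:2, "p")
  expect_error(nucleotide_diversity(
    structure(list(sequences = "ACGTAC", mat = matrix(strsplit("ACGTAC", "")[[1]], 1)),
              class = "phased_alignment")), "insufficient")
  expect_s3_class(diversity_summary(single), "diversity_summary")
})

test_that("frequency-form pi equals brute force over pairs (random alignments)", {
  withr::local_seed(421)
  for (r in 1:40) {
    aln <- random_alignment(n_ind = sample(2:6, 1), L = sample(10:40, 1),
                            n_var = sample(0:6, 1))
    expect_equal(nucleotide_diversity(aln)$pi, oracle_pi(aln),
                 tolerance = 1e-12)
  }
})

test_that("theta_w equals theta_eta exactly when all segregating sites are biallelic", {
  withr::local_seed(99)
  for (r in 1:25) {
    aln <- random_alignment(n_ind = sample(3:8, 1), L = 25, n_var = sample(1:6, 1))
    se <- segregating_sites_and_eta(aln)
    biallelic <- se$S == se$eta
    th <- theta_estimators(se$S, se$eta, length(aln$sequences), se$L)
    if (biallelic) expect_identical(th$theta_w, th$theta_eta)
  }
})

test_that("Hd respects its sample-corrected bound and duplication invariance", {
  withr::local_seed(7)
  for (r in 1:20) {
    aln <- random_alignment(n_ind = sample(3:6, 1), L = 20, n_var = sample(1:5, 1))
    n <- length(aln$sequences)
    hd <- haplotype_diversity(aln)
    # duplicating the whole sample leaves sum(x^2) unchanged: Hd changes
    # only through the n/(n-1) correction
    dup <- make_aln(c(aln$sequences, aln$sequences))
    hd_dup <- haplotype_diversity(dup)
    s2 <- 1 - hd$Hd * (n - 1) / n
    s2_dup <- 1 - hd_dup$Hd * (2 * n - 1) / (2 * n)
    expect_equal(s2, s2_dup, tolerance = 1e-12)
    # adding one copy of an existing variant cannot push Hd above the
    # previous sample-corrected ceiling
    extra <- make_aln(c(aln$sequences, aln$sequences[c(1, 1)]))
    expect_lte(haplotype_diversity(extra)$Hd, (n + 2) / (n + 1))
    expect_gte(hd$Hd, 0); expect_lte(hd$Hd, 1 + 1e-12)
  }
})

test_that("variance formulas give positive SDs scaling like the estimators", {
  aln <- random_alignment(n_ind = 10, L = 50, n_var = 8)
  d <- diversity_summary(aln)
  expect_gt(d$pi_sd, 0); expect_gt(d$Hd_sd, 0); expect_gt(d$theta_w_sd, 0)
  asym <- haplotype_diversity(aln, variant = "asymptotic")
  expect_gte(asym$Hd_sd, 0)
  expect_equal(asym$Hd, haplotype_diversity(aln)$Hd)
})
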