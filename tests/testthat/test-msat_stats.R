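make_ds <- function(a1, a2, pop = NULL, loci = NULL) {
  n <- nrow(as.matrix(a1))
  msat_dataset(sprintf("i%d", seq_len(n)),
               loci %||% sprintf("L%d", seq_len(ncol(as.matrix(a1)))),
               a1, a2, pop %||% "p")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("allele frequencies sum to one and reject empty loci", {
  ds <- make_ds(cbind(c(150L, 150L)), cbind(c(152L, 150L)))
  f <- allele_frequencies(ds, "L1")
  expect_equal(unname(f), c(0.75, 0.25))
  expect_equal(sum(f), 1)
  empty <- make_ds(cbind(c(NA_integer_, NA_integer_)), cbind(c(NA_integer_, NA_integer_)))
  expect_error(allele_frequencies(empty, "L1"), "empty")

  withr::local_seed(3)
  for (r in 1:50) {
    n <- sample(3:20, 1)
    a <- matrix(sample(1:6, 2 * n, replace = TRUE), ncol = 2)
    ds <- make_ds(cbind(a[, 1]), cbind(a[, 2]))
    expect_equal(sum(allele_frequencies(ds, "L1")), 1, tolerance = 1e-12)
  }
})

test_that("locus diversity reproduces closed-form values and He = 1 - 1/Ae", {
  mono <- make_ds(cbind(rep(5L, 4)), cbind(rep(5L, 4)))
  d <- locus_diversity(mono, "L1")
  expect_equal(d$Ho, 0); expect_equal(d$He, 0)
  expect_equal(d$Ae, 1); expect_equal(d$shannon, 0)

  # frequencies (0.5, 0.25, 0.25) over 8 allele copies
  ds <- make_ds(cbind(c(1L, 1L, 2L, 3L)), cbind(c(1L, 1L, 2L, 3L)))
  d2 <- locus_diversity(ds, "L1")
  expect_equal(d2$Ae, 1 / (0.25 + 0.0625 + 0.0625), tolerance = 1e-9)
  expect_equal(d2$Ae, 2.6667, tolerance = 1e-4)
  expect_equal(d2$shannon, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-9)
  expect_equal(d2$shannon, 1.0397, tolerance = 1e-4)

  withr::local_seed(14)
  for (r in 1:30) {
    n <- sample(5:30, 1)
    a1 <- matrix(sample(1:5, n, replace = TRUE), ncol = 1)
    a2 <- matrix(sample(1:5, n, replace = TRUE), ncol = 1)
    d <- locus_diversity(make_ds(a1, a2), "L1")
    expect_equal(d$He, 1 - 1 / d$Ae, tolerance = 1e-12)
    expect_gte(d$Ae, 1); expect_lte(d$Ae, d$Na + 1e-12)
  }

  unb <- locus_diversity(ds, "L1", unbiased = TRUE)
  expect_equal(unb$He, d2$He * 8 / 7, tolerance = 1e-12)
})

test_that("HWE chi-square matches expectations at equilibrium and extremes", {
  # 25 AA, 50 Aa, 25 aa: exact HWE
  a1 <- c(rep(1L, 25), rep(1L, 50), rep(2L, 25))
  a2 <- c(rep(1L, 25), rep(2L, 50), rep(2L, 25))
  ds <- make_ds(cbind(a1), cbind(a2))
  h <- hwe_test(ds, "L1")
  expect_equal(h$chisq, 0, tolerance = 1e-12)
  expect_equal(h$p, 1)
  expect_equal(h$df, 1L)

  # total heterozygote deficit: chi-square equals n
  a1 <- c(rep(1L, 50), rep(2L, 50)); a2 <- a1
  h2 <- hwe_test(make_ds(cbind(a1), cbind(a2)), "L1")
  expect_equal(h2$chisq, 100, tolerance = 1e-9)
  expect_lt(h2$p, 1e-10)

  mono <- hwe_test(make_ds(cbind(rep(1L, 10)), cbind(rep(1L, 10))), "L1")
  expect_false(mono$applicable)

  mc1 <- hwe_test(ds, "L1", method = "mc", n_mc = 300, seed = 5)
  mc2 <- hwe_test(ds, "L1", method = "mc", n_mc = 300, seed = 5)
  expect_identical(mc1$p, mc2$p)
  expect_gte(mc1$p, 1 / 301)
})

test_that("LD permutation test detects perfect association and is seeded", {
  withr::local_seed(21)
  g <- sample(1:3, 40, replace = TRUE)
  h <- sample(1:3, 40, replace = TRUE)
  a1 <- cbind(g, g)  # locus 2 duplicates locus 1
  a2 <- cbind(h, h)
  ds <- make_ds(a1, a2)
  r <- ld_permutation_test(ds, "L1", "L2", n_perm = 400, seed = 9)
  expect_equal(r$p, 1 / 401, tolerance = 1e-12)  # permutation floor

  ind <- make_ds(cbind(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE)),
                 cbind(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE)))
  r2 <- ld_permutation_test(ind, "L1", "L2", n_perm = 200, seed = 4)
  r3 <- ld_permutation_test(ind, "L1", "L2", n_perm = 200, seed = 4)
  expect_identical(r2$p, r3$p)
  expect_gte(r2$p, 1 / 201)
})

test_that("F_ST estimators hit the boundary cases and respond to divergence", {
  # identical genotype tables in both groups
  block1 <- c(1L, 1L, 2L, 1L, 2L); block2 <- c(1L, 2L, 2L, 1L, 1L)
  ds <- make_ds(cbind(rep(block1, 4)), cbind(rep(block2, 4)),
                pop = rep(c("X", "Y"), each = 10))
  expect_equal(fst_estimate(ds)$fst, 0, tolerance = 1e-12)

  # fixed alternative alleles
  fx <- make_ds(cbind(c(rep(1L, 10), rep(2L, 10))),
                cbind(c(rep(1L, 10), rep(2L, 10))),
                pop = rep(c("X", "Y"), each = 10))
  expect_equal(fst_estimate(fx)$fst, 1, tolerance = 1e-12)
  wc <- fst_estimate(fx, estimator = "weir-cockerham")
  expect_gt(wc$fst, 0.9)

  # monotone sweep: X stays at 50/50, Y moves away from it
  prev <- -Inf
  for (k in c(0, 3, 6, 9)) {
    a1 <- c(rep(c(1L, 2L), each = 10),        # X: 50/50
            rep(1L, 10 - k), rep(2L, 10 + k)) # Y: shifted
    ds2 <- make_ds(cbind(a1), cbind(a1), pop = rep(c("X", "Y"), each = 20))
    f <- fst_estimate(ds2)$fst
    expect_gte(f, prev - 1e-12)
    prev <- f
  }
})

test_that("Bonferroni locus filter drops flagged loci with reasons", {
  hwe <- data.frame(locus = rep(sprintf("L%d", 1:25), each = 2),
                    population = rep(c("X", "Y"), 25),
                    p = 1, chisq = 0, df = 1)
  hwe$p[hwe$locus == "L3" & hwe$population == "X"] <- 1e-8
  hwe$p[hwe$locus == "L12"] <- 1e-8
  ds <- make_ds(matrix(1L, 4, 25), matrix(2L, 4, 25),
                loci = sprintf("L%d", 1:25))
  kept <- locus_qc_filter(ds, hwe, alpha = 0.05)
  expect_equal(length(kept), 23L)
  expect_setequal(names(attr(kept, "dropped")), c("L3", "L12"))
  expect_match(attr(kept, "dropped")[["L12"]], "X & Y")

  none <- locus_qc_filter(ds, transform(hwe, p = 1), alpha = 0.05)
  expect_equal(length(none), 25L)
  all_kept <- locus_qc_filter(ds, hwe, alpha = 0)
  expect_equal(length(all_kept), 25L)
})

test_that("observed heterozygosity converges to He under HWE sampling", {
  cfg <- scenario_config("paper_like", seed = 60)
  cfg$populations$A$n_individuals <- 500L
  cfg$msat$n_loci <- 120L
  cfg$msat$missing_rate <- 0
  ds <- simulate_msat(cfg, "A", seed = 61)
  bias <- vapply(ds$loci, function(l) {
    d <- locus_diversity(ds, l)
    d$Ho - d$He
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.01)
})
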