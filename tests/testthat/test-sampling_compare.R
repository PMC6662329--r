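toy_metadata <- function(n, pop = "SB", calves = 0.05, juv = 0.25,
                         male = 0.55, unknown = 0) {
  age <- sample(c("calf", "juvenile", "adult"), n, replace = TRUE,
                prob = c(calves, juv, 1 - calves - juv))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(male, 1 - male))
  if (unknown > 0) {
    age[runif(n) < unknown] <- "unknown"
    sex[runif(n) < unknown] <- "unknown"
  }
  individual_metadata(data.frame(id = sprintf("%s%03d", pop, seq_len(n)),
                                 population = pop, sex = sex, age_class = age,
                                 stringsAsFactors = FALSE))
}

test_that("conservative draws match the reference composition exactly and are disjoint", {
  withr::local_seed(10)
  md <- toy_metadata(250)
  ref <- list(age_class = c(calf = 2, juvenile = 15, adult = 38),
              sex = c(male = 32, female = 23))
  draws <- conservative_match(md, ref, n_draws = 3, seed = 77)
  expect_length(draws, 3)
  for (d in draws) {
    expect_length(d, 55)
    sub <- md[md$id %in% d, ]
    comp <- composition_of(sub)
    expect_equal(comp$age_class[names(ref$age_class)], ref$age_class)
    expect_equal(comp$sex[names(ref$sex)], ref$sex)
  }
  expect_length(unique(unlist(draws)), 165)  # pairwise disjoint

  # reproducibility under the same seed
  draws2 <- conservative_match(md, ref, n_draws = 3, seed = 77)
  expect_identical(draws, draws2)

  # unknowns are never drawn
  md_u <- toy_metadata(300, unknown = 0.2)
  dr <- conservative_match(md_u, list(age_class = c(adult = 5),
                                      sex = c(male = 3, female = 2)),
                           n_draws = 2, seed = 1)
  picked <- md_u[md_u$id %in% unlist(dr), ]
  expect_false(any(picked$age_class == "unknown"))
  expect_false(any(picked$sex == "unknown"))
})

test_that("conservative matching raises capacity errors naming the deficit", {
  md <- individual_metadata(data.frame(
    id = sprintf("i%d", 1:6), population = "SB",
    sex = rep("female", 6), age_class = rep("adult", 6),
    stringsAsFactors = FALSE))
  ref <- list(age_class = c(adult = 1), sex = c(female = 1))
  draws <- conservative_match(md, ref, n_draws = 3, seed = 2)
  expect_length(draws, 3)
  expect_error(conservative_match(md, ref, n_draws = 7, seed = 2),
               "capacity error")
  ref2 <- list(age_class = c(calf = 1), sex = c(female = 1))
  expect_error(conservative_match(md, ref2, n_draws = 1, seed = 2),
               "calf")
})

test_that("disjoint partition yields floor(n/size) sets and logs leftovers", {
  ids55 <- sprintf("b%d", 1:55)
  sets <- disjoint_partition(ids55, 11, seed = 3)
  expect_length(sets, 5)
  expect_length(attr(sets, "leftover"), 0)
  expect_length(unique(unlist(sets)), 55)

  ids239 <- sprintf("s%d", 1:239)
  sets2 <- disjoint_partition(ids239, 11, seed = 3)
  expect_length(sets2, 21)
  expect_length(attr(sets2, "leftover"), 8)

  sets19 <- disjoint_partition(ids239, 11, n_subsamples = 19, seed = 3)
  expect_length(sets19, 19)
  expect_error(disjoint_partition(sprintf("x%d", 1:10), 11), "insufficient")
  expect_error(disjoint_partition(ids55, 11, n_subsamples = 6), "at most")
})

test_that("t tests handle the documented degenerate contracts", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$df, 4)

  shift <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.001)
  expect_equal(shift$df, 4)

  flat <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p, 1)
  apart <- two_sample_t(c(2, 2), c(3, 3))
  expect_true(is.infinite(apart$t)); expect_equal(apart$p, 0)

  # 19 vs 5 groups: pooled df = 22
  expect_equal(two_sample_t(rnorm(19), rnorm(5))$df, 22)

  pt <- paired_t_over_loci(rep(1, 23), rep(1, 23))
  expect_equal(pt$t, 0); expect_equal(pt$p, 1); expect_equal(pt$df, 22)
  pt2 <- paired_t_over_loci(c(1, 2, 3), c(0, 1, 2))
  expect_true(pt2$degenerate); expect_equal(pt2$p, 0)
  pt3 <- paired_t_over_loci(rnorm(23), rnorm(23))
  expect_equal(pt3$df, 22)
})

test_that("sex-ratio chi-square matches closed forms", {
  expect_equal(sex_ratio_chisq(50, 50)$chisq, 0)
  expect_equal(sex_ratio_chisq(60, 40)$chisq, 4, tolerance = 1e-12)
  hom <- sex_ratio_chisq(30, 20, reference_counts = c(30, 20))
  expect_equal(hom$chisq, 0, tolerance = 1e-12)
  expect_error(sex_ratio_chisq(0, 0), "no observed")
})

test_that("compare_populations composes the tiers into a full report", {
  cfg <- scenario_config("paper_like", seed = 12)
  cfg$populations$A$n_individuals <- 120L
  sc <- simulate_scenario(cfg)
  plan <- sampling_plan(n_conservative_draws = 1, subsample_size = 11,
                        seed = 12)
  rep_ <- compare_populations(sc$alignment, sc$msat, sc$metadata,
                              partition = sc$partition, plan = plan,
                              n_bootstrap = 150)
  expect_s3_class(rep_, "comparison_report")
  expect_setequal(unique(rep_$mhc_diversity$sampling),
                  c("maximum", "conservative", "subsampling"))
  expect_true(all(c("n", "pi", "pi_sd", "Hd", "Hd_sd", "theta_w",
                    "theta_w_sd", "theta_eta", "eta") %in%
                    names(rep_$mhc_diversity)))
  expect_equal(nrow(rep_$t_tests), 8)
  expect_equal(nrow(rep_$selection), 6)
  expect_equal(nrow(rep_$tajima), 4)
  expect_equal(sort(unique(rep_$selection$site_class)),
               c("all", "nonpbr", "pbr"))
  # subsampling t df: n_subsamples_A + n_subsamples_B - 2
  n_sub <- (120L %/% 11L) + (55L %/% 11L)
  expect_equal(rep_$t_tests$df[rep_$t_tests$measure == "pi"], n_sub - 2)
  # paired-t df: retained loci - 1
  expect_equal(rep_$t_tests$df[rep_$t_tests$measure == "Ho"],
               length(rep_$retained_loci) - 1)
})
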