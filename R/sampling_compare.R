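# Three-tier sampling design (maximum / conservative demographic matching /
# disjoint subsampling) and the inter-population statistical comparisons.

#' Demographic composition of a metadata table
#'
#' @param metadata an [individual_metadata()] table (or subset).
#' @return list with named count vectors `age_class` and `sex` (unknowns
#'   excluded).
#' @export
composition_of <- function(metadata) {
  age <- table(metadata$age_class[metadata$age_class != "unknown"])
  sex <- table(metadata$sex[metadata$sex != "unknown"])
  list(age_class = stats::setNames(as.integer(age), names(age)),
       sex = stats::setNames(as.integer(sex), names(sex)))
}

#' Draw demographically matched, disjoint conservative subsamples
#'
#' Draws `n_draws` mutually disjoint sets of individuals from `metadata`
#' (optionally restricted to one population), each exactly matching the
#' reference composition in both the age-class and the sex marginal
#' (e.g. 2 calves, 15 juveniles, 38 adults of which 32 males and 23
#' females). Individuals of unknown age class or sex are excluded.
#' Selection within the constraints is uniform, implemented by randomized
#' greedy fill with restarts.
#'
#' @param metadata an [individual_metadata()] table.
#' @param reference_composition list with named integer vectors `age_class`
#'   and `sex` (as returned by [composition_of()]); the two must sum to the
#'   same total.
#' @param n_draws number of disjoint sets.
#' @param seed integer seed (recorded as an attribute).
#' @param population restrict the source pool to this population label.
#' @param max_restarts greedy restarts per draw before giving up.
#' @return list of character vectors of individual ids, with attribute
#'   `seed`.
#' @export
conservative_match <- function(metadata, reference_composition, n_draws = 3L,
                               seed = NULL, population = NULL,
                               max_restarts = 500L) {
  ref_age <- reference_composition$age_class
  ref_sex <- reference_composition$sex
  if (sum(ref_age) != sum(ref_sex)) {
    stop("reference composition marginals disagree in total", call. = FALSE)
  }
  pool <- metadata
  if (!is.null(population)) pool <- pool[pool$population == population, , drop = FALSE]
  pool <- pool[pool$age_class != "unknown" & pool$sex != "unknown", , drop = FALSE]
  # capacity check per category across all draws
  for (cat_name in names(ref_age)) {
    have <- sum(pool$age_class == cat_name)
    if (have < n_draws * ref_age[[cat_name]]) {
      stop(sprintf("capacity error: need %d x %d individuals of age class '%s', have %d",
                   n_draws, ref_age[[cat_name]], cat_name, have), call. = FALSE)
    }
  }
  for (cat_name in names(ref_sex)) {
    have <- sum(pool$sex == cat_name)
    if (have < n_draws * ref_sex[[cat_name]]) {
      stop(sprintf("capacity error: need %d x %d individuals of sex '%s', have %d",
                   n_draws, ref_sex[[cat_name]], cat_name, have), call. = FALSE)
    }
  }
  with_seed(seed, {
    draws <- vector("list", n_draws)
    available <- pool
    for (d in seq_len(n_draws)) {
      picked <- NULL
      for (try in seq_len(max_restarts)) {
        need_age <- ref_age; need_sex <- ref_sex
        order_idx <- sample.int(nrow(available))
        sel <- integer(0)
        for (i in order_idx) {
          a <- available$age_class[i]; s <- available$sex[i]
          if (!is.na(need_age[a]) && need_age[a] > 0L &&
              !is.na(need_sex[s]) && need_sex[s] > 0L) {
            sel <- c(sel, i)
            need_age[a] <- need_age[a] - 1L
            need_sex[s] <- need_sex[s] - 1L
            if (all(need_age == 0L) && all(need_sex == 0L)) break
          }
        }
        if (all(need_age == 0L) && all(need_sex == 0L)) { picked <- sel; break }
      }
      if (is.null(picked)) {
        stop("capacity error: could not satisfy the joint age x sex composition",
             call. = FALSE)
      }
      draws[[d]] <- available$id[picked]
      available <- available[-picked, , drop = FALSE]
    }
    structure(draws, seed = seed)
  })
}

#' Partition ids into disjoint fixed-size subsamples
#'
#' Randomly partitions `ids` into `floor(length(ids)/subsample_size)` (or a
#' smaller requested number of) disjoint subsamples of exactly
#' `subsample_size`; leftover individuals are unused and reported.
#'
#' @param ids character vector of individual ids.
#' @param subsample_size size of each subsample.
#' @param n_subsamples number of subsamples; default `floor(n/size)`, may
#'   be set lower (e.g. to reproduce a published design).
#' @param seed integer seed.
#' @return list of character vectors, with attributes `leftover` and `seed`.
#' @export
disjoint_partition <- function(ids, subsample_size = 11L, n_subsamples = NULL,
                               seed = NULL) {
  n <- length(ids)
  if (n < subsample_size) {
    stop(sprintf("insufficient: %d ids for subsample size %d", n,
                 subsample_size), call. = FALSE)
  }
  max_sets <- n %/% subsample_size
  n_subsamples <- n_subsamples %||% max_sets
  if (n_subsamples > max_sets) {
    stop(sprintf("insufficient: %d ids allow at most %d disjoint subsamples of %d",
                 n, max_sets, subsample_size), call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(ids)
    sets <- lapply(seq_len(n_subsamples), function(k) {
      shuffled[((k - 1L) * subsample_size + 1L):(k * subsample_size)]
    })
    structure(sets,
              leftover = shuffled[-seq_len(n_subsamples * subsample_size)],
              seed = seed)
  })
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance t with `df = n_a + n_b - 2` (Welch by
#' `var_equal = FALSE`); two groups with zero pooled variance and equal
#' means give `t = 0, p = 1`, and equal-variance-zero groups with unequal
#' means give `|t| = Inf, p = 0` (flagged).
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param var_equal pool the variance (default TRUE).
#' @return list with `t`, `df`, `p` and `degenerate`.
#' @export
two_sample_t <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    df <- length(values_a) + length(values_b) - 2L
    if (mean(values_a) == mean(values_b)) {
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, df = df,
                p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Paired t-test across loci
#'
#' Paired t on per-locus differences with `df = n_loci - 1`. All-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference has zero
#' variance and is reported at the numerical floor (`p = 0`, flagged).
#'
#' @param values_a_by_locus,values_b_by_locus numeric vectors over the same
#'   locus set (length >= 2).
#' @return list with `t`, `df`, `p` and `degenerate`.
#' @export
paired_t_over_loci <- function(values_a_by_locus, values_b_by_locus) {
  if (length(values_a_by_locus) != length(values_b_by_locus)) {
    stop("locus sets differ in length", call. = FALSE)
  }
  if (length(values_a_by_locus) < 2L) stop("need >= 2 loci", call. = FALSE)
  d <- values_a_by_locus - values_b_by_locus
  df <- length(d) - 1L
  if (stats::var(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(d[1]) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a_by_locus, values_b_by_locus, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Sex-ratio chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed male/female counts
#' against an expected ratio (default 50:50), or, when `reference_counts`
#' is supplied, a 2x2 homogeneity chi-square of observed versus reference
#' counts (no continuity correction).
#'
#' @param observed_m,observed_f observed counts.
#' @param expected_ratio length-2 numeric ratio male:female.
#' @param reference_counts optional length-2 vector of reference
#'   male/female counts for a homogeneity test.
#' @return list with `chisq`, `df`, `p`.
#' @export
sex_ratio_chisq <- function(observed_m, observed_f, expected_ratio = c(1, 1),
                            reference_counts = NULL) {
  n <- observed_m + observed_f
  if (n <= 0) stop("no observed individuals", call. = FALSE)
  if (is.null(reference_counts)) {
    e <- n * expected_ratio / sum(expected_ratio)
    if (any(e == 0)) {
      return(list(chisq = NA_real_, df = 1L, p = NA_real_))
    }
    chisq <- sum((c(observed_m, observed_f) - e)^2 / e)
    return(list(chisq = chisq, df = 1L,
                p = stats::pchisq(chisq, 1L, lower.tail = FALSE)))
  }
  tab <- rbind(c(observed_m, observed_f), reference_counts)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e == 0)) return(list(chisq = NA_real_, df = 1L, p = NA_real_))
  chisq <- sum((tab - e)^2 / e)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

#' Define a sampling plan
#'
#' @param n_conservative_draws disjoint demographically matched draws from
#'   the larger population.
#' @param subsample_size individuals per subsampling-tier subsample.
#' @param n_subsamples named list/vector giving the number of subsamples
#'   per population (`NULL` entries mean `floor(n/size)`).
#' @param seed master seed for all random choices.
#' @return list of class `sampling_plan`.
#' @export
sampling_plan <- function(n_conservative_draws = 3L, subsample_size = 11L,
                          n_subsamples = NULL, seed = 1L) {
  structure(list(n_conservative_draws = as.integer(n_conservative_draws),
                 subsample_size = as.integer(subsample_size),
                 n_subsamples = n_subsamples, seed = as.integer(seed)),
            class = "sampling_plan")
}

.summaries_over_sets <- function(aln, sets) {
  lapply(sets, function(ids) diversity_summary(subset_alignment(aln, ids)))
}

.msat_locus_table <- function(ds, individuals, loci, population_label) {
  sub <- subset_msat(ds, individuals = individuals, loci = loci)
  rows <- lapply(loci, function(l) locus_diversity(sub, l))
  tab <- do.call(rbind, rows)
  tab$population <- population_label
  tab
}

#' Full two-population comparison across the three sampling tiers
#'
#' Runs the maximum, conservative and subsampling tiers for both marker
#' systems and composes the selection and neutrality tests, mirroring the
#' table structure of a two-population MHC/microsatellite comparison:
#' per-sample sequence-diversity rows, per-population microsatellite
#' means, Nei-Gojobori selection tests by site class, Tajima's D by site
#' filter, and the subsampling-tier t-tests (sequence measures) plus
#' conservative-tier paired t-tests across loci (microsatellite measures).
#'
#' The smaller population defines the reference demographic composition;
#' the larger population is conservatively matched to it. The
#' subsampling tier partitions each population's conservative-eligible
#' pool (individuals with both marker types) into disjoint subsamples.
#'
#' @param alignment a [phased_alignment()] covering both populations.
#' @param msat an [msat_dataset()] covering both populations.
#' @param metadata an [individual_metadata()] table.
#' @param partition optional [codon_partition()]; when supplied the
#'   selection z-tests, the PBR tally and Tajima's D are included.
#' @param plan a [sampling_plan()].
#' @param hwe_filter drop loci failing the Bonferroni HWE screen first.
#' @param n_bootstrap bootstrap replicates for the selection z-test.
#' @return an object of class `comparison_report` (a list of data.frames:
#'   `mhc_diversity`, `msat_diversity`, `selection`, `tajima`, `t_tests`,
#'   `sex_ratio`, plus `plan`, `retained_loci`, `seed`).
#' @export
compare_populations <- function(alignment, msat, metadata, partition = NULL,
                                plan = sampling_plan(), hwe_filter = TRUE,
                                n_bootstrap = 1000L) {
  pops <- sort(unique(metadata$population))
  if (length(pops) != 2L) stop("need exactly 2 populations", call. = FALSE)
  seed <- plan$seed

  # conservative-eligible pool: individuals with both marker types
  with_mhc <- unique(alignment$individual_id)
  with_msat <- msat$individuals
  eligible <- lapply(pops, function(p) {
    ids <- metadata$id[metadata$population == p]
    intersect(intersect(ids, with_mhc), with_msat)
  })
  names(eligible) <- pops
  n_elig <- vapply(eligible, length, integer(1))
  small <- pops[which.min(n_elig)]; large <- pops[which.max(n_elig)]
  if (small == large) large <- setdiff(pops, small)

  # HWE screen / locus filter
  hwe <- hwe_screen(msat)
  loci <- if (hwe_filter) locus_qc_filter(msat, hwe) else msat$loci

  # --- maximum tier -------------------------------------------------------
  mhc_rows <- list(); msat_rows <- list()
  aln_by_pop <- lapply(pops, function(p) {
    keep <- alignment$population == p
    phased_alignment(alignment$sequences[keep], alignment$individual_id[keep],
                     alignment$haplotype_index[keep], alignment$population[keep],
                     alignment$frame_offset)
  })
  names(aln_by_pop) <- pops
  for (p in pops) {
    ds <- as.data.frame(diversity_summary(aln_by_pop[[p]]))
    ds$population <- p; ds$sampling <- "maximum"; ds$sample <- "max"
    mhc_rows[[paste(p, "max")]] <- ds
    ids_msat <- msat$individuals[msat$population == p]
    msat_rows[[paste(p, "max")]] <-
      .msat_summary_row(msat, ids_msat, loci, p, "maximum")
  }

  # --- conservative tier --------------------------------------------------
  ref_meta <- metadata[metadata$id %in% eligible[[small]], , drop = FALSE]
  ref_comp <- composition_of(ref_meta)
  cons_sets <- list()
  cons_sets[[small]] <- list(eligible[[small]])
  cons_sets[[large]] <- conservative_match(
    metadata[metadata$id %in% eligible[[large]], , drop = FALSE],
    ref_comp, n_draws = plan$n_conservative_draws,
    seed = derive_seed(seed, 1L))
  for (p in pops) {
    for (k in seq_along(cons_sets[[p]])) {
      ids <- cons_sets[[p]][[k]]
      ds <- as.data.frame(diversity_summary(subset_alignment(alignment, ids)))
      ds$population <- p; ds$sampling <- "conservative"
      ds$sample <- if (length(cons_sets[[p]]) == 1L) "cons" else paste0("cons", k)
      mhc_rows[[paste(p, "cons", k)]] <- ds
      msat_rows[[paste(p, "cons", k)]] <-
        .msat_summary_row(msat, ids, loci, p, "conservative",
                          sample = ds$sample[1L])
    }
  }

  # --- subsampling tier ---------------------------------------------------
  sub_sets <- list(); sub_summaries <- list()
  for (p in pops) {
    n_sub <- NULL
    if (!is.null(plan$n_subsamples) && !is.null(plan$n_subsamples[[p]])) {
      n_sub <- plan$n_subsamples[[p]]
    }
    sub_sets[[p]] <- disjoint_partition(eligible[[p]], plan$subsample_size,
                                        n_subsamples = n_sub,
                                        seed = derive_seed(seed, 2L + match(p, pops)))
    sub_summaries[[p]] <- .summaries_over_sets(alignment, sub_sets[[p]])
    vals <- do.call(rbind, lapply(sub_summaries[[p]], as.data.frame))
    row <- data.frame(t(colMeans(vals)))
    row$population <- p; row$sampling <- "subsampling"
    row$sample <- sprintf("mean(%dx%d)", length(sub_sets[[p]]), plan$subsample_size)
    mhc_rows[[paste(p, "sub")]] <- row
  }

  # --- t tests ------------------------------------------------------------
  t_rows <- list()
  for (measure in c("pi", "Hd", "theta_w", "theta_eta")) {
    va <- vapply(sub_summaries[[large]], function(s) s[[measure]], numeric(1))
    vb <- vapply(sub_summaries[[small]], function(s) s[[measure]], numeric(1))
    tt <- two_sample_t(va, vb)
    t_rows[[measure]] <- data.frame(marker = "MHC", measure = measure,
                                    test = "two-sample t (subsampling)",
                                    t = tt$t, df = tt$df, p = tt$p)
  }
  cons_large_ids <- cons_sets[[large]][[1L]]
  msat_small <- .msat_locus_table(msat, eligible[[small]], loci, small)
  msat_large <- .msat_locus_table(msat, cons_large_ids, loci, large)
  for (measure in c("Ho", "He", "Ae", "shannon")) {
    tt <- paired_t_over_loci(msat_large[[measure]], msat_small[[measure]])
    t_rows[[paste0("msat_", measure)]] <-
      data.frame(marker = "msat", measure = measure,
                 test = "paired t over loci (conservative)",
                 t = tt$t, df = tt$df, p = tt$p)
  }

  # --- selection / neutrality tests --------------------------------------
  sel_rows <- list(); taj_rows <- list(); tally <- NULL
  if (!is.null(partition)) {
    for (p in pops) {
      for (sc in c("pbr", "nonpbr", "all")) {
        st <- selection_z_test(aln_by_pop[[p]], partition, sc,
                               n_bootstrap = n_bootstrap,
                               seed = derive_seed(seed, 10L + match(p, pops)))
        sel_rows[[paste(p, sc)]] <-
          data.frame(population = p, site_class = sc, n_codons = st$n_codons,
                     dN = st$dN, dN_se = st$dN_se, dS = st$dS, dS_se = st$dS_se,
                     ratio = st$ratio, z = st$z, p_value = st$p)
      }
      for (sf in c("all", "nonsynonymous")) {
        td <- tajima_D(aln_by_pop[[p]], sf)
        taj_rows[[paste(p, sf)]] <-
          data.frame(population = p, site_filter = sf, n = td$n,
                     S_used = td$S_used, D = td$D, p_value = td$p,
                     significance = td$significance_class)
      }
    }
    tally <- pbr_variable_site_tally(alignment, partition)
  }

  # --- sex ratios ---------------------------------------------------------
  sex_rows <- lapply(pops, function(p) {
    md <- metadata[metadata$population == p, , drop = FALSE]
    m <- sum(md$sex == "male"); f <- sum(md$sex == "female")
    sr <- sex_ratio_chisq(m, f)
    data.frame(population = p, males = m, females = f,
               chisq = sr$chisq, p = sr$p)
  })

  structure(
    list(mhc_diversity = .rbind_fill(mhc_rows),
         msat_diversity = do.call(rbind, msat_rows),
         selection = if (length(sel_rows)) do.call(rbind, sel_rows) else NULL,
         tajima = if (length(taj_rows)) do.call(rbind, taj_rows) else NULL,
         t_tests = do.call(rbind, t_rows),
         sex_ratio = do.call(rbind, sex_rows),
         pbr_tally = tally,
         retained_loci = as.character(loci),
         hwe = hwe,
         plan = plan, seed = seed,
         populations = list(reference = small, matched = large)),
    class = "comparison_report")
}

.msat_summary_row <- function(ds, individuals, loci, population, sampling,
                              sample = sampling) {
  tab <- .msat_locus_table(ds, individuals, loci, population)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(population = population, sampling = sampling, sample = sample,
             n = length(individuals), n_loci = length(loci),
             Ho = mean(tab$Ho), Ho_se = se(tab$Ho),
             He = mean(tab$He), He_se = se(tab$He),
             Na = mean(tab$Na),
             Ae = mean(tab$Ae), Ae_se = se(tab$Ae),
             shannon = mean(tab$shannon), shannon_se = se(tab$shannon))
}

.rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  }))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Two-population diversity comparison\n")
  cat("reference (smaller) population:", x$populations$reference,
      "| matched:", x$populations$matched, "\n")
  cat("retained loci:", length(x$retained_loci), "\n\n")
  cat("Sequence diversity (by sampling tier):\n")
  print(x$mhc_diversity[, c("population", "sampling", "sample", "n", "pi",
                            "Hd", "theta_w", "theta_eta", "eta")],
        row.names = FALSE, digits = 4)
  cat("\nt tests:\n")
  print(x$t_tests, row.names = FALSE, digits = 4)
  invisible(x)
}
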