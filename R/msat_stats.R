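# Per-locus microsatellite diversity, Hardy-Weinberg and linkage
# screening, Bonferroni locus filtering and F_ST.

.pop_rows <- function(ds, population = NULL) {
  if (is.null(population)) seq_along(ds$individuals)
  else which(ds$population %in% population)
}

#' Allele frequencies of one locus
#'
#' Frequencies over the 2 x n_typed allele copies of the selected
#' population (missing genotypes excluded).
#'
#' @param ds an [msat_dataset()].
#' @param locus locus name.
#' @param population population label(s); `NULL` pools everything.
#' @return named numeric vector summing to 1, names are allele labels.
#' @export
allele_frequencies <- function(ds, locus, population = NULL) {
  ci <- match(locus, ds$loci)
  if (is.na(ci)) stop("unknown locus: ", locus, call. = FALSE)
  rows <- .pop_rows(ds, population)
  a <- c(ds$allele1[rows, ci], ds$allele2[rows, ci])
  a <- a[!is.na(a)]
  if (length(a) == 0L) {
    stop("empty locus: no typed individuals for ", locus, call. = FALSE)
  }
  tab <- table(a)
  stats::setNames(as.numeric(tab) / length(a), names(tab))
}

#' Per-locus diversity summary
#'
#' Observed heterozygosity `Ho` (fraction of typed individuals carrying two
#' different alleles), expected heterozygosity `He = 1 - sum(p^2)` (the
#' uncorrected form; `unbiased = TRUE` applies the 2n/(2n-1) correction),
#' effective allele number `Ae = 1/sum(p^2)` and Shannon index
#' `-sum(p log p)`.
#'
#' @inheritParams allele_frequencies
#' @param unbiased apply the small-sample correction to He.
#' @return one-row data.frame with `locus`, `population`, `n_typed`, `Na`,
#'   `Ae`, `Ho`, `He`, `shannon`.
#' @export
locus_diversity <- function(ds, locus, population = NULL, unbiased = FALSE) {
  ci <- match(locus, ds$loci)
  if (is.na(ci)) stop("unknown locus: ", locus, call. = FALSE)
  rows <- .pop_rows(ds, population)
  a1 <- ds$allele1[rows, ci]; a2 <- ds$allele2[rows, ci]
  typed <- !is.na(a1)
  n_typed <- sum(typed)
  if (n_typed < 2L) stop("need >= 2 typed individuals at ", locus, call. = FALSE)
  p <- allele_frequencies(ds, locus, population)
  s2 <- sum(p^2)
  he <- 1 - s2
  if (unbiased) he <- he * (2 * n_typed) / (2 * n_typed - 1)
  data.frame(locus = locus,
             population = if (is.null(population)) "all" else paste(population, collapse = "+"),
             n_typed = n_typed, Na = length(p), Ae = 1 / s2,
             Ho = mean(a1[typed] != a2[typed]), He = he,
             shannon = -sum(p * log(p)), stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium test for one locus
#'
#' Chi-square goodness-of-fit of observed genotype counts against HWE
#' expectations over all k(k+1)/2 genotype classes with df = k(k-1)/2
#' (`method = "chisq"`), or a seeded Monte-Carlo test that reshuffles the
#' 2n allele copies into genotypes and compares the chi-square statistic
#' (`method = "mc"`), which is robust to sparse genotype classes.
#'
#' @inheritParams allele_frequencies
#' @param method `"chisq"` or `"mc"`.
#' @param n_mc Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo method.
#' @return list with `p`, `chisq`, `df`, `method`, `low_power` (fewer than
#'   5 typed individuals) and `applicable` (`FALSE` for monomorphic loci,
#'   with `p = NA`).
#' @export
hwe_test <- function(ds, locus, population = NULL,
                     method = c("chisq", "mc"), n_mc = 2000L, seed = NULL) {
  method <- match.arg(method)
  ci <- match(locus, ds$loci)
  if (is.na(ci)) stop("unknown locus: ", locus, call. = FALSE)
  rows <- .pop_rows(ds, population)
  a1 <- ds$allele1[rows, ci]; a2 <- ds$allele2[rows, ci]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) {
    return(list(p = NA_real_, chisq = NA_real_, df = NA_integer_,
                method = method, low_power = n < 5L, applicable = FALSE))
  }
  stat <- .hwe_chisq_stat(a1, a2, alleles, n)
  df <- k * (k - 1L) / 2L
  p <- if (method == "chisq") {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    pool <- c(a1, a2)
    with_seed(seed, {
      hits <- 0L
      for (r in seq_len(n_mc)) {
        perm <- sample(pool)
        s <- .hwe_chisq_stat(perm[seq_len(n)], perm[n + seq_len(n)], alleles, n)
        if (s >= stat - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_mc)
    })
  }
  list(p = p, chisq = stat, df = df, method = method,
       low_power = n < 5L, applicable = TRUE)
}

.hwe_chisq_stat <- function(a1, a2, alleles, n) {
  k <- length(alleles)
  i1 <- match(pmin(a1, a2), alleles); i2 <- match(pmax(a1, a2), alleles)
  obs <- matrix(0, k, k)
  for (g in seq_along(i1)) obs[i1[g], i2[g]] <- obs[i1[g], i2[g]] + 1
  cnt <- tabulate(c(i1, i2), nbins = k)
  p <- cnt / (2 * n)
  stat <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      if (e > 0) stat <- stat + (obs[i, j] - e)^2 / e
    }
  }
  stat
}

#' All-locus, all-population HWE screen
#'
#' @inheritParams hwe_test
#' @return data.frame with one row per locus x population: `locus`,
#'   `population`, `p`, `chisq`, `df`.
#' @export
hwe_screen <- function(ds, method = "chisq", n_mc = 2000L, seed = NULL) {
  pops <- unique(ds$population)
  grid <- expand.grid(locus = ds$loci, population = pops,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    h <- hwe_test(ds, grid$locus[i], grid$population[i], method = method,
                  n_mc = n_mc,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    data.frame(locus = grid$locus[i], population = grid$population[i],
               p = h$p, chisq = h$chisq, df = h$df, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Genotypic linkage-disequilibrium permutation G-test
#'
#' Log-likelihood-ratio G statistic of the genotype x genotype contingency
#' table of two loci, with the null distribution obtained by permuting one
#' locus's genotypes across individuals. The p-value honours the
#' `(1 + hits) / (1 + n_perm)` permutation floor.
#'
#' @inheritParams allele_frequencies
#' @param locus_a,locus_b locus names.
#' @param n_perm number of permutations.
#' @param seed integer seed (the test is reproducible under a fixed seed).
#' @return list with `p`, `G`, `n_perm`, `applicable`.
#' @export
ld_permutation_test <- function(ds, locus_a, locus_b, population = NULL,
                                n_perm = 10000L, seed = NULL) {
  ca <- match(locus_a, ds$loci); cb <- match(locus_b, ds$loci)
  if (is.na(ca) || is.na(cb)) stop("unknown locus", call. = FALSE)
  rows <- .pop_rows(ds, population)
  ga <- sprintf("%s/%s", ds$allele1[rows, ca], ds$allele2[rows, ca])
  gb <- sprintf("%s/%s", ds$allele1[rows, cb], ds$allele2[rows, cb])
  ok <- !is.na(ds$allele1[rows, ca]) & !is.na(ds$allele1[rows, cb])
  ga <- ga[ok]; gb <- gb[ok]
  if (length(ga) < 2L || length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    return(list(p = NA_real_, G = NA_real_, n_perm = n_perm, applicable = FALSE))
  }
  g_obs <- .g_statistic(ga, gb)
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      if (.g_statistic(ga, sample(gb)) >= g_obs - 1e-12) hits <- hits + 1L
    }
    list(p = (1 + hits) / (1 + n_perm), G = g_obs, n_perm = n_perm,
         applicable = TRUE)
  })
}

.g_statistic <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Multilocus F_ST between populations
#'
#' Default estimator: per locus `(Ht - mean(Hs)) / Ht`, with `Ht` the
#' expected heterozygosity of the pooled allele frequencies and `Hs` the
#' within-group expected heterozygosities, averaged over loci
#' (`estimator = "ht-hs"`). `estimator = "weir-cockerham"` gives the
#' variance-components theta of Weir and Cockerham (1984), combined across
#' loci as sum(a) / sum(a + b + c). Loci monomorphic over all groups are
#' skipped and reported.
#'
#' @param ds an [msat_dataset()].
#' @param grouping named character vector mapping individual id to group;
#'   defaults to the dataset's population labels.
#' @param estimator `"ht-hs"` or `"weir-cockerham"`.
#' @param loci loci to use (default all).
#' @return an object of class `fst_result`: list with `per_locus`
#'   (data.frame `locus`, `fst`), `fst` (multilocus), `estimator`,
#'   `skipped` (monomorphic loci).
#' @export
fst_estimate <- function(ds, grouping = NULL,
                         estimator = c("ht-hs", "weir-cockerham"),
                         loci = NULL) {
  estimator <- match.arg(estimator)
  groups <- if (is.null(grouping)) {
    ds$population
  } else {
    unname(grouping[ds$individuals])
  }
  if (anyNA(groups)) stop("grouping does not cover all individuals", call. = FALSE)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  loci <- loci %||% ds$loci
  per_locus <- numeric(0); kept <- character(0); skipped <- character(0)
  num <- 0; den <- 0  # Weir-Cockerham accumulators
  for (locus in loci) {
    ci <- match(locus, ds$loci)
    a1 <- ds$allele1[, ci]; a2 <- ds$allele2[, ci]
    typed <- !is.na(a1)
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    if (length(alleles) < 2L) { skipped <- c(skipped, locus); next }
    if (estimator == "ht-hs") {
      gl <- split(seq_along(groups)[typed], groups[typed])
      gl <- gl[vapply(gl, length, integer(1)) > 0L]
      hs <- vapply(gl, function(rows) {
        p <- table(factor(c(a1[rows], a2[rows]), levels = alleles))
        p <- as.numeric(p) / sum(p)
        1 - sum(p^2)
      }, numeric(1))
      pt <- table(factor(c(a1[typed], a2[typed]), levels = alleles))
      pt <- as.numeric(pt) / sum(pt)
      ht <- 1 - sum(pt^2)
      if (ht <= 0) { skipped <- c(skipped, locus); next }
      per_locus <- c(per_locus, (ht - mean(hs)) / ht)
      kept <- c(kept, locus)
    } else {
      wc <- .wc_components(a1, a2, groups, alleles)
      per_locus <- c(per_locus,
                     if (wc$den > 0) wc$num / wc$den else NA_real_)
      kept <- c(kept, locus)
      num <- num + wc$num; den <- den + wc$den
    }
  }
  if (length(kept) == 0L) stop("all loci monomorphic across groups", call. = FALSE)
  fst <- if (estimator == "ht-hs") mean(per_locus) else num / den
  structure(list(per_locus = data.frame(locus = kept, fst = per_locus,
                                        stringsAsFactors = FALSE),
                 fst = fst, estimator = estimator, skipped = skipped),
            class = "fst_result")
}

# Weir & Cockerham (1984) variance components for one locus, summed over
# alleles; num = a, den = a + b + c
.wc_components <- function(a1, a2, groups, alleles) {
  typed <- !is.na(a1)
  groups <- groups[typed]; a1 <- a1[typed]; a2 <- a2[typed]
  gl <- split(seq_along(groups), groups)
  gl <- gl[vapply(gl, length, integer(1)) > 0L]
  r <- length(gl)
  n_i <- vapply(gl, length, integer(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (al in alleles) {
    p_i <- vapply(gl, function(rows) {
      (sum(a1[rows] == al) + sum(a2[rows] == al)) / (2 * length(rows))
    }, numeric(1))
    h_i <- vapply(gl, function(rows) {
      mean((a1[rows] == al) != (a2[rows] == al))
    }, numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  list(num = num, den = den)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST (%s) over %d loci: %.4f\n", x$estimator,
              nrow(x$per_locus), x$fst))
  if (length(x$skipped) > 0L) {
    cat("skipped monomorphic loci:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bonferroni locus filter from an HWE screen
#'
#' Drops every locus flagged in any population at the Bonferroni-corrected
#' level `alpha / (n_loci x n_populations)`, mirroring the common practice
#' of removing out-of-equilibrium loci before diversity comparisons.
#'
#' @param ds an [msat_dataset()].
#' @param hwe_results data.frame from [hwe_screen()].
#' @param alpha family-wise error rate before correction.
#' @return character vector of retained loci, with attributes `dropped`
#'   (named character vector of reasons) and `threshold`.
#' @export
locus_qc_filter <- function(ds, hwe_results, alpha = 0.05) {
  n_tests <- length(unique(hwe_results$locus)) *
    length(unique(hwe_results$population))
  threshold <- alpha / n_tests
  flagged <- hwe_results[!is.na(hwe_results$p) & hwe_results$p < threshold, ,
                         drop = FALSE]
  drop_loci <- unique(flagged$locus)
  reasons <- vapply(drop_loci, function(l) {
    pops <- flagged$population[flagged$locus == l]
    sprintf("HWE departure after Bonferroni in %s", paste(pops, collapse = " & "))
  }, character(1))
  retained <- setdiff(ds$loci, drop_loci)
  structure(retained, dropped = stats::setNames(reasons, drop_loci),
            threshold = threshold)
}

#' Simple data-quality warnings for a microsatellite dataset
#'
#' A lightweight stand-in for dedicated scoring-error software: reports
#' loci with a high missing rate or a strong global heterozygote deficit
#' (He - Ho large), which can indicate null alleles or scoring problems.
#'
#' @param ds an [msat_dataset()].
#' @param missing_warn missing-rate threshold.
#' @param het_deficit_warn He - Ho threshold.
#' @return data.frame of warnings (possibly 0 rows): `locus`, `issue`,
#'   `value`.
#' @export
msat_qc_warnings <- function(ds, missing_warn = 0.1, het_deficit_warn = 0.15) {
  out <- list()
  for (locus in ds$loci) {
    ci <- match(locus, ds$loci)
    miss <- mean(is.na(ds$allele1[, ci]))
    if (miss > missing_warn) {
      out[[length(out) + 1L]] <- data.frame(locus = locus,
                                            issue = "high_missing_rate",
                                            value = miss)
    }
    typed <- !is.na(ds$allele1[, ci])
    if (sum(typed) >= 2L &&
        length(unique(c(ds$allele1[typed, ci], ds$allele2[typed, ci]))) >= 2L) {
      d <- locus_diversity(ds, locus)
      if (d$He - d$Ho > het_deficit_warn) {
        out[[length(out) + 1L]] <- data.frame(locus = locus,
                                              issue = "heterozygote_deficit",
                                              value = d$He - d$Ho)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(locus = character(0), issue = character(0), value = numeric(0))
  } else {
    do.call(rbind, out)
  }
}
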