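# Nei-Gojobori codon-based synonymous/nonsynonymous analysis with
# peptide-binding-region partitioning and a bootstrap z-test for positive
# selection, plus the PBR variable-site tally.
#
# Conventions (the classical unweighted Nei-Gojobori method):
#  * per-codon synonymous site fractions exclude single-base changes that
#    create a stop codon (the remaining changes at a position are the
#    denominator); each codon always contributes exactly 3 sites in total;
#  * multi-step codon differences are averaged over all orderings of the
#    substitutions, dropping orderings that pass through a stop codon;
#  * proportions are Jukes-Cantor corrected: d = -3/4 log(1 - 4p/3).

BASES <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position the synonymous fraction is the share of the
#' possible single-base changes (excluding changes that create a stop
#' codon) that leave the amino acid unchanged. The three fractions sum to
#' the codon's synonymous sites; nonsynonymous sites are `3 - syn`.
#'
#' @param codon a 3-letter string of unambiguous bases, not a stop codon.
#' @return named numeric vector `c(syn = , nonsyn = )`.
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("ambiguity error: codon must be 3 unambiguous bases, got '", codon,
         "'", call. = FALSE)
  }
  if (is_stop_codon(codon)) {
    stop("stop-codon error: ", codon, call. = FALSE)
  }
  .ng_site_table[[codon]]
}

.compute_site_counts <- function(codon) {
  aa <- translate_codon(codon)
  syn <- 0
  for (pos in 1:3) {
    alts <- setdiff(BASES, substr(codon, pos, pos))
    muts <- vapply(alts, function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, character(1))
    keep <- !is_stop_codon(muts)
    if (any(keep)) {
      syn <- syn + sum(translate_codon(muts[keep]) == aa) / sum(keep)
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

.sense_codons <- local({
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  sort(all_codons[.codon_table[all_codons] != "*"])
})

.ng_site_table <- local({
  stats::setNames(lapply(.sense_codons, .compute_site_counts), .sense_codons)
})

#' Synonymous and nonsynonymous differences between two codons
#'
#' For codons differing at k positions, every one of the k! substitution
#' orderings is enumerated; orderings passing through a stop codon are
#' discarded and the per-step synonymous/nonsynonymous classifications of
#' the remaining pathways are averaged. When at least one valid pathway
#' exists, `syn + nonsyn = k`.
#'
#' @param codon_a,codon_b 3-letter codon strings of unambiguous bases.
#' @return named numeric vector `c(syn = , nonsyn = )`; both `NA` (with
#'   attribute `n_pathways = 0`) when every pathway passes through a stop.
#' @export
pairwise_codon_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!grepl("^[ACGT]{3}$", cd)) {
      stop("ambiguity error: codon must be 3 unambiguous bases, got '", cd,
           "'", call. = FALSE)
    }
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) {
    return(structure(c(syn = 0, nonsyn = 0), n_pathways = 1L))
  }
  orderings <- .permutations(diff_pos)
  tot_syn <- 0; tot_nonsyn <- 0; n_valid <- 0L
  for (ord in orderings) {
    cur <- codon_a
    path_syn <- 0; path_nonsyn <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop_codon(nxt)) { valid <- FALSE; break }
      if (translate_codon(cur) == translate_codon(nxt)) {
        path_syn <- path_syn + 1
      } else {
        path_nonsyn <- path_nonsyn + 1
      }
      cur <- nxt
    }
    if (valid) {
      tot_syn <- tot_syn + path_syn
      tot_nonsyn <- tot_nonsyn + path_nonsyn
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) {
    return(structure(c(syn = NA_real_, nonsyn = NA_real_), n_pathways = 0L))
  }
  structure(c(syn = tot_syn / n_valid, nonsyn = tot_nonsyn / n_valid),
            n_pathways = n_valid)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Codon strings per haplotype class for the frame-aligned codons; NA for
# codons containing a gap, N, or a stop, which are then dropped pairwise.
.codon_matrix <- function(aln) {
  L <- alignment_length(aln)
  n_codons <- (L - aln$frame_offset) %/% 3L
  key <- apply(aln$mat, 1L, paste, collapse = "")
  counts <- table(key)
  keys <- names(counts)
  cm <- matrix(NA_character_, nrow = length(keys), ncol = n_codons)
  for (j in seq_len(n_codons)) {
    start <- aln$frame_offset + 3L * (j - 1L) + 1L
    cod <- substr(keys, start, start + 2L)
    ok <- grepl("^[ACGT]{3}$", cod) & !(cod %in% names(.codon_table)[.codon_table == "*"])
    cm[, j] <- ifelse(ok, cod, NA_character_)
  }
  list(codons = cm, counts = as.integer(counts), n_codons = n_codons)
}

# Per (codon, haplotype-class-pair) Nei-Gojobori components:
# average syn/nonsyn site counts and syn/nonsyn difference counts, with
# pairwise deletion at codon granularity (NA codons or stop-blocked
# pathways contribute zero sites and zero differences for that pair).
.ng_components <- function(aln, codon_idx) {
  cmat <- .codon_matrix(aln)
  codon_idx <- codon_idx[codon_idx <= cmat$n_codons]
  K <- nrow(cmat$codons)
  pairs <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  P <- nrow(pairs)
  nC <- length(codon_idx)
  SS <- matrix(0, nC, P); NS <- matrix(0, nC, P)
  SD <- matrix(0, nC, P); ND <- matrix(0, nC, P)
  n_blocked <- 0L
  diff_cache <- new.env(parent = emptyenv())
  for (ci in seq_len(nC)) {
    cods <- cmat$codons[, codon_idx[ci]]
    site_c <- lapply(cods, function(cd) if (is.na(cd)) NULL else .ng_site_table[[cd]])
    for (p in seq_len(P)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      ca <- cods[i]; cb <- cods[j]
      if (is.na(ca) || is.na(cb)) next
      if (ca == cb) {
        s <- site_c[[i]]
        SS[ci, p] <- s[["syn"]]; NS[ci, p] <- s[["nonsyn"]]
        next
      }
      ckey <- if (ca < cb) paste0(ca, cb) else paste0(cb, ca)
      d <- diff_cache[[ckey]]
      if (is.null(d)) {
        d <- pairwise_codon_differences(ca, cb)
        diff_cache[[ckey]] <- d
      }
      if (is.na(d[["syn"]])) { n_blocked <- n_blocked + 1L; next }
      SS[ci, p] <- (site_c[[i]][["syn"]] + site_c[[j]][["syn"]]) / 2
      NS[ci, p] <- (site_c[[i]][["nonsyn"]] + site_c[[j]][["nonsyn"]]) / 2
      SD[ci, p] <- d[["syn"]]; ND[ci, p] <- d[["nonsyn"]]
    }
  }
  counts <- cmat$counts
  w_pair <- ifelse(pairs[, 1L] == pairs[, 2L],
                   counts[pairs[, 1L]] * (counts[pairs[, 1L]] - 1) / 2,
                   counts[pairs[, 1L]] * counts[pairs[, 2L]])
  keep <- w_pair > 0
  list(SS = SS[, keep, drop = FALSE], NS = NS[, keep, drop = FALSE],
       SD = SD[, keep, drop = FALSE], ND = ND[, keep, drop = FALSE],
       pair_weights = w_pair[keep], n_codons = nC, n_blocked = n_blocked)
}

.jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# dN/dS from precomputed components under codon weights (bootstrap reuses
# this with resampled weights). Pairs whose corrected distance is
# undefined (p >= 3/4) are excluded from the mean for that measure.
.ng_distance_from_components <- function(comp, codon_w = NULL) {
  codon_w <- codon_w %||% rep(1, comp$n_codons)
  ss <- as.numeric(crossprod(comp$SS, codon_w))
  ns <- as.numeric(crossprod(comp$NS, codon_w))
  sd_ <- as.numeric(crossprod(comp$SD, codon_w))
  nd <- as.numeric(crossprod(comp$ND, codon_w))
  w <- comp$pair_weights
  pS <- ifelse(ss > 0, sd_ / ss, NA_real_)
  pN <- ifelse(ns > 0, nd / ns, NA_real_)
  dS_pair <- .jc_correct(pS); dN_pair <- .jc_correct(pN)
  wmean <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  list(dN = wmean(dN_pair), dS = wmean(dS_pair))
}

#' Nei-Gojobori dN and dS for a codon subset
#'
#' Mean Jukes-Cantor-corrected nonsynonymous and synonymous distances over
#' all unordered haplotype pairs, computed on the codons selected by
#' `site_class` from the partition. Codons containing a gap, `N` or a stop
#' in either sequence of a pair are dropped for that pair only (pairwise
#' deletion at codon granularity); pairs with an undefined correction
#' (p >= 3/4) are excluded from the mean, and the number of stop-blocked
#' codon pairs is reported.
#'
#' @param aln a [phased_alignment()].
#' @param partition a [codon_partition()].
#' @param site_class `"all"`, `"pbr"` or `"nonpbr"`.
#' @return list with `dN`, `dS`, `ratio` (`NA`-flagged when `dS` is 0 or
#'   undefined), `n_codons` and `n_blocked_pairs`.
#' @export
nei_gojobori_distances <- function(aln, partition,
                                   site_class = c("all", "pbr", "nonpbr")) {
  site_class <- match.arg(site_class)
  codon_idx <- partition_codons(partition, site_class)
  if (length(codon_idx) == 0L) stop("empty codon subset", call. = FALSE)
  comp <- .ng_components(aln, codon_idx)
  d <- .ng_distance_from_components(comp)
  ratio <- if (!is.na(d$dS) && d$dS > 0 && !is.na(d$dN)) d$dN / d$dS else NA_real_
  list(dN = d$dN, dS = d$dS, ratio = ratio, n_codons = comp$n_codons,
       n_blocked_pairs = comp$n_blocked)
}

#' Codon-based bootstrap z-test of positive selection
#'
#' Tests `dN = dS` against the Nei-Gojobori distances on the selected codon
#' subset. The codon columns of the subset are resampled with replacement
#' `n_bootstrap` times; the standard errors of `dN`, `dS` and `dN - dS` are
#' the bootstrap replicate standard deviations, `z = (dN - dS)/se(dN - dS)`
#' and the p-value is normal (two-sided by default; `alternative =
#' "greater"` gives the directional test of positive selection).
#'
#' @inheritParams nei_gojobori_distances
#' @param n_bootstrap number of bootstrap replicates (>= 100).
#' @param seed integer seed recorded in the result.
#' @param alternative `"two.sided"` (default) or `"greater"` (dN > dS).
#' @return an object of class `selection_test_result` with fields
#'   `site_class`, `n_codons`, `dN`, `dN_se`, `dS`, `dS_se`, `ratio`, `z`,
#'   `p`, `n_bootstrap`, `seed` and `applicable`.
#' @export
selection_z_test <- function(aln, partition,
                             site_class = c("all", "pbr", "nonpbr"),
                             n_bootstrap = 1000L, seed = NULL,
                             alternative = c("two.sided", "greater")) {
  site_class <- match.arg(site_class)
  alternative <- match.arg(alternative)
  if (n_bootstrap < 100L) stop("need n_bootstrap >= 100", call. = FALSE)
  codon_idx <- partition_codons(partition, site_class)
  comp <- .ng_components(aln, codon_idx)
  obs <- .ng_distance_from_components(comp)
  res <- list(site_class = site_class, n_codons = comp$n_codons,
              dN = obs$dN, dS = obs$dS,
              dN_se = NA_real_, dS_se = NA_real_,
              ratio = if (!is.na(obs$dS) && obs$dS > 0) obs$dN / obs$dS else NA_real_,
              z = NA_real_, p = NA_real_, n_bootstrap = as.integer(n_bootstrap),
              seed = seed, applicable = TRUE)
  monomorphic <- (is.na(obs$dN) || obs$dN == 0) && (is.na(obs$dS) || obs$dS == 0)
  if (monomorphic) {
    res$applicable <- FALSE
    class(res) <- "selection_test_result"
    return(res)
  }
  nC <- comp$n_codons
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      w <- tabulate(sample.int(nC, nC, replace = TRUE), nbins = nC)
      d <- .ng_distance_from_components(comp, w)
      c(d$dN %||% NA_real_, d$dS %||% NA_real_)
    }, numeric(2))
  })
  dn_b <- boot[1L, ]; ds_b <- boot[2L, ]
  res$dN_se <- stats::sd(dn_b, na.rm = TRUE)
  res$dS_se <- stats::sd(ds_b, na.rm = TRUE)
  diff_b <- dn_b - ds_b
  se_diff <- stats::sd(diff_b, na.rm = TRUE)
  if (is.na(se_diff) || se_diff == 0) {
    res$applicable <- FALSE
  } else {
    res$z <- (obs$dN - obs$dS) / se_diff
    res$p <- if (alternative == "two.sided") {
      2 * stats::pnorm(-abs(res$z))
    } else {
      stats::pnorm(res$z, lower.tail = FALSE)
    }
  }
  class(res) <- "selection_test_result"
  res
}

#' @export
print.selection_test_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori selection test [%s], %d codons\n",
              x$site_class, x$n_codons))
  if (!x$applicable) {
    cat("not applicable (monomorphic or degenerate subset)\n")
    return(invisible(x))
  }
  cat(sprintf("dN = %.4f (se %.4f), dS = %.4f (se %.4f), dN/dS = %s\n",
              x$dN, x$dN_se, x$dS, x$dS_se,
              ifelse(is.na(x$ratio), "undefined", sprintf("%.2f", x$ratio))))
  cat(sprintf("z = %.3f, p = %.4g (%d bootstrap replicates)\n",
              x$z, x$p, x$n_bootstrap))
  invisible(x)
}

#' Tally of variable sites inside the peptide-binding region
#'
#' Counts the usable variable alignment columns falling within the frame
#' region covered by the partition and how many of them lie in PBR codons.
#'
#' @inheritParams nei_gojobori_distances
#' @param max_missing per-column missing tolerance (see [usable_columns()]).
#' @return list with `variable_sites_in_pbr` and `variable_sites_total`.
#' @export
pbr_variable_site_tally <- function(aln, partition, max_missing = 0) {
  use <- usable_columns(aln, max_missing)
  first <- aln$frame_offset + 1L
  last <- aln$frame_offset + 3L * partition$total_codons
  use <- use[use >= first & use <= min(last, alignment_length(aln))]
  if (length(use) == 0L) {
    return(list(variable_sites_in_pbr = 0L, variable_sites_total = 0L))
  }
  m <- aln$mat[, use, drop = FALSE]
  variable <- apply(m, 2L, function(col) length(unique(col[col != "N"])) >= 2L)
  vuse <- use[variable]
  codon_of <- (vuse - aln$frame_offset - 1L) %/% 3L + 1L
  list(variable_sites_in_pbr = sum(codon_of %in% partition$pbr_codons),
       variable_sites_total = length(vuse))
}
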