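# Tajima's D on all usable sites or restricted to nonsynonymous sites,
# with significance from the classical beta-distribution approximation of
# the D null (optionally from conditional coalescent simulation).

#' Constants of Tajima's D
#'
#' The standard constants for a sample of `n` haplotypes:
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n number of sampled haplotypes (>= 2; a warning is issued for
#'   n < 4, where the test is degenerate).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("insufficient sample: need n >= 2", call. = FALSE)
  if (n < 4L) warning("Tajima's D is degenerate for n < 4", call. = FALSE)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Classify variable alignment columns as nonsynonymous
#'
#' A usable variable column is nonsynonymous when exchanging the observed
#' bases at that column, holding the other two positions of its codon at
#' their observed context, changes the encoded amino acid. For codons with
#' several variable positions the minimal substitution pathways between the
#' observed codons are enumerated (stop-free pathways only) and the column
#' is counted nonsynonymous when every pathway's step at that column
#' changes the amino acid. Columns in codons containing gaps, `N` or stop
#' codons in some sequence use only the clean observed codons; a column
#' with no clean polymorphic context is left unclassified.
#'
#' @param aln a [phased_alignment()].
#' @param max_missing per-column missing tolerance (see [usable_columns()]).
#' @return integer vector of nonsynonymous column indices (absolute
#'   alignment coordinates).
#' @export
classify_nonsynonymous_columns <- function(aln, max_missing = 0) {
  use <- usable_columns(aln, max_missing)
  L <- alignment_length(aln)
  n_codons <- (L - aln$frame_offset) %/% 3L
  first <- aln$frame_offset + 1L
  last <- aln$frame_offset + 3L * n_codons
  use <- use[use >= first & use <= last]
  m <- aln$mat
  variable <- use[vapply(use, function(j) {
    col <- m[, j]; length(unique(col[col != "N"])) >= 2L
  }, logical(1))]
  out <- integer(0)
  for (j in variable) {
    codon_idx <- (j - aln$frame_offset - 1L) %/% 3L + 1L
    start <- aln$frame_offset + 3L * (codon_idx - 1L) + 1L
    within <- j - start + 1L
    cods <- unique(substr(aln$sequences, start, start + 2L))
    cods <- cods[grepl("^[ACGT]{3}$", cods)]
    cods <- cods[!is_stop_codon(cods)]
    cods <- cods[!duplicated(cods)]
    if (length(cods) < 2L) next
    nonsyn_steps <- logical(0)
    for (a in seq_len(length(cods) - 1L)) {
      for (b in seq((a + 1L), length(cods))) {
        ca <- cods[a]; cb <- cods[b]
        if (substr(ca, within, within) == substr(cb, within, within)) next
        steps <- .pathway_steps_at(ca, cb, within)
        nonsyn_steps <- c(nonsyn_steps, steps)
      }
    }
    if (length(nonsyn_steps) > 0L && all(nonsyn_steps)) out <- c(out, j)
  }
  out
}

# for every stop-free minimal pathway between two codons, whether the step
# that changes position `within` is nonsynonymous
.pathway_steps_at <- function(codon_a, codon_b, within) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  res <- logical(0)
  for (ord in .permutations(diff_pos)) {
    cur <- codon_a; valid <- TRUE; step_nonsyn <- NA
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop_codon(nxt)) { valid <- FALSE; break }
      if (pos == within) {
        step_nonsyn <- translate_codon(cur) != translate_codon(nxt)
      }
      cur <- nxt
    }
    if (valid && !is.na(step_nonsyn)) res <- c(res, step_nonsyn)
  }
  res
}

# mean pairwise raw difference count and segregating sites over a column set
.kbar_and_S <- function(aln, cols) {
  if (length(cols) == 0L) return(list(kbar = 0, S = 0L))
  sub <- aln$mat[, cols, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  counts <- table(key)
  keys <- names(counts)
  D <- class_difference_matrix(keys, length(cols))
  cnt <- as.integer(counts)
  n <- sum(cnt)
  W <- tcrossprod(cnt)
  diag(W) <- cnt * (cnt - 1)
  kbar <- sum(W * D) / (n * (n - 1))
  n_alleles <- apply(sub, 2L, function(col) length(unique(col[col != "N"])))
  list(kbar = kbar, S = sum(n_alleles >= 2L))
}

#' Tajima's D with beta-approximation significance
#'
#' `D = (kbar - S/a1) / sqrt(e1 S + e2 S (S-1))`, with the mean pairwise
#' difference `kbar` (raw counts, not per site) and segregating sites `S`
#' both computed over the filtered column set: all usable columns, or the
#' usable columns classified nonsynonymous by
#' [classify_nonsynonymous_columns()]. Significance is classified from the
#' scaled beta approximation of the neutral null of D
#' (`method = "beta"`, the default) or from coalescent simulations
#' conditional on S (`method = "simulation"`).
#'
#' @inheritParams classify_nonsynonymous_columns
#' @param site_filter `"all"` or `"nonsynonymous"`.
#' @param method significance method, `"beta"` or `"simulation"`.
#' @param n_sim simulation replicates when `method = "simulation"`.
#' @param seed seed for the simulation method (recorded in the result).
#' @return an object of class `tajima_result` with fields `site_filter`,
#'   `n`, `S_used`, `kbar`, `D`, `p` (two-sided) and `significance_class`
#'   (one of `"p > 0.10"`, `"0.10 > p > 0.05"`, `"p < 0.05"`, `"p < 0.01"`,
#'   `"not-applicable"`).
#' @export
tajima_D <- function(aln, site_filter = c("all", "nonsynonymous"),
                     max_missing = 0, method = c("beta", "simulation"),
                     n_sim = 1000L, seed = NULL) {
  site_filter <- match.arg(site_filter)
  method <- match.arg(method)
  n <- n_haplotype_copies(aln)
  cols <- usable_columns(aln, max_missing)
  if (site_filter == "nonsynonymous") {
    cols <- intersect(cols, classify_nonsynonymous_columns(aln, max_missing))
  }
  ks <- .kbar_and_S(aln, cols)
  res <- list(site_filter = site_filter, n = n, S_used = ks$S, kbar = ks$kbar,
              D = NA_real_, p = NA_real_, significance_class = "not-applicable",
              method = method, seed = seed)
  if (ks$S == 0L || n < 2L) {
    class(res) <- "tajima_result"
    return(res)
  }
  ct <- tajima_constants(n)
  vd <- ct$e1 * ks$S + ct$e2 * ks$S * (ks$S - 1)
  if (vd <= 0) {
    class(res) <- "tajima_result"
    return(res)
  }
  res$D <- (ks$kbar - ks$S / ct$a1) / sqrt(vd)
  res$p <- if (method == "beta") {
    .tajima_beta_p(res$D, n, ct)
  } else {
    .tajima_sim_p(res$D, n, ks$S, ct, n_sim, seed)
  }
  res$significance_class <- if (is.na(res$p)) "not-applicable"
    else if (res$p < 0.01) "p < 0.01"
    else if (res$p < 0.05) "p < 0.05"
    else if (res$p < 0.10) "0.10 > p > 0.05"
    else "p > 0.10"
  class(res) <- "tajima_result"
  res
}

# two-sided p from the scaled beta approximation: D ranges between Dmin
# (all singletons) and Dmax (one intermediate-frequency site) and is
# modelled as a generalized beta with mean 0 and variance 1 on that range.
.tajima_beta_p <- function(D, n, ct) {
  dmin <- (2 / n - 1 / ct$a1) / sqrt(ct$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / ct$a1) / sqrt(ct$e2)
  if (!(dmin < 0 && dmax > 0) || (1 + dmin * dmax) >= 0) return(NA_real_)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  if (alpha <= 0 || beta <= 0) return(NA_real_)
  u <- (D - dmin) / (dmax - dmin)
  u <- min(max(u, 0), 1)
  f <- stats::pbeta(u, beta, alpha)
  min(2 * min(f, 1 - f), 1)
}

# p from neutral coalescent genealogies with S mutations dropped on
# branches proportionally to branch length (conditional-on-S null)
.tajima_sim_p <- function(D, n, S, ct, n_sim, seed) {
  with_seed(seed, {
    sims <- vapply(seq_len(n_sim), function(r) {
      sizes <- .coalescent_mutation_sizes(n, S)
      kbar <- sum(2 * sizes * (n - sizes)) / (n * (n - 1))
      vd <- ct$e1 * S + ct$e2 * S * (S - 1)
      (kbar - S / ct$a1) / sqrt(vd)
    }, numeric(1))
    (1 + sum(abs(sims) >= abs(D))) / (1 + n_sim)
  })
}

# one neutral coalescent genealogy for n tips; returns the number of tips
# subtended by each of S mutations placed uniformly on total branch length
.coalescent_mutation_sizes <- function(n, S) {
  sizes <- rep(1L, n)
  active <- seq_len(n)
  branch_len <- rep(0, 2 * n - 1)
  node_size <- c(rep(1L, n), rep(0L, n - 1L))
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    branch_len[active] <- branch_len[active] + t_k
    pick <- sample(seq_along(active), 2L)
    merged <- active[pick]
    node_size[nxt] <- sum(node_size[merged])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  root <- active[1L]
  branch_len[root] <- 0
  probs <- branch_len / sum(branch_len)
  hit <- sample.int(length(branch_len), S, replace = TRUE, prob = probs)
  node_size[hit]  # derived allele count per mutation
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("Tajima's D [%s sites]: n = %d, S = %d\n",
              x$site_filter, x$n, x$S_used))
  if (is.na(x$D)) {
    cat("not applicable (no segregating sites)\n")
  } else {
    cat(sprintf("D = %.3f, %s (two-sided p = %.4g, %s method)\n",
                x$D, x$significance_class, x$p, x$method))
  }
  invisible(x)
}
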