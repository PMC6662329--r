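# Sequence-level diversity estimators and their sampling variances.
#
# All per-site quantities share one usable-column set: columns containing a
# gap are excluded alignment-wide (complete deletion), and columns whose
# fraction of N exceeds the missing tolerance likewise, so that S, Eta, pi
# and the theta estimators are all expressed over the same L.

#' Indices of usable alignment columns
#'
#' A column is usable when it contains no gap and its fraction of `N` does
#' not exceed `max_missing` (default 0: any `N` drops the column). This
#' complete-deletion rule is applied identically by every sequence
#' statistic in the package.
#'
#' @param aln a [phased_alignment()].
#' @param max_missing maximum tolerated fraction of `N` per column.
#' @return integer vector of column indices.
#' @export
usable_columns <- function(aln, max_missing = 0) {
  m <- aln$mat
  has_gap <- colSums(m == "-") > 0L
  n_frac <- colSums(m == "N") / nrow(m)
  which(!has_gap & n_frac <= max_missing)
}

#' Segregating sites and minimum mutation count
#'
#' Counts `S`, the number of usable columns with at least two distinct
#' bases, and `Eta`, the minimum number of mutations (each column
#' contributes its number of distinct bases minus one, so a tri-allelic
#' column adds two).
#'
#' @inheritParams usable_columns
#' @return list with `S`, `eta` and `L` (number of usable columns).
#' @export
segregating_sites_and_eta <- function(aln, max_missing = 0) {
  use <- usable_columns(aln, max_missing)
  if (length(use) == 0L) {
    stop("degenerate input: no usable alignment columns", call. = FALSE)
  }
  m <- aln$mat[, use, drop = FALSE]
  n_alleles <- apply(m, 2L, function(col) length(unique(col[col != "N"])))
  list(S = sum(n_alleles >= 2L), eta = sum(pmax(n_alleles - 1L, 0L)),
       L = length(use))
}

# haplotype strings restricted to the usable columns, with copy counts
haplotype_classes <- function(aln, max_missing = 0) {
  use <- usable_columns(aln, max_missing)
  if (length(use) == 0L) {
    stop("degenerate input: no usable alignment columns", call. = FALSE)
  }
  key <- apply(aln$mat[, use, drop = FALSE], 1L, paste, collapse = "")
  counts <- table(key)
  list(keys = names(counts), counts = as.integer(counts),
       freqs = as.integer(counts) / length(key), use = use)
}

# pairwise difference-count matrix between distinct haplotype classes,
# computed with base-indicator matrix products (fast for large n)
class_difference_matrix <- function(keys, L) {
  K <- length(keys)
  m <- matrix(unlist(strsplit(keys, "", fixed = TRUE), use.names = FALSE),
              nrow = K, byrow = TRUE)
  matches <- matrix(0, K, K)
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  L - matches
}

#' Nucleotide diversity with sampling standard deviation
#'
#' The per-site probability that two randomly drawn haplotypes differ,
#' computed in frequency form over distinct sequence variants with the
#' n/(n-1) sample correction; identical to the mean pairwise difference
#' over all n(n-1)/2 sequence pairs divided by the usable length. The
#' standard deviation follows Nei's (1987) sampling variance for
#' nucleotide diversity,
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#'
#' @inheritParams usable_columns
#' @return list with `pi` and `pi_sd`.
#' @export
nucleotide_diversity <- function(aln, max_missing = 0) {
  n <- n_haplotype_copies(aln)
  if (n < 2L) stop("insufficient sample: need at least 2 sequences", call. = FALSE)
  hc <- haplotype_classes(aln, max_missing)
  L <- length(hc$use)
  D <- class_difference_matrix(hc$keys, L)
  x <- hc$freqs
  pi_site <- (n / (n - 1)) * as.numeric(t(x) %*% (D / L) %*% x)
  v <- (n + 1) / (3 * (n - 1) * L) * pi_site +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_site^2
  list(pi = pi_site, pi_sd = sqrt(v))
}

#' Haplotype diversity with sampling standard deviation
#'
#' `Hd = n/(n-1) (1 - sum(x_k^2))` over distinct sequence variants; the
#' sample-corrected probability that two randomly drawn haplotypes are
#' distinct variants. The default standard deviation uses the full
#' small-sample variance
#' \deqn{V(Hd)=\frac{2}{n(n-1)}\Big[2(n-2)\big(\sum x^3-(\sum x^2)^2\big)
#'   +\sum x^2-(\sum x^2)^2\Big];}
#' `variant = "asymptotic"` instead uses the delta-method variance
#' \eqn{\frac{4}{n}\big(\sum x^3 - (\sum x^2)^2\big)} appropriate for large
#' samples.
#'
#' @inheritParams usable_columns
#' @param variant `"sampling"` (default) or `"asymptotic"`.
#' @return list with `Hd`, `Hd_sd` and `n_variants`.
#' @export
haplotype_diversity <- function(aln, max_missing = 0,
                                variant = c("sampling", "asymptotic")) {
  variant <- match.arg(variant)
  n <- n_haplotype_copies(aln)
  if (n < 2L) stop("insufficient sample: need at least 2 sequences", call. = FALSE)
  hc <- haplotype_classes(aln, max_missing)
  x <- hc$freqs
  s2 <- sum(x^2); s3 <- sum(x^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- if (variant == "sampling") {
    2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  } else {
    4 / n * (s3 - s2^2)
  }
  list(Hd = hd, Hd_sd = sqrt(max(v, 0)), n_variants = length(x))
}

#' Watterson and total-mutation theta estimators (per site)
#'
#' `theta_w = S / (a1 L)` and `theta_eta = Eta / (a1 L)` with
#' `a1 = sum_{i=1}^{n-1} 1/i`. The standard deviation of the Watterson
#' estimator uses the no-recombination neutral variance
#' \deqn{V(\hat\theta_W)=\frac{\hat\theta_W}{a_1 L}
#'   +\frac{a_2}{a_1^2}\hat\theta_W^2,\qquad a_2=\sum_{i=1}^{n-1} 1/i^2.}
#' The two estimators coincide whenever every segregating site is
#' biallelic (S = Eta).
#'
#' @param S number of segregating sites.
#' @param eta minimum number of mutations.
#' @param n number of sampled haplotypes.
#' @param L number of usable sites.
#' @return list with `theta_w`, `theta_w_sd` and `theta_eta`.
#' @export
theta_estimators <- function(S, eta, n, L) {
  if (n < 2L) stop("insufficient sample: need n >= 2", call. = FALSE)
  if (L < 1L) stop("need L >= 1", call. = FALSE)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  theta_w <- S / (a1 * L)
  theta_eta <- eta / (a1 * L)
  v <- theta_w / (a1 * L) + (a2 / a1^2) * theta_w^2
  list(theta_w = theta_w, theta_w_sd = sqrt(v), theta_eta = theta_eta)
}

#' Full sequence-diversity summary for one sample
#'
#' Composes [segregating_sites_and_eta()], [nucleotide_diversity()],
#' [haplotype_diversity()] and [theta_estimators()] on the shared
#' usable-column set.
#'
#' @inheritParams usable_columns
#' @param hd_variant passed to [haplotype_diversity()].
#' @return an object of class `diversity_summary`: a list with `n`, `L`,
#'   `S`, `eta`, `pi`, `pi_sd`, `Hd`, `Hd_sd`, `theta_w`, `theta_w_sd`,
#'   `theta_eta` and `n_variants`.
#' @export
diversity_summary <- function(aln, max_missing = 0, hd_variant = "sampling") {
  se <- segregating_sites_and_eta(aln, max_missing)
  nd <- nucleotide_diversity(aln, max_missing)
  hd <- haplotype_diversity(aln, max_missing, hd_variant)
  th <- theta_estimators(se$S, se$eta, n_haplotype_copies(aln), se$L)
  structure(
    list(n = n_haplotype_copies(aln), L = se$L, S = se$S, eta = se$eta,
         pi = nd$pi, pi_sd = nd$pi_sd, Hd = hd$Hd, Hd_sd = hd$Hd_sd,
         theta_w = th$theta_w, theta_w_sd = th$theta_w_sd,
         theta_eta = th$theta_eta, n_variants = hd$n_variants),
    class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d haplotypes, L = %d usable sites, %d variants\n", x$n, x$L,
    x$n_variants))
  cat(sprintf("S = %d, Eta = %d\n", x$S, x$eta))
  cat(sprintf("pi      = %.4f (%.4f)\n", x$pi, x$pi_sd))
  cat(sprintf("Hd      = %.4f (%.4f)\n", x$Hd, x$Hd_sd))
  cat(sprintf("theta_W = %.4f (%.4f)\n", x$theta_w, x$theta_w_sd))
  cat(sprintf("theta_E = %.4f\n", x$theta_eta))
  invisible(x)
}

#' @export
as.data.frame.diversity_summary <- function(x, ...) {
  data.frame(n = x$n, L = x$L, S = x$S, eta = x$eta, pi = x$pi,
             pi_sd = x$pi_sd, Hd = x$Hd, Hd_sd = x$Hd_sd,
             theta_w = x$theta_w, theta_w_sd = x$theta_w_sd,
             theta_eta = x$theta_eta, n_variants = x$n_variants)
}
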