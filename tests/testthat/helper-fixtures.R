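# Shared fixture builders and independent oracles.

# quick alignment from haplotype strings: seq i belongs to individual
# ceiling(i/2); n must be even
make_aln <- function(seqs, population = "p", frame_offset = 0L) {
  n <- length(seqs)
  stopifnot(n %% 2 == 0)
  phased_alignment(seqs,
                   individual_id = rep(sprintf("i%d", seq_len(n / 2)), each = 2),
                   haplotype_index = rep(c(1L, 2L), times = n / 2),
                   population = population, frame_offset = frame_offset)
}

# random alignment with a handful of variable columns (no gaps/N unless asked)
random_alignment <- function(n_ind = 4, L = 30, n_var = 5,
                             alphabet = c("A", "C", "G", "T")) {
  n <- 2 * n_ind
  base <- sample(alphabet, L, replace = TRUE)
  m <- matrix(rep(base, each = n), nrow = n)
  var_cols <- sample.int(L, min(n_var, L))
  for (j in var_cols) {
    alt <- sample(setdiff(alphabet, m[1, j]), 1)
    carriers <- sample.int(n, sample(seq_len(n - 1), 1))
    m[carriers, j] <- alt
  }
  make_aln(apply(m, 1, paste, collapse = ""))
}

# brute-force nucleotide diversity: mean pairwise per-site difference over
# all unordered sequence pairs, on the gap/N-free columns
oracle_pi <- function(aln) {
  use <- which(apply(aln$mat, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
  m <- aln$mat[, use, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / choose(n, 2) / length(use)
}

# independent Tajima's D: kbar and S through ape (raw pairwise difference
# counts and segregating sites), constants written out directly
oracle_tajima_D <- function(aln) {
  use <- which(apply(aln$mat, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
  m <- tolower(aln$mat[, use, drop = FALSE])
  bin <- ape::as.DNAbin(m)
  kbar <- mean(ape::dist.dna(bin, model = "N"))
  S <- length(ape::seg.sites(bin))
  n <- nrow(m)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
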