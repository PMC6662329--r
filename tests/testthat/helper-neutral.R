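# Minimal neutral infinite-sites coalescent simulator, independent of the
# package's internals: used to check estimator consistency and the
# neutrality tests' calibration.

# simulate one genealogy for n tips; returns a list of branches, each with
# its descendant tip set and length (coalescent time units)
sim_coalescent_branches <- function(n) {
  branches <- lapply(seq_len(n), function(i) list(tips = i, len = 0))
  active <- seq_len(n)
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    for (b in active) branches[[b]]$len <- branches[[b]]$len + t_k
    pick <- sample(seq_along(active), 2)
    merged <- active[pick]
    branches[[length(branches) + 1]] <-
      list(tips = c(branches[[merged[1]]]$tips, branches[[merged[2]]]$tips),
           len = 0)
    active <- c(active[-pick], length(branches))
    k <- k - 1
  }
  branches[-length(branches)]  # drop the root branch (no length / all tips)
}

# infinite-sites sample: haplotype 0/1 matrix (n x S), mutations Poisson
# with per-locus theta
sim_infinite_sites <- function(n, theta) {
  br <- sim_coalescent_branches(n)
  lens <- vapply(br, `[[`, numeric(1), "len")
  n_mut <- rpois(1, theta / 2 * sum(lens))
  m <- matrix(0L, nrow = n, ncol = n_mut)
  if (n_mut > 0) {
    hit <- sample.int(length(br), n_mut, replace = TRUE, prob = lens)
    for (s in seq_len(n_mut)) m[br[[hit[s]]]$tips, s] <- 1L
  }
  m
}

# wrap an infinite-sites sample as a phased_alignment (padded with a few
# invariant columns so the container's minimum-length invariant holds)
sim_neutral_alignment <- function(n, theta, pad = 6) {
  m01 <- sim_infinite_sites(n, theta)
  chars <- matrix("A", nrow = n, ncol = ncol(m01) + pad)
  if (ncol(m01) > 0) chars[, seq_len(ncol(m01))][m01 == 1L] <- "T"
  make_aln(apply(chars, 1, paste, collapse = ""))
}
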