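# Two-population synthetic fixtures with the statistical structure the
# analysis assumes: an MHC-like amplicon whose variation is concentrated at
# nonsynonymous peptide-binding-region positions, with unequal haplotype
# richness between populations, and multiallelic microsatellites near
# Hardy-Weinberg equilibrium with similar diversity in both populations.
#
# Haplotype pools are constructed directly (no coalescent machinery): the
# analysis needs controlled pi, Hd and PBR concentration, not genealogical
# realism.

#' Scenario configuration for the synthetic generator
#'
#' Builds the full parameter set describing a two-population scenario.
#' Defaults follow the demographic and diversity structure of a
#' conservation-genetics comparison of one large viable population (`A`)
#' and one small declining population (`B`): a 172-bp in-frame amplicon
#' (frame offset 2, 56 complete codons, 17 of them PBR), population sizes
#' 239 and 55 (individuals with both marker types), age-class composition
#' 2:15:38 calves:juveniles:adults and sex composition 32:23 males:females,
#' richer MHC variation in `A` (26 vs 21 variable sites, 40 vs 25
#' haplotypes, expected nucleotide diversity ratio about 1.25), mutation
#' placement concentrated on PBR-nonsynonymous positions (82% of variable
#' sites in PBR codons), and 25 microsatellite loci with identical
#' generating frequencies in the two populations.
#'
#' @param preset `"paper_like"` (unequal MHC richness, shared msat
#'   frequencies) or `"null"` (one shared haplotype pool and shared msat
#'   frequencies: the two populations are statistically identical).
#' @param seed master seed; every stochastic step derives its own child
#'   seed from it.
#' @param ... named overrides of any top-level config entry (`amplicon`,
#'   `populations`, `msat`, `composition`).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(preset = c("paper_like", "null"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    amplicon = list(length = 172L, frame_offset = 2L, total_codons = 56L,
                    n_pbr = 17L),
    populations = list(
      A = list(n_individuals = 239L, n_haplotypes = 40L,
               n_variable_sites = 26L, derived_prob = 0.35,
               hap_freq_alpha = 1,
               placement_weights = c(pbr_nonsyn = 0.72, pbr_syn = 0.10,
                                     nonpbr = 0.18)),
      B = list(n_individuals = 55L, n_haplotypes = 25L,
               n_variable_sites = 21L, derived_prob = 0.35,
               hap_freq_alpha = 1,
               placement_weights = c(pbr_nonsyn = 0.72, pbr_syn = 0.10,
                                     nonpbr = 0.18))),
    msat = list(n_loci = 25L, allele_range = c(3L, 8L), freq_alpha = 1,
                missing_rate = 0.02, inbreeding_f = 0,
                shared_frequencies = TRUE),
    composition = list(
      age_class = c(calf = 2, juvenile = 15, adult = 38) / 55,
      sex = c(male = 32, female = 23) / 55,
      unknown_rate = 0))
  if (preset == "null") {
    # statistically identical populations: one shared haplotype pool and
    # shared msat frequencies; only the sampling depths differ
    n_a <- cfg$populations$A$n_individuals
    cfg$populations$A <- cfg$populations$B
    cfg$populations$A$n_individuals <- n_a
    cfg$mhc_shared_pool <- TRUE
  } else {
    cfg$mhc_shared_pool <- FALSE
  }
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  ok <- vapply(cfg$populations, function(p) {
    p$n_individuals >= 2L && all(p$placement_weights >= 0) &&
      sum(p$placement_weights) > 0
  }, logical(1))
  if (!all(ok)) stop("invalid population config", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

# deterministic stop-free base amplicon and PBR codon choice for a config
.base_amplicon <- function(config) {
  with_seed(derive_seed(config$seed, 100L), {
    amp <- config$amplicon
    codons <- sample(.sense_codons, amp$total_codons, replace = TRUE)
    prefix <- paste(sample(BASES, amp$frame_offset, replace = TRUE),
                    collapse = "")
    tail_len <- amp$length - amp$frame_offset - 3L * amp$total_codons
    suffix <- if (tail_len > 0L) {
      paste(sample(BASES, tail_len, replace = TRUE), collapse = "")
    } else ""
    base <- paste0(prefix, paste(codons, collapse = ""), suffix)
    pbr <- sort(sample.int(amp$total_codons, amp$n_pbr))
    list(base = base, partition = codon_partition(pbr, amp$total_codons))
  })
}

# candidate single-base substitutions of the base sequence, classified as
# pbr_nonsyn / pbr_syn / nonpbr; substitutions creating stops are excluded
.candidate_substitutions <- function(base, partition, frame_offset) {
  n_codons <- partition$total_codons
  out <- list()
  for (codon_idx in seq_len(n_codons)) {
    start <- frame_offset + 3L * (codon_idx - 1L) + 1L
    cod <- substr(base, start, start + 2L)
    aa <- translate_codon(cod)
    in_pbr <- codon_idx %in% partition$pbr_codons
    for (within in 1:3) {
      pos <- start + within - 1L
      ref <- substr(cod, within, within)
      for (alt in setdiff(BASES, ref)) {
        mut <- cod; substr(mut, within, within) <- alt
        if (is_stop_codon(mut)) next
        syn <- translate_codon(mut) == aa
        class_ <- if (!in_pbr) "nonpbr" else if (syn) "pbr_syn" else "pbr_nonsyn"
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, alt = alt, class = class_, codon = codon_idx,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

.rdirichlet <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Generate a haplotype pool for one population
#'
#' Derives `n_haplotypes` distinct stop-free haplotypes from the scenario's
#' base amplicon by choosing `n_variable_sites` substitution positions
#' according to the placement weights (PBR-nonsynonymous / PBR-synonymous /
#' non-PBR, verified against the codon table) and giving each non-base
#' haplotype every site's derived allele independently with probability
#' `derived_prob`. Haplotype frequencies are drawn from a symmetric
#' Dirichlet with concentration `hap_freq_alpha`.
#'
#' @param config a [scenario_config()].
#' @param population `"A"` or `"B"`.
#' @param seed optional seed override (defaults to a child of the config
#'   master seed).
#' @return list with `haplotypes` (character vector), `freqs`, `sites`
#'   (data.frame of variable positions with class labels), `base` and
#'   `partition`.
#' @export
generate_haplotype_pool <- function(config, population = "A", seed = NULL) {
  pcfg <- config$populations[[population]]
  if (is.null(pcfg)) stop("unknown population: ", population, call. = FALSE)
  amp <- .base_amplicon(config)
  cand <- .candidate_substitutions(amp$base, amp$partition,
                                   config$amplicon$frame_offset)
  seed <- seed %||% derive_seed(config$seed, 200L + match(population, c("A", "B")))
  with_seed(seed, {
    w <- pcfg$placement_weights
    class_w <- c(pbr_nonsyn = unname(w["pbr_nonsyn"]),
                 pbr_syn = unname(w["pbr_syn"]),
                 nonpbr = unname(w["nonpbr"]))
    # class-level placement probabilities: divide by the number of
    # candidates per class so rare classes are not swamped by common ones
    class_n <- table(factor(cand$class, levels = names(class_w)))
    cand_w <- class_w[cand$class] / as.numeric(class_n[cand$class])
    cand_w[is.na(cand_w) | !is.finite(cand_w)] <- 0
    n_sites <- min(pcfg$n_variable_sites, sum(cand_w > 0))
    # sample positions without replacement, one substitution per position
    picked <- integer(0); avail <- which(cand_w > 0)
    while (length(picked) < n_sites && length(avail) > 0L) {
      i <- avail[sample.int(length(avail), 1L, prob = cand_w[avail])]
      picked <- c(picked, i)
      avail <- avail[cand$pos[avail] != cand$pos[i]]
    }
    sites <- cand[picked, , drop = FALSE]
    K <- pcfg$n_haplotypes
    if (K == 1L || nrow(sites) == 0L) {
      haps <- amp$base
      freqs <- 1
    } else {
      haps <- amp$base
      max_attempts <- 200L * K
      attempts <- 0L
      while (length(haps) < K) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("generation error: could not build ", K,
               " distinct stop-free haplotypes", call. = FALSE)
        }
        h <- amp$base
        carry <- stats::runif(nrow(sites)) < pcfg$derived_prob
        for (si in which(carry)) {
          substr(h, sites$pos[si], sites$pos[si]) <- sites$alt[si]
        }
        if (!(h %in% haps)) haps <- c(haps, h)
      }
      freqs <- .rdirichlet(K, pcfg$hap_freq_alpha)
    }
    list(haplotypes = haps, freqs = freqs, sites = sites, base = amp$base,
         partition = amp$partition)
  })
}

#' Simulate a diploid population sample from a haplotype pool
#'
#' Draws `2 n` haplotypes by random mating (independent draws from the pool
#' frequencies), pairs them into individuals, and samples each individual's
#' age class and sex from the configured composition proportions
#' (multinomially, with an optional unknown rate).
#'
#' @param config a [scenario_config()].
#' @param population `"A"` or `"B"`.
#' @param seed seed for the draws.
#' @param pool optional pre-generated pool (see [generate_haplotype_pool()]);
#'   used to share one pool realisation between populations in the null
#'   scenario.
#' @return list with `alignment` (a [phased_alignment()]) and `metadata`
#'   (an [individual_metadata()] table).
#' @export
simulate_population <- function(config, population = "A", seed = NULL,
                                pool = NULL) {
  pcfg <- config$populations[[population]]
  pool <- pool %||% generate_haplotype_pool(config, population)
  seed <- seed %||% derive_seed(config$seed, 300L + match(population, c("A", "B")))
  with_seed(seed, {
    n <- pcfg$n_individuals
    draws <- sample.int(length(pool$haplotypes), 2L * n, replace = TRUE,
                        prob = pool$freqs)
    ids <- sprintf("%s%03d", population, seq_len(n))
    aln <- phased_alignment(
      sequences = pool$haplotypes[draws],
      individual_id = rep(ids, each = 2L),
      haplotype_index = rep(c(1L, 2L), times = n),
      population = population,
      frame_offset = config$amplicon$frame_offset)
    comp <- config$composition
    age <- sample(names(comp$age_class), n, replace = TRUE,
                  prob = comp$age_class)
    sex <- sample(names(comp$sex), n, replace = TRUE, prob = comp$sex)
    if (comp$unknown_rate > 0) {
      age[stats::runif(n) < comp$unknown_rate] <- "unknown"
      sex[stats::runif(n) < comp$unknown_rate] <- "unknown"
    }
    md <- individual_metadata(data.frame(
      id = ids, population = population, sex = sex, age_class = age,
      stringsAsFactors = FALSE))
    list(alignment = aln, metadata = md)
  })
}

# per-locus allele frequency realisations for the msat system
.msat_frequencies <- function(config, seed) {
  with_seed(seed, {
    m <- config$msat
    lapply(seq_len(m$n_loci), function(l) {
      k <- sample(seq(m$allele_range[1L], m$allele_range[2L]), 1L)
      .rdirichlet(k, m$freq_alpha)
    })
  })
}

#' Simulate a microsatellite dataset for one population
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet (or
#' supplied via `freqs`, which the scenario uses to share one realisation
#' between the two populations). Genotypes follow Hardy-Weinberg
#' proportions with an optional inbreeding-like heterozygote-deficit
#' parameter `F`: `P(hom k) = p_k^2 + F p_k (1 - p_k)`. Genotypes go
#' missing independently at the configured rate.
#'
#' @param config a [scenario_config()].
#' @param population `"A"` or `"B"`.
#' @param seed seed for the draws.
#' @param freqs optional list of per-locus frequency vectors.
#' @param ids optional individual ids (defaults to the population's ids).
#' @return an [msat_dataset()].
#' @export
simulate_msat <- function(config, population = "A", seed = NULL, freqs = NULL,
                          ids = NULL) {
  pcfg <- config$populations[[population]]
  m <- config$msat
  seed <- seed %||% derive_seed(config$seed, 400L + match(population, c("A", "B")))
  freqs <- freqs %||%
    .msat_frequencies(config, derive_seed(config$seed, 410L))
  with_seed(seed, {
    n <- pcfg$n_individuals
    ids <- ids %||% sprintf("%s%03d", population, seq_len(n))
    loci <- sprintf("L%02d", seq_along(freqs))
    a1 <- matrix(NA_integer_, n, length(freqs))
    a2 <- a1
    for (l in seq_along(freqs)) {
      p <- freqs[[l]]
      k <- length(p)
      x1 <- sample.int(k, n, replace = TRUE, prob = p)
      if (m$inbreeding_f > 0) {
        ibd <- stats::runif(n) < m$inbreeding_f
        x2 <- ifelse(ibd, x1, sample.int(k, n, replace = TRUE, prob = p))
      } else {
        x2 <- sample.int(k, n, replace = TRUE, prob = p)
      }
      miss <- stats::runif(n) < m$missing_rate
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      # allele labels as plausible fragment sizes: 100 + 2*index
      a1[, l] <- 100L + 2L * x1
      a2[, l] <- 100L + 2L * x2
    }
    msat_dataset(ids, loci, a1, a2, population)
  })
}

#' Simulate a full two-population scenario in memory
#'
#' @param config a [scenario_config()].
#' @return list with `alignment` (both populations combined), `msat`,
#'   `metadata`, `partition`, `pools` and `config`.
#' @export
simulate_scenario <- function(config) {
  pool_a <- generate_haplotype_pool(config, "A")
  pool_b <- if (isTRUE(config$mhc_shared_pool)) pool_a else
    generate_haplotype_pool(config, "B")
  sim_a <- simulate_population(config, "A", pool = pool_a)
  sim_b <- simulate_population(config, "B", pool = pool_b)
  shared_freqs <- if (isTRUE(config$msat$shared_frequencies)) {
    .msat_frequencies(config, derive_seed(config$seed, 410L))
  } else NULL
  ms_a <- simulate_msat(config, "A", freqs = shared_freqs)
  ms_b <- simulate_msat(config, "B", freqs = shared_freqs)
  aln <- phased_alignment(
    c(sim_a$alignment$sequences, sim_b$alignment$sequences),
    c(sim_a$alignment$individual_id, sim_b$alignment$individual_id),
    c(sim_a$alignment$haplotype_index, sim_b$alignment$haplotype_index),
    c(sim_a$alignment$population, sim_b$alignment$population),
    config$amplicon$frame_offset)
  msat <- msat_dataset(
    c(ms_a$individuals, ms_b$individuals), ms_a$loci,
    rbind(ms_a$allele1, ms_b$allele1), rbind(ms_a$allele2, ms_b$allele2),
    c(ms_a$population, ms_b$population))
  metadata <- individual_metadata(rbind(sim_a$metadata, sim_b$metadata))
  list(alignment = aln, msat = msat, metadata = metadata,
       partition = pool_a$partition,
       pools = list(A = pool_a, B = pool_b), config = config)
}

#' Write a full scenario fixture bundle to disk
#'
#' Emits the same formats the readers consume -- `alignment.fasta`,
#' `genotypes.csv`, `metadata.csv`, `pbr_partition.json` -- plus
#' `manifest.json` recording the true generating parameters and the
#' dimensions of every emitted file (for parameter-recovery tests).
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_scenario <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_scenario(config)
  write_phased_fasta(sc$alignment, file.path(out_dir, "alignment.fasta"))
  write_genotype_csv(sc$msat, file.path(out_dir, "genotypes.csv"))
  utils::write.csv(as.data.frame(sc$metadata),
                   file.path(out_dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(pbr_codons = sc$partition$pbr_codons,
                            total_codons = sc$partition$total_codons),
                       file.path(out_dir, "pbr_partition.json"),
                       auto_unbox = TRUE)
  manifest <- list(
    seed = config$seed, preset = config$preset,
    amplicon = config$amplicon,
    n_individuals = lapply(config$populations, `[[`, "n_individuals"),
    n_haplotypes_pool = lapply(sc$pools, function(p) length(p$haplotypes)),
    n_sequences = length(sc$alignment$sequences),
    n_msat_individuals = length(sc$msat$individuals),
    n_loci = length(sc$msat$loci),
    files = c("alignment.fasta", "genotypes.csv", "metadata.csv",
              "pbr_partition.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
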