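---
title: "Comparing adaptive and neutral genetic diversity between two populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing adaptive and neutral genetic diversity between two populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divcompare)
```

## The problem

Conservation assessments of wild populations usually report genetic
diversity at selectively neutral markers such as microsatellites. For
adaptive potential, however, diversity at functionally important loci —
classically the major histocompatibility complex (MHC) — is the more
relevant quantity. `divcompare` implements the full analysis needed to
contrast the two marker systems between two conspecific populations that
were sampled at very different depths: sequence-level diversity of a
phased MHC class II DQB exon-2 amplicon, codon-level tests of selection
partitioned by the peptide-binding region (PBR), Tajima's $D$,
per-locus microsatellite diversity with quality screening, and a
demographically matched sampling framework that makes the two
populations statistically comparable.

The package operates on four plain-text inputs: a phased haplotype FASTA
(two sequences per diploid individual), a genotype CSV (two integer
alleles per locus, missing allowed), an individual metadata CSV
(population, sex, age class) and a codon-partition file giving the
1-based indices of the PBR codons within the amplicon reading frame. The
PBR partition is always an input, never hard-coded: the codon positions
come from structural annotations that differ between studies.

## Sequence diversity estimators

All per-site statistics share one *usable-column* set: any column
containing an alignment gap is removed alignment-wide (complete
deletion), and columns whose fraction of `N` exceeds a tolerance
(default 0) likewise. On those $L$ columns the package computes, for $n$
sampled haplotypes with variant frequencies $x_k$:

* nucleotide diversity
  $\pi = \frac{n}{n-1}\sum_{i}\sum_{j} x_i x_j \pi_{ij}$, the
  sample-corrected per-site probability that two random haplotypes
  differ, identical to the mean pairwise difference over all
  $\binom{n}{2}$ sequence pairs divided by $L$;
* haplotype diversity $H_d = \frac{n}{n-1}(1 - \sum_k x_k^2)$;
* the Watterson estimator $\hat\theta_W = S/(a_1 L)$ from the number of
  segregating sites $S$, with $a_1 = \sum_{i=1}^{n-1} 1/i$;
* $\hat\theta_\eta = \eta/(a_1 L)$ from the minimum mutation count
  $\eta$, which exceeds $S$ at columns carrying more than two bases
  (each extra base adds one mutation).

Sampling variances follow the classical formulas: for $\pi$,
$V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2$; for
$H_d$ the full small-sample variance
$\frac{2}{n(n-1)}\left[2(n-2)\left(\sum x^3 - (\sum x^2)^2\right) + \sum
x^2 - (\sum x^2)^2\right]$ (a delta-method asymptotic variance is
available via `variant = "asymptotic"` — the literature is ambiguous
about which of the two a given program reports, so both are offered and
the small-sample form is the default); for $\hat\theta_W$ the
no-recombination neutral variance
$\hat\theta_W/(a_1 L) + (a_2/a_1^2)\hat\theta_W^2$. All are reported as
standard deviations.

## Selection on the amplicon

`selection_z_test()` implements the unweighted Nei–Gojobori method. Each
codon contributes synonymous site fractions computed by enumerating its
nine single-base mutants (changes creating stop codons are excluded from
the per-position denominator, so each codon still carries exactly 3
sites). Differences between codons are averaged over all substitution
orderings, discarding orderings that pass through a stop codon. Per
sequence pair, $p_N$ and $p_S$ are the difference/site ratios over the
analyzed codon subset (all codons, PBR only, or non-PBR only) and are
Jukes–Cantor corrected, $d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)$; $d_N$
and $d_S$ are means over pairs. Codons containing gaps, `N` or stops in
a pair are dropped for that pair only (pairwise deletion at codon
granularity), and pairs with $p \ge 3/4$ are excluded from the mean with
a count reported.

The test of $d_N = d_S$ resamples the codon columns of the analyzed
subset with replacement (1,000 replicates by default); the replicate
standard deviation of $d_N - d_S$ gives the standard error,
$z = (d_N - d_S)/\mathrm{se}$, and the p-value is normal. The two-sided
test is the default; positive selection is directional, so a one-sided
variant is available via `alternative = "greater"`.

`tajima_D()` computes
$D = (\bar{k} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with $\bar{k}$ the raw
(not per-site) mean pairwise difference count, either on all usable
columns or restricted to columns classified nonsynonymous. A variable
column is nonsynonymous when exchanging its observed bases within the
observed codon context changes the amino acid; codons with several
variable positions are resolved by enumerating stop-free minimal
pathways, and a column counts as nonsynonymous only if every pathway's
step at that column changes the amino acid. Significance is classified
(`p > 0.10`, `0.10 > p > 0.05`, `p < 0.05`, `p < 0.01`) from the scaled
beta approximation of the neutral null of $D$; the original description
of the statistic does not pin down a significance recipe, so a
coalescent-simulation p-value conditional on $S$ is offered behind
`method = "simulation"` with a stored seed, and the beta approximation
is the default because it is what the standard software reports.

## Microsatellite statistics

Per locus and population: observed heterozygosity $H_o$, expected
heterozygosity $H_e = 1 - \sum_k p_k^2$ (uncorrected, matching the
convention of the standard population-genetics spreadsheet software;
the $2n/(2n-1)$ unbiased form is behind a flag), effective allele number
$A_e = 1/\sum p_k^2$ (so $H_e = 1 - 1/A_e$ always holds) and Shannon
index $-\sum p_k \ln p_k$.

Hardy–Weinberg departures are screened with a chi-square goodness-of-fit
over all $k(k+1)/2$ genotype classes (df $= k(k-1)/2$); a seeded
Monte-Carlo variant that reshuffles the $2n$ allele copies is available
for sparse tables. The Bonferroni family for the locus filter is
loci × populations: a locus flagged in *any* population below
$\alpha/(L \cdot P)$ is dropped for all downstream comparisons, which is
how a 25-locus panel shrinks to 23 when two loci fail.

Linkage disequilibrium is screened with a permutation G-test on the
genotype × genotype contingency table, permuting one locus across
individuals; p-values honour the $(1 + \text{hits})/(1 + N)$ floor. This
replaces the Markov-chain exact test of the classical software with a
simpler, seeded procedure; in the intended workflow the LD screen is
advisory only (no locus is dropped on LD evidence alone).

$F_{ST}$ defaults to the heterozygosity form
$(H_t - \bar{H}_s)/H_t$ per locus with $H_t$ from pooled allele
frequencies, averaged over loci; the Weir–Cockerham variance-components
$\theta$ (summed over loci as $\sum a / \sum (a+b+c)$) is available
because published multilocus $F_{ST}$ values rarely state their
estimator.

## The three-tier sampling framework

When one population is sampled several times more deeply than the
other, raw diversity comparisons confound depth with biology. The
framework therefore reports three tiers:

1. **Maximum** — every individual with data for the marker at hand.
2. **Conservative** — restrict to individuals with *both* marker types;
   the smaller population defines a reference demographic composition
   (age-class and sex marginals), and disjoint subsamples of the larger
   population are drawn to match that composition exactly (randomized
   greedy fill with restarts; individuals of unknown age or sex are
   excluded; infeasible compositions raise a capacity error naming the
   deficient category).
3. **Subsampling** — each population's conservative-eligible pool is
   partitioned into disjoint subsamples of 11 individuals
   ($\lfloor n/11 \rfloor$ by default, overridable to reproduce a
   published design), the sequence statistics are computed per
   subsample, and the populations are compared with a pooled-variance
   two-sample t-test (df $= k_A + k_B - 2$; pooled rather than Welch
   because published comparisons of 19 + 5 subsamples report df = 22).
   Microsatellite measures are compared with paired t-tests across loci
   (df $=$ loci $- 1$).

All random choices flow from one master seed through
`derive_seed()`, so a full `run_analysis()` is bit-reproducible.

## What the synthetic generator emulates — and what it does not

`scenario_config()` describes a two-population world; its defaults are
the demographic structure the analysis was designed around: populations
of 239 and 55 individuals with both marker types, age-class proportions
2:15:38 (calves:juveniles:adults) and sexes 32:23 (males:females), a
172-bp in-frame amplicon with 56 complete codons of which 17 are PBR.
Haplotype pools are built directly from a base sequence: variable
positions are placed with class weights 0.72/0.10/0.18
(PBR-nonsynonymous / PBR-synonymous / non-PBR, giving ~82% of variable
sites in PBR codons), each non-base haplotype carries each derived
allele with probability 0.35, and haplotype frequencies come from a
symmetric Dirichlet ($\alpha = 1$, giving $H_d \approx 0.92$–$0.95$ for
pools of 25–40 haplotypes, matching the high haplotype diversity typical
of MHC data). Population A carries 26 variable sites and 40 haplotypes
against B's 21 and 25, which yields an expected nucleotide-diversity
ratio of about 1.25 at similar $H_d$ — the qualitative signature of a
viable versus declining population pair. Microsatellites use one shared
per-locus frequency realisation for both populations (3–8 alleles,
Dirichlet $\alpha = 1$, 2% missing), so the neutral contrast is null by
construction; an inbreeding-like knob $F$ can break Hardy–Weinberg for
power checks.

The `"null"` preset makes the populations statistically identical: one
shared haplotype pool realisation and shared microsatellite
frequencies. Sharing the realisation (rather than redrawing from the
same distribution) is deliberate — with independent Dirichlet draws the
two populations would have different true frequencies and the nominal
null would be false. For calibration of the subsampling t-test the
cleanest reading of "identical populations" also equalises sampling
depth (55 vs 55 individuals, 5 × 11 subsamples each); with that design
the type-I error is ~4.5% (600 seeds). With strongly unbalanced
subsample counts (21 vs 5) the pooled t over a skewed statistic is
mildly anti-conservative (~6%), which is worth knowing when
interpreting published df = 22 comparisons.

The generator makes no attempt at genealogical realism: pools are
constructed, not coalescent-simulated, so site-frequency spectra are not
neutral (generated data typically show positive Tajima's $D$), there is
no recombination, no mutation-rate realism and no pedigree structure. A
green pipeline test therefore establishes that the estimators and the
sampling machinery behave correctly on data with the right *structure*,
not that any particular biological inference is reproduced. Neutral
calibration of the estimators themselves uses a separate infinite-sites
coalescent oracle in the test suite, which recovers the generating
$\theta$ for $\pi$, $\theta_W$ and $\theta_\eta$ within Monte-Carlo
error.

## Numerical choices and degenerate inputs

* $d_N/d_S$ is reported as `NA` (flagged) when $d_S = 0$; the ratio is
  invariant to any uniform rescaling of the distances, which matters
  because some software reports per-100-site values.
* Tests on monomorphic inputs return `applicable = FALSE` /
  `"not-applicable"` rather than an error; zero-variance t-tests return
  $t = 0, p = 1$ when means agree and a flagged numerical-floor result
  when they do not.
* Chi-square HWE p-values are only trusted in regimes with adequate
  expected counts; the calibration suite uses 2–3 alleles at moderate
  frequencies with $n = 500$, and the Monte-Carlo method is recommended
  below that.
* The demographic matcher can fail on an unlucky multinomial metadata
  draw (e.g. fewer calves than the reference requires); this surfaces
  as a capacity error, and the acceptance script falls back to a
  deterministically derived seed.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config("paper_like", seed = 3)
sc <- simulate_scenario(cfg)

ids_b <- unique(sc$alignment$individual_id[sc$alignment$population == "B"])
diversity_summary(subset_alignment(sc$alignment, ids_b))

report <- compare_populations(sc$alignment, sc$msat, sc$metadata,
                              partition = sc$partition,
                              plan = sampling_plan(seed = 3))
report$t_tests

# or end to end, writing table1.tsv ... table5.tsv:
run_analysis(list(simulate = list(preset = "paper_like", seed = 3),
                  seed = 3), out_dir = "run3")
```

## Known limitations

* The nonsynonymous-column classifier needs the observed codon context;
  columns whose codons are never observed cleanly stay unclassified.
* Null-allele and scoring-error detection is reduced to missing-rate and
  heterozygote-deficit warnings (`msat_qc_warnings()`); dedicated tools
  exist for serious screening.
* Haplotype *phasing* is out of scope: the package consumes already
  phased sequences and trusts the two-per-individual pairing.
* With only two populations, significant contrasts say nothing about
  cause and effect; the framework quantifies the contrast, not its
  origin.
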