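---
title: "Modelling the evolution of physical linkage between a magic trait and mating-preference loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of physical linkage between a magic trait and mating-preference loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When a trait under divergent ecological selection also serves as the mating
cue (a *magic trait*), selection and assortative mating are automatically
coupled at that locus. The preference acting on the cue, however, is
typically polygenic, and recombination can dissociate preference alleles
from the trait alleles they "match". One way out is *physical linkage*:
preference mutations that happen to land close to the trait locus are less
often separated from it by crossing over, so chromosomes carrying such
architectures can be favoured. `magiclink` implements an individual-based
model of this process: rather than imposing a genetic architecture, it lets
the population *choose* one, by filtering preference mutations that arise
at random positions along the chromosome.

## The model

The population holds $2K$ diploid individuals (default $K = 5000$ per
habitat) with a single pair of homologous chromosomes of $L = 100$ loci.
Position 0 is the ecological trait locus with alleles $A$ and $A'$;
codominance gives three phenotypes (AA, AA$'$, A$'$A$'$). The remaining 99
positions start in an inert "wild" state and can mutate into alleles
conferring preference for AA mates, preference for A$'$A$'$ mates, or a
neutral marker used as the null for every distance statistic. Habitats are
non-spatial: habitat 1 favours AA, habitat 2 favours A$'$A$'$.

Each discrete, non-overlapping generation executes five stages in order:

1. **Pair formation.** Females choose in a fresh random order. Each is
   sequentially paired with up to `max_pairings` (10) males drawn uniformly
   from the unmated male pool of *both* habitats (males move freely while
   searching). A female with preference score $d$ — her count of
   preference-for-AA alleles minus preference-for-A$'$A$'$ alleles over
   both chromosomes — accepts an AA male with probability
   $$P_A = \frac{1}{1 + e^{-d \cdot pf}},$$
   an A$'$A$'$ male with $P_{A'} = 1 - P_A$, and a heterozygote male with a
   constant 0.5 (`het_mate_prob`). The preference-strength factor $pf$
   scales the effect of each additional allele. Mating is monogamous; a
   female exhausting her pairings does not reproduce.
2. **Reproduction.** Each pair produces `n_offspring` (4) offspring, half
   of each sex, each inheriting one uniformly chosen chromosome per parent,
   placed in the mother's habitat. Parents die.
3. **Recombination and mutation.** Each offspring undergoes
   `n_crossovers` (1) tail-swap crossovers at a uniform cut among the
   $L-1$ gaps; this never alters its own genotype or preference score,
   only the gametes it will transmit. Then a 1% share of individuals
   (see below) each receive one mutation at a uniform non-trait position on
   a uniform homolog, the new state uniform over the three mutant classes
   (so repeat hits and back-mutations occur). The trait locus never
   mutates.
4. **Ecological selection.** Locally adapted homozygotes always survive;
   every other habitat/phenotype combination dies with probability $s$
   (heterozygotes with $s \times$ `het_selection_rel`, default equal). The
   adaptive allele is thus effectively recessive within each habitat.
5. **Density regulation.** Each habitat independently keeps a uniform
   subsample of at most $K$ survivors.

A run lasts `generations` (3000) steps; an emptied habitat terminates the
run with an extinction flag.

## What is measured

* **Distance statistics.** Distance of a locus from the trait locus is its
  position index (the adjacent locus is at distance 1); this convention is
  declared once and used everywhere. Per individual, the positions of loci
  of one type (preference-for-AA, preference-for-A$'$A$'$, or neutral) are
  pooled over both chromosomes and averaged; individuals carrying none are
  excluded, and the per-individual means are averaged separately over AA
  and A$'$A$'$ phenotypes (heterozygotes are not part of the per-class
  statistics, and a pooled-type option exists). The *minimum* of the
  replicate-mean series over a run summarizes the strongest physical
  linkage attained. Under uniformly random placement the expected distance
  is $L/2 = 50$, which is what the neutral series tracks.
* **Assortative mating.** The proportion of mating pairs sharing a
  phenotype, all three classes counted (heterozygote pairs match).
* **Architecture fingerprints.** Position histograms of preference loci
  per chromosome class, and the mean count of preference loci per
  chromosome.
* **Sweep statistics.** Over the $s \in \{0.5,...,0.8\} \times pf \in
  \{0.3,...,2.4\}$ grid, the per-combination minimum mean distance feeds an
  OLS regression on $s$ and $pf$ (16 combination means, residual df 13;
  partial F-tests per predictor, interaction model with df 12), and
  replicate simulations at generation 700 feed Pearson correlations
  between distance and matching proportion (one observation per
  simulation, two-sided p from the t transform).

## The mutation-supply reading

The model's mutation supply can be quantified three ways: as a fixed count
of individuals (100 at the nominal population size of 10,000), as a
fraction of individuals (one percent), or as a per-locus rate
($5\times10^{-5}$ per generation). At the stage where mutation acts — the
offspring pool, roughly $2 \times 2K$ individuals — these are not all
compatible: a fixed 100 individuals there is only 0.5% of individuals and
a per-locus rate of $2.5\times10^{-5}$. Only the proportional reading (1%
of the individuals present, i.e. $0.01/(2L-2) = 5\times10^{-5}$ per locus
per generation) keeps the rate at its defining value, and it is also the reading under which the
model's benchmark timings of assortment build-up (the generations to 90%
matching pairs at weak and strong preference) are recovered by the
acceptance analyses. `magiclink` therefore defaults to
`mut_on_pool = TRUE` (the proportional reading); `mut_on_pool = FALSE`
provides the fixed-count anchoring to the nominal population
(`floor(mut_fraction * 2K)` = exactly 100 individuals at the defaults) for
comparison. Within `run_simulation()` the count is capped at the pool size
so a collapsing population ends as an extinction, not an error;
`mutate_offspring()` called directly is strict, as a guard against
misconfiguration.

## Numerical and design choices

* **Logistic stability.** Acceptance probabilities use a saturating
  logistic (`stats::plogis` in R, the equivalent guarded form in C++):
  $P_A + P_{A'} = 1$ holds to full precision and extreme $d \cdot pf$
  saturates to 0/1 rather than NaN.
* **Rejected males** return to the pool and may be redrawn, even by the
  same female — draws are with replacement across her pairings. The males
  a female meets are always drawn from the *currently* unmated pool, so
  early-choosing females deplete the pool for later ones.
* **Initialization** assigns each chromosome's trait allele A/A$'$ with
  probability 0.5, independently of habitat — the maximally mixed start —
  and all non-trait loci to the wild state. Wild is distinct from
  "neutral": neutral loci are explicit marker mutations accumulated over
  time, which is what makes them a proper null for the distance
  statistics.
* **Selection and culling** are independent Bernoulli draws and uniform
  subsampling respectively, not deterministic proportions; offspring sexes
  are fixed (2 + 2), not Bernoulli.
* **Ties and missing values.** The minimum of a distance series resolves
  ties to the earliest generation and skips missing entries; the
  90%-assortment generation is the first crossing, with no hysteresis;
  missing metrics are written as explicit `NA` sentinels in TSV output.
* **Seeding.** One R-level RNG stream drives everything, including the
  compiled engine; replicate $r$ of a set uses `base_seed + r`, and sweep
  combinations use disjoint seed blocks. Identical seeds give bit-identical
  trajectories.
* **Regression on combination means.** The sweep regression uses the 16
  per-combination means (not the raw replicate runs), so the main-effects
  model has residual df 13 and the interaction model df 12 — the
  granularity at which the sweep's F-tests are defined.

## Scaled-down problem sizes

The test suite and acceptance script keep the full population size
($K = 5000$, $L = 100$) but scale down the replication of the canonical
analyses: 5 replicates for timing and sweep checks (canonically 20), 30
simulations for the generation-700 correlation (same as the reference),
and a sweep horizon of 1500 generations rather than 3000. The distance
minimum falls during the assortment build-up, which is complete by roughly
generation 1300 at the slowest grid combination, and the post-minimum rise
is very slow, so the shortened horizon captures the minima; the long-run
behaviour (slow relaxation of linkage after assortment saturates) is
checked separately on full-length 3000-generation runs at $s = 0.5$,
$pf = 0.3$.

## What the simulations do and do not emulate

The generator *is* the study system: there is no external data. It
encodes the model's assumptions — two habitats with full
mixing during mate search, codominant single-locus magic trait, polygenic
preference with equal-effect alleles, monogamy, fixed brood size, hard
carrying capacity. It does not emulate spatial structure, restricted
migration, polygamous males, variable brood sizes, costs of choosiness
beyond the pairing cap, chromosomal rearrangements or recombination-rate
modifiers, or the two-trait-locus variant; several of these exist as
parameter hooks (`het_mate_prob`, `het_selection_rel`, `n_crossovers`,
`max_pairings`) but are not shipped as experiments. Conclusions from
passing tests therefore concern the model world, not any particular
empirical system.

Occasional replicate extinction at the weak end of the selection grid is
expected behaviour, not a bug: with $s$ at the edge of the
stable-coexistence range, a frequency asymmetry between the homozygotes
can self-amplify through the mating market until one phenotype collapses.
Replicate sets exclude extinct runs from their means and say so in a
warning.

## Known limitations

* The per-generation metrics record the population *after* density
  regulation together with the mating record of the pairing that produced
  it; analyses that need other intermediate states should use the
  per-stage functions directly.
* At small population sizes the discreteness of `floor(mut_fraction * n)`
  makes the realized mutation supply step-shaped; the tests use explicit
  `mut_fraction` values chosen to avoid zero-mutation regimes.
* The preference-locus count per chromosome keeps rising slowly long after
  assortment saturates; statistics quoted "at generation $g$" are
  snapshots of a moving quantity and are sensitive to the exact timing of
  the assortment build-up.
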