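# Population-level statistics. All functions here are pure: they consume a
# population (or mating record) and never touch the RNG, so they can be
# applied to live populations, snapshots, or reloaded snapshot files alike.
# Distance of a locus from the trait locus = its position index (the locus
# adjacent to the trait locus is at distance 1, the last at L - 1).

pref_code <- function(pref_type) {
  cc <- allele_codes()
  switch(match.arg(pref_type, c("pref_a", "pref_aprime", "neutral")),
         pref_a = cc$PREF_A, pref_aprime = cc$PREF_APRIME,
         neutral = cc$NEUTRAL)
}

#' Average distance of preference (or neutral) loci from the trait locus
#'
#' For each individual of the given phenotype class, the positions of all
#' loci holding `pref_type` are pooled over both chromosomes and averaged;
#' individuals carrying no such locus are excluded. The returned value is
#' the mean of these per-individual averages — the statistic whose minimum
#' over a run measures the strength of physical linkage.
#'
#' @param pop A `sim_population`.
#' @param pref_type One of `"pref_a"`, `"pref_aprime"`, `"neutral"`, or
#'   `"pref_both"` to pool the two preference types into one per-individual
#'   average.
#' @param phenotype_class `"AA"` or `"AprimeAprime"` (heterozygotes are not
#'   part of the per-class statistics), or `"all"` to pool every individual.
#' @return Mean distance in locus units (`1` to `L - 1`), or `NA` if no
#'   individual of the class carries such a locus.
#' @export
#' @examples
#' pop <- initialize_population(model_params(K = 4, L = 10))
#' avg_pref_distance(pop, "pref_a", "AA")  # NA: no preference loci yet
avg_pref_distance <- function(pop, pref_type = "pref_a",
                              phenotype_class = c("AA", "AprimeAprime", "all")) {
  phenotype_class <- match.arg(phenotype_class)
  pref_type <- match.arg(pref_type,
                         c("pref_a", "pref_aprime", "neutral", "pref_both"))
  cc <- allele_codes()
  keep <- if (phenotype_class == "all") rep(TRUE, nrow(pop$chrom1))
          else phenotypes(pop) == phenotype_class
  if (!any(keep)) return(NA_real_)
  b1 <- pop$chrom1[keep, -1, drop = FALSE]
  b2 <- pop$chrom2[keep, -1, drop = FALSE]
  if (pref_type == "pref_both") {
    g1 <- b1 == cc$PREF_A | b1 == cc$PREF_APRIME
    g2 <- b2 == cc$PREF_A | b2 == cc$PREF_APRIME
  } else {
    code <- pref_code(pref_type)
    g1 <- b1 == code
    g2 <- b2 == code
  }
  posn <- seq_len(ncol(g1))  # column j is position j
  sums <- as.vector(g1 %*% posn + g2 %*% posn)
  cnts <- rowSums(g1) + rowSums(g2)
  ok <- cnts > 0
  if (!any(ok)) return(NA_real_)
  mean(sums[ok] / cnts[ok])
}

#' Proportion of phenotypically matching mating pairs
#'
#' Fraction of realized pairs in which female and male share the same
#' trait-locus phenotype (all three phenotype classes count, including
#' heterozygote x heterozygote). This is the assortative-mating measure.
#'
#' @param record A `mating_record` from [form_mating_pairs()] or
#'   [step_generation()].
#' @return Proportion in `[0, 1]`, or `NA` for an empty record.
#' @export
matching_pair_proportion <- function(record) {
  if (nrow(record) == 0L) return(NA_real_)
  mean(record$female_phenotype == record$male_phenotype)
}

#' Histogram of preference-locus positions
#'
#' Counts, at every non-trait position, the chromosomes holding a
#' preference allele — separately for chromosomes whose trait allele is A
#' vs A', and for the two preference types. This is the architecture
#' fingerprint recorded at a chosen generation (1000 in the reference
#' analyses): with recombination, counts pile up adjacent to the trait
#' locus; without, they scatter.
#'
#' @param pop A `sim_population`.
#' @return Data frame with columns `chrom_class` (`"A"`/`"Aprime"`),
#'   `pref_type` (`"pref_a"`/`"pref_aprime"`), `position` (1..L-1), `count`.
#' @export
position_histogram <- function(pop) {
  cc <- allele_codes()
  L <- ncol(pop$chrom1)
  # stack the two homologs: each row is one chromosome
  chroms <- rbind(pop$chrom1, pop$chrom2)
  cls <- ifelse(chroms[, 1] == cc$A, "A", "Aprime")
  out <- expand.grid(position = seq_len(L - 1L),
                     pref_type = c("pref_a", "pref_aprime"),
                     chrom_class = c("A", "Aprime"),
                     stringsAsFactors = FALSE)[, 3:1]
  out$count <- 0L
  body <- chroms[, -1, drop = FALSE]
  k <- 1L
  for (ccls in c("A", "Aprime")) {
    sub <- body[cls == ccls, , drop = FALSE]
    for (tp in c("pref_a", "pref_aprime")) {
      cnt <- colSums(sub == pref_code(tp))
      out$count[seq.int(k, k + L - 2L)] <- as.integer(cnt)
      k <- k + L - 1L
    }
  }
  out
}

#' Mean number of preference loci per chromosome
#'
#' Total count of loci holding either preference type, over all `2N`
#' chromosomes in the population, divided by the chromosome count.
#'
#' @param pop A `sim_population`.
#' @return Non-negative real.
#' @export
mean_pref_loci_per_chromosome <- function(pop) {
  cc <- allele_codes()
  body1 <- pop$chrom1[, -1, drop = FALSE]
  body2 <- pop$chrom2[, -1, drop = FALSE]
  n_pref <- sum(body1 == cc$PREF_A | body1 == cc$PREF_APRIME) +
            sum(body2 == cc$PREF_A | body2 == cc$PREF_APRIME)
  n_pref / (2 * nrow(pop$chrom1))
}

#' One row of per-generation metrics from a population
#'
#' Recomputes, in R, the same summary row that [run_simulation()] records
#' each generation: habitat sizes, phenotype frequencies, the six
#' class-by-type mean distances, matching-pair proportion (from `record`,
#' if given) and mean preference loci per chromosome.
#'
#' @param pop A `sim_population`.
#' @param record Optional `mating_record` for the generation.
#' @param n_mutations Mutation event count for the generation (default `NA`).
#' @return One-row data frame matching the `metrics` columns of a
#'   [run_simulation()] result.
#' @export
generation_metrics <- function(pop, record = NULL, n_mutations = NA_integer_) {
  ph <- factor(phenotypes(pop), levels = PHENOTYPE_LEVELS)
  tab <- as.numeric(table(ph)) / max(1L, length(ph))
  data.frame(
    generation = pop$generation,
    n_h1 = sum(pop$habitat == 1L),
    n_h2 = sum(pop$habitat == 2L),
    n_pairs = if (is.null(record)) 0L else nrow(record),
    match_prop = if (is.null(record)) NA_real_
                 else matching_pair_proportion(record),
    freq_AA = tab[1], freq_AAprime = tab[2], freq_AprimeAprime = tab[3],
    dist_prefA_AA = avg_pref_distance(pop, "pref_a", "AA"),
    dist_prefAp_AA = avg_pref_distance(pop, "pref_aprime", "AA"),
    dist_neutral_AA = avg_pref_distance(pop, "neutral", "AA"),
    dist_prefA_ApAp = avg_pref_distance(pop, "pref_a", "AprimeAprime"),
    dist_prefAp_ApAp = avg_pref_distance(pop, "pref_aprime", "AprimeAprime"),
    dist_neutral_ApAp = avg_pref_distance(pop, "neutral", "AprimeAprime"),
    mean_pref_per_chrom = mean_pref_loci_per_chromosome(pop),
    n_mutations = n_mutations)
}
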