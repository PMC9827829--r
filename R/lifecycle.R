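#' Female preference score
#'
#' The score `d` is the number of preference-for-AA alleles minus the number
#' of preference-for-A'A' alleles carried over both chromosomes (trait locus
#' excluded). Positive `d` biases acceptance towards AA males, negative
#' towards A'A' males. Range: `-2(L-1)` to `2(L-1)`.
#'
#' @param pop A `sim_population`.
#' @param i Optional indices of individuals (default: all). The score is
#'   defined for any individual; only females use it when choosing.
#' @return Integer vector of scores.
#' @export
#' @examples
#' pop <- initialize_population(model_params(K = 4, L = 10))
#' preference_score(pop)  # all zero: no preference alleles yet
preference_score <- function(pop, i = seq_len(nrow(pop$chrom1))) {
  cc <- allele_codes()
  g1 <- pop$chrom1[i, -1, drop = FALSE]
  g2 <- pop$chrom2[i, -1, drop = FALSE]
  as.integer(rowSums(g1 == cc$PREF_A) + rowSums(g2 == cc$PREF_A) -
             rowSums(g1 == cc$PREF_APRIME) - rowSums(g2 == cc$PREF_APRIME))
}

#' Mate-acceptance probability
#'
#' Logistic female choice: the probability that a female with preference
#' score `d` accepts an AA male is `1 / (1 + exp(-d * pf))`; the probability
#' of accepting an A'A' male is its complement; heterozygote (AA') males are
#' accepted with the constant `het_mate_prob`, independent of `d`. The
#' implementation uses [stats::plogis()] and is saturating-stable for large
#' `|d * pf|` (never NaN).
#'
#' @param d Integer preference score(s).
#' @param pf Preference strength factor (>= 0).
#' @param male_phenotype `"AA"`, `"AAprime"` or `"AprimeAprime"` (recycled).
#' @param het_mate_prob Acceptance probability for heterozygote males
#'   (default 0.5).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' mate_probability(0, 2.4, "AA")            # 0.5
#' mate_probability(1, 2.4, "AA")            # ~0.917
#' mate_probability(5, 2.4, "AAprime")       # 0.5 regardless of d
mate_probability <- function(d, pf, male_phenotype,
                             het_mate_prob = 0.5) {
  stopifnot(pf >= 0)
  male_phenotype <- match.arg(male_phenotype, PHENOTYPE_LEVELS,
                              several.ok = TRUE)
  n <- max(length(d), length(male_phenotype))
  d <- rep_len(d, n)
  male_phenotype <- rep_len(male_phenotype, n)
  pA <- plogis(d * pf)
  out <- ifelse(male_phenotype == "AA", pA,
                ifelse(male_phenotype == "AprimeAprime", 1 - pA,
                       het_mate_prob))
  as.numeric(out)
}

new_mating_record <- function(female, male, female_phenotype, male_phenotype) {
  structure(data.frame(female = as.integer(female), male = as.integer(male),
                       female_phenotype = female_phenotype,
                       male_phenotype = male_phenotype,
                       stringsAsFactors = FALSE),
            class = c("mating_record", "data.frame"))
}

#' Form mating pairs for one generation
#'
#' Females are processed in a fresh uniformly random order. Each female is
#' sequentially paired with up to `max_pairings` males drawn uniformly (with
#' replacement across her pairings) from the currently unmated male pool of
#' both habitats — males move freely while searching for mates. She accepts
#' each with [mate_probability()]; on acceptance both leave the pool
#' (monogamy). A female who exhausts her pairings, or faces an empty pool,
#' does not reproduce.
#'
#' @param pop A `sim_population` (needs >= 1 female and >= 1 male to produce
#'   any pairs; degenerate pools give an empty record).
#' @param params A [model_params()] object.
#' @return A `mating_record`: data frame with columns `female`, `male`
#'   (row indices into `pop`), `female_phenotype`, `male_phenotype`.
#' @export
form_mating_pairs <- function(pop, params) {
  stopifnot(inherits(pop, "sim_population"), inherits(params, "model_params"))
  pr <- cpp_form_pairs(unclass(pop), unclass(params))
  new_mating_record(pr$female, pr$male,
                    phenotypes(pop, pr$female), phenotypes(pop, pr$male))
}

#' Produce the offspring pool from a mating record
#'
#' Each pair produces `n_offspring` offspring, half female and half male
#' (2 + 2 at the default). Every offspring independently receives one
#' uniformly chosen chromosome from its mother and one from its father, and
#' is placed in its mother's habitat. The returned pool replaces the parent
#' generation (generations do not overlap).
#'
#' @param pop Parent `sim_population`.
#' @param record A `mating_record` from [form_mating_pairs()].
#' @param params A [model_params()] object.
#' @return Offspring `sim_population` (generation counter unchanged; it is
#'   advanced by [step_generation()]).
#' @export
reproduce <- function(pop, record, params) {
  stopifnot(inherits(pop, "sim_population"))
  out <- cpp_reproduce(unclass(pop), record$female, record$male,
                       unclass(params))
  out
}

#' Recombine offspring chromosomes
#'
#' For each offspring, `n_crossovers` cut points are drawn uniformly from
#' the `L - 1` inter-locus gaps and the allele content strictly after each
#' cut is exchanged between the two homologs. The per-locus allele multiset
#' of the individual is unchanged — recombination affects only the gametes
#' the offspring will later transmit, never its own genotype or preference
#' score. `n_crossovers = 0` is the no-recombination control and leaves the
#' population untouched.
#'
#' @inheritParams reproduce
#' @return The recombined `sim_population`.
#' @export
recombine_offspring <- function(pop, params) {
  cpp_recombine(unclass(pop), unclass(params))
}

#' Mutate offspring
#'
#' A `mut_fraction` share of the pool — `floor(mut_fraction * n)`
#' individuals for a pool of size `n` at the default `mut_on_pool = TRUE`,
#' or the fixed `floor(mut_fraction * 2K)` when anchored to the nominal
#' population — is drawn without replacement; each receives exactly one
#' mutation at a uniformly chosen non-trait position on a uniformly chosen
#' homolog. The new state is uniform over preference-for-AA,
#' preference-for-A'A' and neutral, and overwrites the previous state, so
#' repeat hits and back mutations are possible. The trait locus is never
#' mutated.
#'
#' @inheritParams reproduce
#' @param strict If `TRUE` (default), error when the mutation count exceeds
#'   the pool size; [run_simulation()] instead caps the count so a
#'   collapsing population does not abort a run.
#' @return The mutated `sim_population`, with the realized event count in
#'   attribute `"n_mutations"`.
#' @export
mutate_offspring <- function(pop, params, strict = TRUE) {
  out <- cpp_mutate(unclass(pop), unclass(params), strict)
  structure(out$population, n_mutations = out$n_mutations)
}

#' Apply divergent ecological selection
#'
#' AA individuals in habitat 1 and A'A' individuals in habitat 2 always
#' survive. Every other habitat/phenotype combination dies independently
#' with probability `s` (heterozygotes with `s * het_selection_rel`). The
#' adaptive allele is thus effectively recessive within each habitat.
#'
#' @inheritParams reproduce
#' @return The surviving `sim_population`.
#' @export
apply_selection <- function(pop, params) {
  cpp_apply_selection(unclass(pop), unclass(params))
}

#' Density-dependent regulation
#'
#' Each habitat independently supports at most `K` individuals: when
#' survivors exceed `K`, a uniform random subsample of exactly `K` is kept;
#' otherwise all survive.
#'
#' @inheritParams reproduce
#' @return The regulated `sim_population`.
#' @export
regulate_density <- function(pop, params) {
  cpp_regulate(unclass(pop), unclass(params))
}

#' Advance the population by one generation
#'
#' Composes the five life-cycle stages in their fixed order — pair
#' formation, reproduction, recombination, mutation, ecological selection,
#' density regulation — and advances the generation counter. Parents never
#' persist into the next generation.
#'
#' @inheritParams reproduce
#' @return List with elements `population` (the new generation), `record`
#'   (the `mating_record` of the realized matings, phenotypes taken from the
#'   parents), `match_prop` (proportion of phenotypically matching pairs,
#'   `NA` if no pairs formed) and `n_mutations`.
#' @export
#' @examples
#' p <- model_params(K = 50, L = 20, generations = 1)
#' set.seed(1)
#' pop <- initialize_population(p)
#' nxt <- step_generation(pop, p)
#' nxt$population$generation
step_generation <- function(pop, params) {
  stopifnot(inherits(pop, "sim_population"), inherits(params, "model_params"))
  st <- cpp_step(unclass(pop), unclass(params))
  rec <- new_mating_record(st$female, st$male,
                           PHENOTYPE_LEVELS[st$female_phenotype + 1L],
                           PHENOTYPE_LEVELS[st$male_phenotype + 1L])
  list(population = st$population, record = rec,
       match_prop = st$match_prop, n_mutations = st$n_mutations)
}

#' Run a full simulation
#'
#' Initializes a population and advances it `params$generations` steps,
#' recording the complete per-generation metrics series (see
#' [generation_metrics()] for column definitions). If either habitat
#' empties, the run stops and is flagged extinct at that generation.
#'
#' @param params A [model_params()] object.
#' @param snapshot_generations Integer vector of generations at which to
#'   keep a full population snapshot (e.g. `c(700, 1000)`).
#' @param seed Integer seed; defaults to `params$seed`. If `NULL`, the
#'   current RNG state is used as-is.
#' @param keep_final Keep the final population in the result (default TRUE).
#' @return A `"sim_run"`: list with `metrics` (data frame, one row per
#'   generation 0..T), `snapshots` (named list of `sim_population`s),
#'   `final` population, `params`, `seed`, `extinct`, `extinct_generation`.
#' @export
#' @examples
#' run <- run_simulation(model_params(K = 50, L = 20, generations = 5, seed = 1))
#' run$metrics$match_prop
run_simulation <- function(params, snapshot_generations = integer(0),
                           seed = params$seed, keep_final = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  pop <- initialize_population(params)
  raw <- cpp_run(unclass(pop), unclass(params), params$generations,
                 as.integer(snapshot_generations), keep_final)
  metrics <- as.data.frame(raw$metrics)
  res <- list(metrics = metrics, snapshots = raw$snapshots,
              final = raw$final, params = params,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              extinct = raw$extinct,
              extinct_generation = raw$extinct_generation)
  class(res) <- "sim_run"
  res
}

#' @export
print.sim_run <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("sim_run: s = %g, pf = %g, %d generations%s\n",
              x$params$s, x$params$pf, nrow(x$metrics) - 1L,
              if (isTRUE(x$extinct))
                sprintf(" (EXTINCT at %d)", x$extinct_generation) else ""))
  cat(sprintf("  final: %d + %d individuals, matching-pair proportion %.3f\n",
              last$n_h1, last$n_h2, last$match_prop))
  invisible(x)
}
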