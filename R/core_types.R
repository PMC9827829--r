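#' Integer allele codes used in chromosome matrices
#'
#' Chromosomes are stored as integer matrices with one row per individual and
#' one column per locus. Position 1 (index 0 in distance terms) is the
#' ecological trait locus and holds `A` (1) or `APRIME` (2). All other
#' positions hold one of `WILD` (0, the untouched starting state), `PREF_A`
#' (1, preference for AA mates), `PREF_APRIME` (2, preference for A'A'
#' mates) or `NEUTRAL` (3, a marker mutation with no effect, used as the
#' null for the distance statistics). The trait-locus and non-trait
#' alphabets are disjoint by position, so the numeric overlap is harmless.
#'
#' @return Named list of integer codes.
#' @export
#' @examples
#' allele_codes()$PREF_A
allele_codes <- function() {
  list(A = 1L, APRIME = 2L,
       WILD = 0L, PREF_A = 1L, PREF_APRIME = 2L, NEUTRAL = 3L)
}

# sex codes: 0 = female, 1 = male; habitat codes: 1 = H1, 2 = H2
SEX_FEMALE <- 0L
SEX_MALE <- 1L

PHENOTYPE_LEVELS <- c("AA", "AAprime", "AprimeAprime")

#' Model parameters
#'
#' Constructs and validates the full parameter set of the model. Defaults
#' are the study conditions of the underlying model: 2K = 10,000 diploid
#' individuals on a single pair of homologous chromosomes of `L = 100` loci,
#' run for 3000 non-overlapping generations.
#'
#' @param s Selection coefficient: per-generation death probability of an
#'   individual whose phenotype is maladapted in its habitat (AA is favoured
#'   in habitat 1, A'A' in habitat 2, every other combination is maladapted).
#'   Must lie in `[0, 1]`; stable coexistence of the two homozygotes holds
#'   roughly for `s` in 0.5–0.8.
#' @param pf Preference strength factor: slope of the logistic acceptance
#'   function; each extra matching preference allele multiplies the odds of
#'   acceptance by `exp(pf)`. Must be >= 0 (`pf = 0` gives random mating).
#' @param K Carrying capacity per habitat (default 5000). Must be even so the
#'   initial population can hold `K/2` of each sex per habitat.
#' @param L Number of loci per chromosome (default 100), trait locus included.
#' @param mut_fraction Fraction of individuals receiving one mutation per
#'   generation (default 0.01, "one percent of individuals"). Applied to the
#'   realized offspring pool when `mut_on_pool = TRUE` (the default), giving
#'   a per-locus mutation rate of `mut_fraction / (2L - 2)` (5e-5 at the
#'   defaults) irrespective of pool size.
#' @param max_pairings Maximum number of males a female is sequentially
#'   paired with before she forgoes reproduction (default 10).
#' @param n_offspring Offspring per mating pair (default 4), half of each
#'   sex; must be even.
#' @param n_crossovers Crossovers per offspring (default 1); 0 disables
#'   recombination (the control condition).
#' @param het_mate_prob Acceptance probability for a heterozygote (AA')
#'   male, a constant independent of the female's preferences (default 0.5).
#' @param het_selection_rel Selection strength against heterozygotes relative
#'   to maladapted homozygotes (default 1: equally maladaptive).
#' @param generations Number of generations to simulate (default 3000).
#' @param seed Optional integer seed; used by [run_simulation()].
#' @param mut_on_pool If `TRUE` (default), the mutated-individual count is
#'   `mut_fraction` of the realized offspring pool (~`2 * n_offspring * K /
#'   2` individuals), which keeps the per-locus mutation rate constant. If
#'   `FALSE`, it is anchored to the nominal population: exactly
#'   `floor(mut_fraction * 2K)` individuals (100 at the defaults) no matter
#'   how large the pool at the mutation stage is. See the methods vignette
#'   for why the pool-proportional reading is the default.
#'
#' @return A validated list of class `"model_params"`.
#' @export
#' @examples
#' p <- model_params(s = 0.5, pf = 0.3)
#' p$K
model_params <- function(s = 0.5, pf = 0.3, K = 5000L, L = 100L,
                         mut_fraction = 0.01, max_pairings = 10L,
                         n_offspring = 4L, n_crossovers = 1L,
                         het_mate_prob = 0.5, het_selection_rel = 1,
                         generations = 3000L, seed = NULL,
                         mut_on_pool = TRUE) {
  p <- list(s = as.numeric(s), pf = as.numeric(pf), K = as.integer(K),
            L = as.integer(L), mut_fraction = as.numeric(mut_fraction),
            max_pairings = as.integer(max_pairings),
            n_offspring = as.integer(n_offspring),
            n_crossovers = as.integer(n_crossovers),
            het_mate_prob = as.numeric(het_mate_prob),
            het_selection_rel = as.numeric(het_selection_rel),
            generations = as.integer(generations),
            seed = if (is.null(seed)) NULL else as.integer(seed),
            mut_on_pool = isTRUE(mut_on_pool))
  validate_params(p)
}

validate_params <- function(p) {
  stopif <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stopif(is.na(p$s) || p$s < 0 || p$s > 1, "`s` must be in [0, 1]")
  stopif(is.na(p$pf) || p$pf < 0, "`pf` must be >= 0")
  stopif(is.na(p$K) || p$K < 2, "`K` must be >= 2")
  stopif(p$K %% 2L != 0L, "`K` must be even (K/2 of each sex per habitat)")
  stopif(is.na(p$L) || p$L < 2, "`L` must be >= 2")
  stopif(p$mut_fraction < 0 || p$mut_fraction > 1,
         "`mut_fraction` must be in [0, 1]")
  stopif(p$max_pairings < 1, "`max_pairings` must be >= 1")
  stopif(p$n_offspring < 2 || p$n_offspring %% 2L != 0L,
         "`n_offspring` must be an even integer >= 2")
  stopif(p$n_crossovers < 0, "`n_crossovers` must be >= 0")
  stopif(p$het_mate_prob < 0 || p$het_mate_prob > 1,
         "`het_mate_prob` must be in [0, 1]")
  stopif(p$het_selection_rel < 0, "`het_selection_rel` must be >= 0")
  stopif(p$s * p$het_selection_rel > 1,
         "`s * het_selection_rel` must not exceed 1")
  stopif(p$generations < 0, "`generations` must be >= 0")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  flds <- setdiff(names(x), "seed")
  for (f in flds) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  cat(sprintf("  %-18s %s\n", "seed",
              if (is.null(x$seed)) "(none)" else x$seed))
  invisible(x)
}

#' Initialize a population
#'
#' Creates the generation-0 population: `K` individuals per habitat, exactly
#' `K/2` of each sex, every chromosome drawing its trait allele A or A'
#' independently with probability 0.5 (the maximally mixed start: trait
#' alleles are uncorrelated with habitat), and every non-trait locus in the
#' wild (mutation-free) state.
#'
#' @param params A [model_params()] object.
#' @return A `"sim_population"`: list with integer matrices `chrom1`,
#'   `chrom2` (individuals x loci), integer vectors `sex` (0 = female,
#'   1 = male) and `habitat` (1 or 2), and a `generation` counter.
#' @export
#' @examples
#' pop <- initialize_population(model_params(K = 10, L = 10))
#' nrow(pop$chrom1)  # 2K = 20
initialize_population <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- 2L * params$K
  L <- params$L
  c1 <- matrix(0L, n, L)
  c2 <- matrix(0L, n, L)
  c1[, 1] <- sample(c(1L, 2L), n, replace = TRUE)
  c2[, 1] <- sample(c(1L, 2L), n, replace = TRUE)
  pop <- list(chrom1 = c1, chrom2 = c2,
              sex = rep(rep(c(SEX_FEMALE, SEX_MALE), each = params$K %/% 2L), 2L),
              habitat = rep(c(1L, 2L), each = params$K),
              generation = 0L)
  class(pop) <- "sim_population"
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  ph <- table(factor(phenotypes(x), levels = PHENOTYPE_LEVELS))
  cat(sprintf("sim_population: %d individuals, L = %d, generation %d\n",
              nrow(x$chrom1), ncol(x$chrom1), x$generation))
  cat(sprintf("  habitat 1: %d, habitat 2: %d\n",
              sum(x$habitat == 1L), sum(x$habitat == 2L)))
  cat("  phenotypes:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Trait-locus phenotypes of a population
#'
#' The ecological trait alleles are codominant: the three diploid genotypes
#' map to three phenotypes. The mapping is symmetric in the two homologs,
#' so (A, A') and (A', A) both give the heterozygote phenotype.
#'
#' @param pop A `sim_population`.
#' @param i Optional indices of individuals (default: all).
#' @return Character vector with values `"AA"`, `"AAprime"`,
#'   `"AprimeAprime"`.
#' @export
#' @examples
#' pop <- initialize_population(model_params(K = 4, L = 2))
#' phenotypes(pop)
phenotypes <- function(pop, i = seq_len(nrow(pop$chrom1))) {
  a <- pop$chrom1[i, 1]
  b <- pop$chrom2[i, 1]
  PHENOTYPE_LEVELS[ifelse(a == b, ifelse(a == 1L, 1L, 3L), 2L)]
}

#' Number of individuals in a population
#' @param pop A `sim_population`.
#' @return Integer count.
#' @export
population_size <- function(pop) nrow(pop$chrom1)
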