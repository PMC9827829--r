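test_that("preference score counts matching minus opposing alleles", {
  # all-wild genome scores 0
  pop <- initialize_population(tiny_params())
  expect_true(all(preference_score(pop) == 0L))
  # 3 pref-A on chrom1, 1 pref-A' on chrom2 -> d = 2
  c1 <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), 1, 6)
  c2 <- matrix(c(1L, 2L, 0L, 0L, 0L, 0L), 1, 6)
  pop1 <- make_pop(c1, c2, sex = 0L, habitat = 1L)
  expect_equal(preference_score(pop1), 2L)
})

test_that("preference score equals an exhaustive per-locus tally", {
  set.seed(42)
  for (rep in 1:5) {
    pop <- random_pop(n = 20, L = 15, p_mut = 0.4)
    d <- preference_score(pop)
    for (i in seq_len(20))
      expect_identical(d[i], oracle_pref_score(pop, i))
  }
})

test_that("mate probability follows the logistic preference function", {
  # d = 0 is indifference, for any pf
  expect_equal(mate_probability(0, 2.4, "AA"), 0.5)
  expect_equal(mate_probability(0, 0.3, "AprimeAprime"), 0.5)
  # one extra matching allele at pf = 2.4 pushes acceptance above 0.9
  expect_equal(mate_probability(1, 2.4, "AA"), 1 / (1 + exp(-2.4)))
  expect_gt(mate_probability(1, 2.4, "AA"), 0.9)
  # independent evaluation of the logistic expression
  expect_equal(mate_probability(-3, 0.3, "AA"), 1 / (1 + exp(0.9)))
  # heterozygote males: constant acceptance, independent of d
  for (d in c(-5, 0, 5))
    expect_equal(mate_probability(d, 2.4, "AAprime"), 0.5)
  expect_equal(mate_probability(3, 1, "AAprime", het_mate_prob = 0.7), 0.7)
})

test_that("acceptance probabilities for the two homozygotes sum to one and saturate stably", {
  for (pf in c(0, 0.3, 2.4, 50)) {
    d <- -6:6
    pA <- mate_probability(d, pf, "AA")
    pAp <- mate_probability(d, pf, "AprimeAprime")
    expect_equal(pA + pAp, rep(1, length(d)))
    expect_true(all(diff(pA) >= 0))
    expect_equal(pA, rev(pAp))  # P_A(d) = P_A'(-d)
  }
  expect_equal(mate_probability(2000, 50, "AA"), 1)
  expect_equal(mate_probability(-2000, 50, "AA"), 0)
  expect_false(any(is.nan(mate_probability(c(-1e6, 1e6), 100, "AA"))))
})

test_that("indifferent females mate like geometric trials with p = 0.5", {
  # 300 indifferent females, abundant AA males: per-pairing acceptance is
  # 0.5, so ~1 - 0.5^10 of females should mate within 10 pairings, and
  # ~0.5 should mate when only one pairing is allowed
  n_f <- 300L; n_m <- 5000L; n <- n_f + n_m
  c1 <- matrix(0L, n, 2); c2 <- matrix(0L, n, 2)
  c1[, 1] <- 1L; c2[, 1] <- 1L                     # everyone AA, wild elsewhere
  pop <- make_pop(c1, c2, sex = rep(c(0L, 1L), c(n_f, n_m)),
                  habitat = rep(1L, n))
  p <- model_params(K = 10000, L = 2, max_pairings = 10)
  set.seed(8)
  rec <- form_mating_pairs(pop, p)
  expect_gt(nrow(rec), n_f * (1 - 0.5^10) - 4 * sqrt(n_f * 0.25))
  p1 <- model_params(K = 10000, L = 2, max_pairings = 1)
  set.seed(9)
  rec1 <- form_mating_pairs(pop, p1)
  expect_lt(abs(nrow(rec1) / n_f - 0.5), 4 * sqrt(0.25 / n_f))
})

test_that("a saturated preference gives first-pairing acceptance; empty pools give empty records", {
  n_f <- 50L; n_m <- 50L; n <- n_f + n_m
  c1 <- matrix(0L, n, 3); c2 <- matrix(0L, n, 3)
  c1[, 1] <- 1L; c2[, 1] <- 1L                     # everyone AA
  c1[seq_len(n_f), 2] <- 1L  # each female carries one pref-A allele: d = 1
  pop <- make_pop(c1, c2, sex = rep(c(0L, 1L), c(n_f, n_m)),
                  habitat = rep(1L, n))
  p <- model_params(K = 100, L = 3, pf = 50, max_pairings = 1)
  set.seed(2)
  rec <- form_mating_pairs(pop, p)
  expect_equal(nrow(rec), n_f)      # every female mates despite 1 pairing
  expect_true(!anyDuplicated(rec$male))  # monogamy
  # 1 female, 0 males
  lone <- make_pop(matrix(1L, 1, 3), matrix(1L, 1, 3), sex = 0L, habitat = 1L)
  expect_equal(nrow(form_mating_pairs(lone, p)), 0L)
})

test_that("reproduction gives fixed brood size and sexes, Mendelian inheritance, maternal habitat", {
  # AA mother x A'A' father: every offspring is a trait heterozygote
  pop <- make_pop(matrix(c(1L, 2L), 2, 4), matrix(c(1L, 2L), 2, 4),
                  sex = c(0L, 1L), habitat = c(2L, 1L))
  p <- model_params(K = 10, L = 4)
  rec <- new_mating_record(1L, 2L, "AA", "AprimeAprime")
  set.seed(1)
  off <- reproduce(pop, rec, p)
  expect_equal(population_size(off), 4L)
  expect_equal(sum(off$sex == 0L), 2L)
  expect_equal(sum(off$sex == 1L), 2L)
  expect_true(all(phenotypes(off) == "AAprime"))
  expect_true(all(off$habitat == 2L))  # mother's habitat
  # het x het broods segregate ~1:2:1
  n_pairs <- 400L
  n <- 2L * n_pairs
  c1 <- matrix(1L, n, 2); c2 <- matrix(2L, n, 2)  # all heterozygotes
  poph <- make_pop(c1, c2, sex = rep(c(0L, 1L), each = n_pairs),
                   habitat = rep(1L, n))
  rech <- new_mating_record(seq_len(n_pairs), n_pairs + seq_len(n_pairs),
                            rep("AAprime", n_pairs), rep("AAprime", n_pairs))
  set.seed(4)
  offh <- reproduce(poph, rech, p)
  expect_equal(population_size(offh), 4L * n_pairs)
  frq <- table(factor(phenotypes(offh),
                      levels = c("AA", "AAprime", "AprimeAprime"))) /
         population_size(offh)
  tol <- 4 * sqrt(0.25 / population_size(offh))
  expect_lt(abs(frq[[1]] - 0.25), tol)
  expect_lt(abs(frq[[2]] - 0.50), tol * 2)
  expect_lt(abs(frq[[3]] - 0.25), tol)
})

test_that("recombination swaps the tail after the cut and conserves per-locus allele pairs", {
  # L = 2: the only possible cut is after the trait locus
  pop <- make_pop(matrix(c(1L, 1L), 1, 2), matrix(c(2L, 3L), 1, 2),
                  sex = 0L, habitat = 1L)
  p <- model_params(K = 2, L = 2)
  set.seed(1)
  out <- recombine_offspring(pop, p)
  expect_equal(out$chrom1[1, ], c(1L, 3L))
  expect_equal(out$chrom2[1, ], c(2L, 1L))
  # multiset conservation and preference-score invariance on random genomes
  set.seed(99)
  pop <- random_pop(n = 1000, L = 12, p_mut = 0.3)
  for (nc in c(1L, 2L, 3L)) {
    pnc <- model_params(K = 1000, L = 12, n_crossovers = nc)
    out <- recombine_offspring(pop, pnc)
    expect_identical(locus_multisets(out), locus_multisets(pop))
    expect_identical(preference_score(out), preference_score(pop))
    expect_identical(phenotypes(out), phenotypes(pop))
  }
  # n_crossovers = 0 is the untouched control
  p0 <- model_params(K = 1000, L = 12, n_crossovers = 0)
  expect_identical(recombine_offspring(pop, p0), pop)
})

test_that("mutation hits the configured number of individuals, once each, never the trait locus", {
  set.seed(21)
  pop <- initialize_population(model_params(K = 20, L = 10))
  p <- model_params(K = 20, L = 10, mut_fraction = 0.1)  # floor(0.1*40) = 4
  out <- mutate_offspring(pop, p)
  expect_equal(attr(out, "n_mutations"), 4L)
  changed <- rowSums(out$chrom1 != pop$chrom1) +
             rowSums(out$chrom2 != pop$chrom2)
  expect_equal(sum(changed > 0), 4L)       # exactly 4 individuals
  expect_true(all(changed <= 1))           # one locus each
  expect_identical(out$chrom1[, 1], pop$chrom1[, 1])  # trait locus untouched
  expect_identical(out$chrom2[, 1], pop$chrom2[, 1])
  expect_true(all(c(out$chrom1[, -1], out$chrom2[, -1]) %in% 0:3))
  # nominal anchoring: fixed count regardless of pool size
  pnom <- model_params(K = 20, L = 10, mut_fraction = 0.1, mut_on_pool = FALSE)
  outn <- mutate_offspring(pop, pnom)
  expect_equal(attr(outn, "n_mutations"), 4L)  # floor(0.1 * 2K)
  # requesting more mutants than the pool holds errors (strict mode)
  pbig <- model_params(K = 100, L = 10, mut_fraction = 0.5,
                       mut_on_pool = FALSE)    # wants 100 of a pool of 40
  expect_error(mutate_offspring(pop, pbig), "exceeds")
  # ... but the capped mode mutates everyone at most
  capped <- mutate_offspring(pop, pbig, strict = FALSE)
  expect_equal(attr(capped, "n_mutations"), population_size(pop))
})

test_that("selection spares locally adapted homozygotes and kills others at rate s", {
  n <- 10000L
  # habitat 1 filled with AA: immune at any s
  aa <- make_pop(matrix(1L, n, 2), matrix(1L, n, 2),
                 sex = rep_len(c(0L, 1L), n), habitat = rep(1L, n))
  expect_equal(population_size(apply_selection(aa, model_params(s = 1, K = n))), n)
  # same AA individuals in habitat 2 all die at s = 1
  aa2 <- aa; aa2$habitat <- rep(2L, n)
  expect_equal(population_size(apply_selection(aa2, model_params(s = 1, K = n))), 0L)
  # s = 0: no deaths anywhere
  expect_equal(population_size(apply_selection(aa2, model_params(s = 0, K = n))), n)
  # s = 0.5 on an all-maladapted pool: ~half survive (binomial)
  set.seed(31)
  kept <- population_size(apply_selection(aa2, model_params(s = 0.5, K = n)))
  expect_lt(abs(kept - n / 2), 4 * sqrt(n * 0.25))
  # heterozygotes die at s * het_selection_rel
  het <- make_pop(matrix(1L, n, 2), matrix(2L, n, 2),
                  sex = rep_len(c(0L, 1L), n), habitat = rep(1L, n))
  expect_equal(population_size(apply_selection(het, model_params(s = 0.5, het_selection_rel = 2, K = n))), 0L)
})

test_that("density regulation caps each habitat at K with a uniform subsample", {
  p <- model_params(K = 10, L = 4)
  # 30 in habitat 1, 6 in habitat 2: only habitat 1 is culled
  pop <- make_pop(matrix(1L, 36, 4), matrix(1L, 36, 4),
                  sex = rep_len(c(0L, 1L), 36),
                  habitat = rep(c(1L, 2L), c(30L, 6L)))
  set.seed(12)
  out <- regulate_density(pop, p)
  expect_equal(sum(out$habitat == 1L), 10L)
  expect_equal(sum(out$habitat == 2L), 6L)
  # under capacity: untouched
  small <- make_pop(matrix(1L, 8, 4), matrix(1L, 8, 4),
                    sex = rep_len(c(0L, 1L), 8), habitat = rep(1L, 8))
  expect_identical(regulate_density(small, p), small)
  # uniformity: a marked individual among n survivors is kept ~K/n of the time
  n <- 8L
  marked <- make_pop(rbind(matrix(3L, 1, 4), matrix(1L, n - 1, 4)),
                     matrix(1L, n, 4),
                     sex = rep_len(c(0L, 1L), n), habitat = rep(1L, n))
  p4 <- model_params(K = 4, L = 4)
  set.seed(77)
  kept <- replicate(600, any(regulate_density(marked, p4)$chrom1[, 1] == 3L))
  expect_lt(abs(mean(kept) - 0.5), 4 * sqrt(0.25 / 600))
})

test_that("one generation composes the stages: capped habitats, advanced counter, mated parents replaced", {
  p <- model_params(K = 100, L = 10, generations = 1)
  set.seed(50)
  pop <- initialize_population(p)
  st <- step_generation(pop, p)
  expect_equal(st$population$generation, 1L)
  expect_lte(sum(st$population$habitat == 1L), p$K)
  expect_lte(sum(st$population$habitat == 2L), p$K)
  expect_s3_class(st$record, "mating_record")
  expect_false(anyDuplicated(st$record$female) > 0)
  expect_false(anyDuplicated(st$record$male) > 0)
  expect_equal(st$match_prop,
               mean(st$record$female_phenotype == st$record$male_phenotype))
})

test_that("with pf = 0 the matching proportion equals the random-mating expectation", {
  p <- model_params(K = 2000, L = 5, pf = 0)
  set.seed(60)
  pop <- initialize_population(p)
  st <- step_generation(pop, p)
  rec <- st$record
  expected <- sum(table(factor(rec$female_phenotype, levels = c("AA", "AAprime", "AprimeAprime"))) / nrow(rec) *
                  table(factor(rec$male_phenotype, levels = c("AA", "AAprime", "AprimeAprime"))) / nrow(rec))
  se <- sqrt(expected * (1 - expected) / nrow(rec))
  expect_lt(abs(st$match_prop - expected), 5 * se)
})

test_that("step-by-step and full-run trajectories are bit-identical under one seed", {
  p <- model_params(K = 60, L = 10, generations = 4, seed = 123)
  run <- run_simulation(p)
  set.seed(123)
  pop <- initialize_population(p)
  for (g in 1:4) pop <- step_generation(pop, p)$population
  expect_identical(run$final$chrom1, pop$chrom1)
  expect_identical(run$final$chrom2, pop$chrom2)
  expect_identical(run$final$sex, pop$sex)
  expect_identical(run$final$habitat, pop$habitat)
  # and the whole run replays identically
  expect_identical(run$metrics, run_simulation(p)$metrics)
})

test_that("a zero-length run reports only generation 0", {
  p <- model_params(K = 10, L = 5, generations = 0, seed = 1)
  run <- run_simulation(p)
  expect_equal(nrow(run$metrics), 1L)
  expect_equal(run$metrics$generation, 0)
  expect_false(run$extinct)
})

test_that("an emptied habitat is flagged as extinction with its generation", {
  p <- model_params(K = 2, L = 5, s = 1, generations = 100, seed = 6)
  run <- run_simulation(p)
  expect_true(run$extinct)
  expect_true(run$extinct_generation >= 1)
  expect_equal(nrow(run$metrics), run$extinct_generation + 1)
})

test_that("heterozygotes collapse and habitats fix their locally adapted homozygote", {
  p <- model_params(K = 500, L = 20, s = 0.5, pf = 2.4, generations = 400,
                    seed = 14)
  run <- run_simulation(p)
  last <- run$metrics[nrow(run$metrics), ]
  expect_false(run$extinct)
  expect_lt(last$freq_AAprime, 0.05)
  fin <- run$final
  ph <- phenotypes(fin)
  expect_gt(mean(ph[fin$habitat == 1L] == "AA"), 0.9)
  expect_gt(mean(ph[fin$habitat == 2L] == "AprimeAprime"), 0.9)
})
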