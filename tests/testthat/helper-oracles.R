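# Shared helpers: tiny-population constructors and independent brute-force
# oracles the vectorized/compiled implementations are checked against.

tiny_params <- function(...) {
  defaults <- list(K = 20L, L = 10L, generations = 5L)
  do.call(model_params, modifyList(defaults, list(...)))
}

# build a population directly from allele matrices (bypasses initialization)
make_pop <- function(chrom1, chrom2, sex, habitat, generation = 0L) {
  stopifnot(nrow(chrom1) == nrow(chrom2), length(sex) == nrow(chrom1),
            length(habitat) == nrow(chrom1))
  structure(list(chrom1 = chrom1, chrom2 = chrom2, sex = as.integer(sex),
                 habitat = as.integer(habitat),
                 generation = as.integer(generation)),
            class = "sim_population")
}

# a random population with preference/neutral alleles scattered at random
random_pop <- function(n = 30, L = 12, p_mut = 0.2) {
  draw <- function() {
    m <- matrix(0L, n, L)
    m[, 1] <- sample(c(1L, 2L), n, replace = TRUE)
    body <- matrix(sample(0:3, n * (L - 1), replace = TRUE,
                          prob = c(1 - p_mut, p_mut / 3, p_mut / 3, p_mut / 3)),
                   n, L - 1)
    m[, -1] <- body
    m
  }
  make_pop(draw(), draw(),
           sex = rep_len(c(0L, 1L), n),
           habitat = sample(1:2, n, replace = TRUE))
}

# brute-force preference score: explicit loop over every non-trait slot
oracle_pref_score <- function(pop, i) {
  d <- 0L
  for (chrom in list(pop$chrom1, pop$chrom2))
    for (j in 2:ncol(chrom)) {
      if (chrom[i, j] == 1L) d <- d + 1L
      if (chrom[i, j] == 2L) d <- d - 1L
    }
  d
}

# brute-force per-individual mean distance, then mean over individuals
oracle_avg_pref_distance <- function(pop, code, class_label) {
  vals <- c()
  for (i in seq_len(nrow(pop$chrom1))) {
    if (phenotypes(pop, i) != class_label) next
    pos <- c()
    for (chrom in list(pop$chrom1, pop$chrom2))
      for (j in 2:ncol(chrom))
        if (chrom[i, j] == code) pos <- c(pos, j - 1L)
    if (length(pos) > 0) vals <- c(vals, mean(pos))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# brute-force position histogram tally
oracle_position_histogram <- function(pop) {
  hist <- position_histogram(pop)
  hist$count <- 0L
  chroms <- rbind(pop$chrom1, pop$chrom2)
  for (r in seq_len(nrow(chroms))) {
    ccls <- if (chroms[r, 1] == 1L) "A" else "Aprime"
    for (j in 2:ncol(chroms)) {
      tp <- if (chroms[r, j] == 1L) "pref_a"
            else if (chroms[r, j] == 2L) "pref_aprime" else NA
      if (!is.na(tp)) {
        k <- which(hist$chrom_class == ccls & hist$pref_type == tp &
                   hist$position == j - 1L)
        hist$count[k] <- hist$count[k] + 1L
      }
    }
  }
  hist
}

# unordered per-locus allele pairs, to verify recombination conserves them
locus_multisets <- function(pop) {
  a <- pmin(pop$chrom1, pop$chrom2)
  b <- pmax(pop$chrom1, pop$chrom2)
  list(lo = a, hi = b)
}
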