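# Replicate and parameter-sweep orchestration plus the inferential layer:
# minimum-average-distance extraction, Pearson correlations across
# simulations, and OLS F-tests over the s x pf grid.

DIST_COLS <- c("dist_prefA_AA", "dist_prefAp_AA", "dist_neutral_AA",
               "dist_prefA_ApAp", "dist_prefAp_ApAp", "dist_neutral_ApAp")
MEANABLE_COLS <- c("match_prop", DIST_COLS, "mean_pref_per_chrom",
                   "n_h1", "n_h2")

#' Run replicate simulations and average their metric series
#'
#' Runs `n_reps` independent simulations of the same parameter set,
#' replicate `r` seeded with `base_seed + r`, and averages every metric
#' column generation-by-generation across replicates (with standard
#' errors). Replicates that go extinct are excluded from the means with a
#' warning.
#'
#' @param params A [model_params()] object.
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`.
#' @param snapshot_generations Passed to [run_simulation()].
#' @param keep_runs Keep the individual `sim_run` objects (default TRUE;
#'   set FALSE to save memory in large sweeps).
#' @return A `"replicate_set"`: list with `mean_series` (data frame:
#'   `generation`, then `mean_*`, `se_*`, `n_reps` per generation), `runs`
#'   (list of `sim_run` or `NULL`), `metrics` (list of per-replicate metric
#'   data frames), `seeds`, `extinct` (logical vector), `params`.
#' @export
#' @examples
#' p <- model_params(K = 30, L = 10, generations = 3)
#' rs <- run_replicates(p, n_reps = 2, base_seed = 1)
#' rs$mean_series$mean_match_prop
run_replicates <- function(params, n_reps, base_seed,
                           snapshot_generations = integer(0),
                           keep_runs = TRUE) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_reps)
  runs <- vector("list", n_reps)
  metrics <- vector("list", n_reps)
  extinct <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    run <- run_simulation(params, snapshot_generations = snapshot_generations,
                          seed = seeds[r], keep_final = FALSE)
    metrics[[r]] <- run$metrics
    extinct[r] <- isTRUE(run$extinct)
    if (keep_runs) runs[[r]] <- run
  }
  if (any(extinct))
    warning(sprintf("%d of %d replicates went extinct; excluded from means",
                    sum(extinct), n_reps))
  use <- which(!extinct)
  if (length(use) == 0L) stop("all replicates went extinct")
  gens <- 0:params$generations
  ms <- data.frame(generation = gens)
  for (cl in MEANABLE_COLS) {
    vals <- vapply(use, function(r) metrics[[r]][[cl]], numeric(length(gens)))
    vals <- matrix(vals, nrow = length(gens))
    ms[[paste0("mean_", cl)]] <- rowMeans(vals, na.rm = TRUE)
    nr <- rowSums(!is.na(vals))
    sdv <- apply(vals, 1, sd, na.rm = TRUE)
    ms[[paste0("se_", cl)]] <- ifelse(nr > 1, sdv / sqrt(nr), NA_real_)
  }
  ms$n_reps <- length(use)
  is.na(ms) <- sapply(ms, is.nan)
  structure(list(mean_series = ms, runs = if (keep_runs) runs else NULL,
                 metrics = metrics, seeds = seeds, extinct = extinct,
                 params = params),
            class = "replicate_set")
}

#' Minimum of a (mean) distance series
#'
#' The minimum over generations of a distance series — the summary used to
#' quantify the strength of physical linkage attained during a run. Missing
#' entries are skipped; ties resolve to the earliest generation.
#'
#' @param series Numeric vector (typically a `mean_dist_*` column).
#' @param generations Optional vector of generation labels (defaults to
#'   `0:(length(series)-1)`).
#' @return List with `value` and `generation` (the argmin).
#' @export
#' @examples
#' min_avg_distance(c(50, 10, 12))
min_avg_distance <- function(series, generations = seq_along(series) - 1L) {
  stopifnot(length(series) == length(generations), length(series) > 0)
  if (all(is.na(series))) stop("series is entirely missing")
  i <- which.min(series)  # ignores NA, first index on ties
  list(value = series[[i]], generation = generations[[i]])
}

#' First generation reaching an assortment threshold
#'
#' First generation at which the (replicate-mean) matching-pair proportion
#' reaches `threshold`; the first crossing counts, with no hysteresis.
#'
#' @param series Numeric vector of matching-pair proportions.
#' @param generations Generation labels (defaults to 0-based positions).
#' @param threshold In `(0, 1]`; default 0.9.
#' @return Generation of first crossing, or `NA` if never reached.
#' @export
#' @examples
#' generation_to_assortment(c(0.5, 0.91, 0.89))  # 1
generation_to_assortment <- function(series,
                                     generations = seq_along(series) - 1L,
                                     threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1,
            length(series) == length(generations))
  hit <- which(!is.na(series) & series >= threshold)
  if (length(hit) == 0L) return(NA_integer_)
  generations[[hit[1L]]]
}

# all-missing series reduce to NA inside sweeps instead of erroring (a short
# run may simply not have accumulated any preference locus yet)
safe_min_avg_distance <- function(series, generations = seq_along(series) - 1L) {
  if (all(is.na(series)))
    return(list(value = NA_real_, generation = NA_integer_))
  min_avg_distance(series, generations)
}

#' Per-replicate metric table at a fixed generation
#'
#' Extracts, from a [run_replicates()] result, one row per (non-extinct)
#' replicate with the distance columns and matching-pair proportion at the
#' given generation — the observations used in the distance-vs-assortment
#' correlation test.
#'
#' @param reps A `replicate_set`.
#' @param generation Generation at which to read the metrics (default 700).
#' @return Data frame with `replicate`, `seed`, the six `dist_*` columns
#'   and `match_prop`.
#' @export
replicate_table <- function(reps, generation = 700) {
  stopifnot(inherits(reps, "replicate_set"))
  use <- which(!reps$extinct)
  rows <- lapply(use, function(r) {
    m <- reps$metrics[[r]]
    i <- match(generation, m$generation)
    if (is.na(i)) stop(sprintf("replicate %d has no generation %d", r,
                               generation))
    cbind(data.frame(replicate = r, seed = reps$seeds[r]),
          m[i, c(DIST_COLS, "match_prop")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between physical linkage and assortative mating
#'
#' Pearson correlation, across replicate simulations, between the mean
#' distance of preference loci from the trait locus and the matching-pair
#' proportion, computed separately for each phenotype class (AA with
#' preference-for-AA distances, A'A' with preference-for-A'A' distances)
#' and, as the null comparison, for neutral-locus distances in both
#' classes. Each simulation contributes one observation; `df = n - 2` and
#' the two-sided p-value comes from the t transform of r.
#'
#' @param rows Data frame as returned by [replicate_table()] (one row per
#'   simulation).
#' @return Data frame with `phenotype_class`, `pref_type`, `dist_col`, `n`,
#'   `r`, `df`, `p`.
#' @export
distance_assortment_correlation <- function(rows) {
  combos <- data.frame(
    phenotype_class = c("AA", "AprimeAprime", "AA", "AprimeAprime"),
    pref_type = c("pref_a", "pref_aprime", "neutral", "neutral"),
    dist_col = c("dist_prefA_AA", "dist_prefAp_ApAp",
                 "dist_neutral_AA", "dist_neutral_ApAp"),
    stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    x <- rows[[combos$dist_col[i]]]
    y <- rows$match_prop
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) stop("need >= 3 simulations with non-missing values")
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      stop("degenerate (zero-variance) observations")
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(combos[i, ], n = sum(ok), r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the s x pf parameter sweep
#'
#' Runs `n_reps` replicate simulations for every combination of the
#' selection-coefficient and preference-strength grids (canonical grid:
#' `s = 0.5, 0.6, 0.7, 0.8` x `pf = 0.3, 0.6, 1.2, 2.4`, 20 replicates).
#' Per combination, the replicate-mean distance series is reduced to its
#' minimum over generations (per preference type and phenotype class), and
#' the first generation reaching 90% assortment is recorded. Seeds are
#' disjoint across the whole sweep: combination `i` (row-major over the
#' grid) uses `base_seed + (i-1) * n_reps + r`.
#'
#' @param s_values,pf_values Numeric grids.
#' @param n_reps Replicates per combination.
#' @param base_seed Integer base seed.
#' @param params Template [model_params()]; `s` and `pf` are overwritten per
#'   combination (use its `generations` to control sweep length).
#' @return A `"sweep_result"`: list with `summary` (one row per combination:
#'   `s`, `pf`, `n_reps`, `min_dist_*` and `argmin_*` for the four
#'   preference/neutral columns, `gen_at_90`) and `replicates` (one row per
#'   run with per-run minima and seeds).
#' @export
run_sweep <- function(s_values, pf_values, n_reps, base_seed,
                      params = model_params()) {
  grid <- expand.grid(pf = pf_values, s = s_values)[, c("s", "pf")]
  sum_rows <- vector("list", nrow(grid))
  rep_rows <- vector("list", nrow(grid))
  track <- c(min_dist_prefA_AA = "mean_dist_prefA_AA",
             min_dist_prefAp_ApAp = "mean_dist_prefAp_ApAp",
             min_dist_neutral_AA = "mean_dist_neutral_AA",
             min_dist_neutral_ApAp = "mean_dist_neutral_ApAp")
  for (i in seq_len(nrow(grid))) {
    pi <- validate_params(modifyList(unclass(params),
                                     list(s = grid$s[i], pf = grid$pf[i])))
    reps <- run_replicates(pi, n_reps,
                           base_seed = as.integer(base_seed) + (i - 1L) * n_reps,
                           keep_runs = FALSE)
    ms <- reps$mean_series
    row <- data.frame(s = grid$s[i], pf = grid$pf[i], n_reps = ms$n_reps[1])
    for (nm in names(track)) {
      mn <- safe_min_avg_distance(ms[[track[[nm]]]], ms$generation)
      row[[nm]] <- mn$value
      row[[sub("^min_", "argmin_", nm)]] <- mn$generation
    }
    row$gen_at_90 <- generation_to_assortment(ms$mean_match_prop,
                                              ms$generation)
    sum_rows[[i]] <- row
    rr <- lapply(which(!reps$extinct), function(r) {
      m <- reps$metrics[[r]]
      data.frame(s = grid$s[i], pf = grid$pf[i], replicate = r,
                 seed = reps$seeds[r],
                 min_dist_prefA_AA =
                   safe_min_avg_distance(m$dist_prefA_AA)$value,
                 min_dist_prefAp_ApAp =
                   safe_min_avg_distance(m$dist_prefAp_ApAp)$value,
                 gen_at_90 = generation_to_assortment(m$match_prop,
                                                     m$generation))
    })
    rep_rows[[i]] <- do.call(rbind, rr)
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 replicates = do.call(rbind, rep_rows),
                 params = params, base_seed = as.integer(base_seed),
                 n_reps = as.integer(n_reps)),
            class = "sweep_result")
}

#' OLS regression of minimum distance on s and pf
#'
#' Fits, per preference type, an ordinary least-squares regression of the
#' per-combination minimum average distance on `s` and `pf` — one
#' observation per grid combination, the model's canonical design (16
#' combinations give residual df 13 for the main-effects model) — and
#' reports partial F-tests per predictor. A second model adds the `s:pf`
#' interaction (residual df 12) whose F-test is reported separately.
#'
#' @param sweep_summary The `summary` data frame of a [run_sweep()] result
#'   (or a `sweep_result` object).
#' @param responses Named character vector mapping a preference-type label
#'   to its `min_dist_*` column.
#' @return Data frame with `response`, `term`, `estimate`, `F`, `df1`,
#'   `df2`, `p`; terms are `s` and `pf` from the main-effects model plus
#'   `s:pf` from the interaction model.
#' @export
sweep_regression <- function(sweep_summary,
                             responses = c(pref_a = "min_dist_prefA_AA",
                                           pref_aprime = "min_dist_prefAp_ApAp")) {
  if (inherits(sweep_summary, "sweep_result"))
    sweep_summary <- sweep_summary$summary
  out <- lapply(names(responses), function(lbl) {
    y <- sweep_summary[[responses[[lbl]]]]
    dat <- data.frame(y = y, s = sweep_summary$s, pf = sweep_summary$pf)
    dat <- dat[!is.na(dat$y), ]
    fit <- lm(y ~ s + pf, data = dat)
    if (qr(fit)$rank < 3) stop("rank-deficient design (degenerate grid)")
    dr <- drop1(fit, test = "F")
    fit_int <- lm(y ~ s * pf, data = dat)
    dri <- drop1(fit_int, test = "F")
    co <- coef(fit)
    data.frame(
      response = lbl,
      term = c("s", "pf", "s:pf"),
      estimate = c(co[["s"]], co[["pf"]], coef(fit_int)[["s:pf"]]),
      F = c(dr["s", "F value"], dr["pf", "F value"], dri["s:pf", "F value"]),
      df1 = 1L,
      df2 = c(fit$df.residual, fit$df.residual, fit_int$df.residual),
      p = c(dr["s", "Pr(>F)"], dr["pf", "Pr(>F)"], dri["s:pf", "Pr(>F)"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
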