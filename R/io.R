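# Config parsing, TSV writers/readers, population snapshots, fixtures.
# All tables are written as TSV with a header row; missing values are the
# literal string "NA" (never silently dropped). Numeric output is rounded
# to 6 significant digits by default for diffability; full precision is
# available via `digits = NA`.

CONFIG_KEYS <- c("s", "pf", "K", "L", "mut_fraction", "max_pairings",
                 "n_offspring", "n_crossovers", "het_mate_prob",
                 "het_selection_rel", "generations", "seed", "mut_on_pool",
                 "out_dir", "snapshot_generations", "n_reps", "base_seed",
                 "verbose")

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file whose keys are the [model_params()] fields plus the
#' run-level keys `out_dir`, `snapshot_generations`, `n_reps`, `base_seed`
#' and `verbose`. Missing keys take the model defaults (an empty file gives
#' the full default parameter set); unknown keys are rejected by name;
#' invalid values fail [model_params()] validation.
#'
#' @param path Path to a YAML config file.
#' @return A `"run_config"`: list with `params` (a `model_params`),
#'   `out_dir`, `snapshot_generations`, `n_reps`, `base_seed`, `verbose`.
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("s: 0.6\npf: 1.2", cfg_file)
#' load_config(cfg_file)$params$s
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), CONFIG_KEYS)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  par_keys <- intersect(names(raw), names(formals(model_params)))
  params <- do.call(model_params, raw[par_keys])
  structure(list(
    params = params,
    out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
    snapshot_generations = as.integer(raw$snapshot_generations %||% integer(0)),
    n_reps = as.integer(raw$n_reps %||% 1L),
    base_seed = if (is.null(raw$base_seed)) NULL else as.integer(raw$base_seed),
    verbose = isTRUE(raw$verbose)),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: the write/read round trip reproduces the
#' configuration exactly.
#'
#' @param config A `run_config` (or a bare `model_params`, in which case
#'   run-level keys take their defaults).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "model_params"))
    config <- structure(list(params = config, out_dir = ".",
                             snapshot_generations = integer(0), n_reps = 1L,
                             base_seed = NULL, verbose = FALSE),
                        class = "run_config")
  stopifnot(inherits(config, "run_config"))
  out <- c(unclass(config$params),
           list(out_dir = config$out_dir,
                snapshot_generations = config$snapshot_generations,
                n_reps = config$n_reps, base_seed = config$base_seed,
                verbose = config$verbose))
  out <- out[!vapply(out, is.null, logical(1))]
  out <- out[vapply(out, length, integer(1)) > 0]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a metrics table as TSV
#'
#' @param metrics Data frame (e.g. the `metrics` of a [run_simulation()]
#'   result, or a sweep summary).
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6); `NA`
#'   writes full precision.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, digits = 6) {
  out <- metrics
  if (!is.na(digits))
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a metrics TSV written by [write_metrics()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_metrics <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write a population snapshot as TSV
#'
#' One row per chromosome: `id` (individual), `sex` (`F`/`M`), `habitat`
#' (`H1`/`H2`), `chromosome` (1/2), then the `L` integer allele codes in
#' columns `p0..p(L-1)` (see [allele_codes()]; `p0` is the trait locus).
#' The read/write round trip reproduces the allele vectors exactly.
#'
#' @param pop A `sim_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  n <- nrow(pop$chrom1)
  L <- ncol(pop$chrom1)
  alle <- rbind(pop$chrom1, pop$chrom2)
  df <- data.frame(id = rep(seq_len(n), 2L),
                   sex = rep(ifelse(pop$sex == SEX_FEMALE, "F", "M"), 2L),
                   habitat = rep(paste0("H", pop$habitat), 2L),
                   chromosome = rep(c(1L, 2L), each = n))
  colnames(alle) <- paste0("p", seq_len(L) - 1L)
  df <- cbind(df, as.data.frame(alle))
  df <- df[order(df$id, df$chromosome), ]
  attr(df, "generation") <- pop$generation
  data.table::fwrite(cbind(data.frame(generation = pop$generation), df),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a population snapshot written by [write_population()]
#' @param path Input path.
#' @return A `sim_population`.
#' @export
read_population <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
  d1 <- df[df$chromosome == 1L, ]
  d2 <- df[df$chromosome == 2L, ]
  d1 <- d1[order(d1$id), ]
  d2 <- d2[order(d2$id), ]
  stopifnot(nrow(d1) == nrow(d2), all(d1$id == d2$id))
  pop <- list(
    chrom1 = as.matrix(d1[, pcols]),
    chrom2 = as.matrix(d2[, pcols]),
    sex = ifelse(d1$sex == "F", SEX_FEMALE, SEX_MALE),
    habitat = as.integer(sub("^H", "", d1$habitat)),
    generation = as.integer(df$generation[1]))
  dimnames(pop$chrom1) <- NULL
  dimnames(pop$chrom2) <- NULL
  storage.mode(pop$chrom1) <- "integer"
  storage.mode(pop$chrom2) <- "integer"
  class(pop) <- "sim_population"
  pop
}

#' Write deterministic test fixtures
#'
#' Emits a small, fully deterministic set of files used by the test suite
#' and as worked examples: a tiny population snapshot (`K = 10`, `L = 10`),
#' the metrics of a short run at the same scale, and a config file. Calling
#' twice with the same seed produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- model_params(K = 10L, L = 10L, generations = 20L, seed = as.integer(seed))
  f_pop <- file.path(dir, "population_K10_L10.tsv")
  f_met <- file.path(dir, "metrics_K10_L10.tsv")
  f_cfg <- file.path(dir, "config_K10_L10.yaml")
  run <- run_simulation(p)
  write_population(run$final, f_pop)
  write_metrics(run$metrics, f_met)
  write_config(p, f_cfg)
  invisible(c(f_pop, f_met, f_cfg))
}
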