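#' Write a trial table to CSV/TSV
#'
#' Writes the tidy long format with the fixed header
#' `progeny_id, entry_type, generation, rep, block, plot, ancestry_group,
#' trait, value` (UTF-8, `.` decimal separator). The separator is chosen
#' from the file extension: `.tsv`/`.tab` write tab-separated, anything else
#' comma-separated.
#'
#' @param trial A `trial_table` (or any data frame with the nine columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(all(trial_columns %in% names(trial)))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(trial)[, trial_columns], path,
                     sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table written by [write_trial()]
#'
#' @param path Input CSV/TSV path.
#' @return A `trial_table` data frame.
#' @export
read_trial <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = c(progeny_id = "character",
                                         entry_type = "character",
                                         generation = "character",
                                         ancestry_group = "character",
                                         trait = "character"))
  missing <- setdiff(trial_columns, names(df))
  if (length(missing))
    stop_recsel("trial file %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  new_trial_table(df)
}

#' Read and validate a JSON run configuration
#'
#' Loads the pipeline configuration and validates it against the schema
#' shipped in `inst/schema/run-config-schema.json`: required keys must be
#' present with the right types and unknown top-level keys are rejected.
#'
#' @param path Path to a JSON file, or a list already parsed.
#' @return The validated configuration as a list, with `design`, `traits`
#'   and `depression` blocks converted to their spec objects.
#' @seealso [run_pipeline()], [default_run_config()]
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE)
  else path
  validate_run_config(config)
}

run_config_keys <- c("mode", "paths", "design", "traits", "genetic_corr",
                     "depression", "weights", "directions",
                     "selection_fraction", "strategies", "k_grid",
                     "gain_mode", "out_dir", "seed", "log_level")

validate_run_config <- function(config) {
  if (!is.list(config)) stop_recsel("run config must be a JSON object")
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown))
    stop_recsel("run config has unknown key(s): %s", paste(unknown, collapse = ", "))
  config$mode <- config$mode %||% "simulate"
  if (!config$mode %in% c("simulate", "files"))
    stop_recsel("run config: mode must be 'simulate' or 'files'")
  if (is.null(config$seed) || !is_number(config$seed))
    stop_recsel("run config: an integer `seed` is required")
  config$seed <- as.integer(config$seed)

  if (config$mode == "simulate") {
    d <- config$design
    if (is.null(d)) stop_recsel("run config: `design` block required in simulate mode")
    if (!inherits(d, "design_spec"))
      config$design <- design_spec(
        n_progenies = d$n_progenies, n_checks = d$n_checks %||% 2,
        n_reps = d$n_reps %||% 3, blocks_per_rep = d$blocks_per_rep %||% 14,
        n_ancestry_groups = d$n_ancestry_groups %||% 5, seed = config$seed)
    if (is.null(config$traits)) stop_recsel("run config: `traits` block required in simulate mode")
    if (!all(vapply(config$traits, inherits, TRUE, "trait_spec")))
      config$traits <- lapply(config$traits, function(tr)
        trait_spec(tr$name, tr$base_mean, tr$sigma2_family, tr$sigma2_plot,
                   tr$sigma2_rep %||% 0, tr$sigma2_block %||% 0,
                   tr$direction %||% "maximize"))
    config$traits <- as_trait_list(config$traits)
    if (!is.null(config$depression) &&
        !all(vapply(config$depression, inherits, TRUE, "depression_spec")))
      config$depression <- lapply(config$depression, function(d)
        depression_spec(d$trait, d$mean_id, d$sd_id))
    if (!is.null(config$genetic_corr))
      config$genetic_corr <- check_corr_matrix(as.matrix(config$genetic_corr),
                                               length(config$traits))
  } else {
    p <- config$paths
    if (is.null(p$s0) || is.null(p$s1))
      stop_recsel("run config: paths$s0 and paths$s1 required in files mode")
  }

  if (!is.null(config$weights)) config$weights <- unlist(config$weights)
  if (!is.null(config$directions)) config$directions <- unlist(config$directions)
  config$selection_fraction <- config$selection_fraction %||% 0.20
  if (!is_number(config$selection_fraction) ||
      config$selection_fraction <= 0 || config$selection_fraction > 1)
    stop_recsel("run config: selection_fraction must be in (0, 1]")
  config$strategies <- config$strategies %||%
    c("BIA", "SHI", "MMI", "BLUP_GY", "BLUP_ID")
  bad <- setdiff(config$strategies, c("BIA", "SHI", "MMI", "BLUP_GY", "BLUP_ID"))
  if (length(bad)) stop_recsel("run config: unknown strategies: %s", paste(bad, collapse = ", "))
  config$k_grid <- as.integer(config$k_grid %||% c(10L, 20L, 30L, 40L))
  config$gain_mode <- config$gain_mode %||% "heritability_adjusted"
  if (!config$gain_mode %in% c("heritability_adjusted", "differential"))
    stop_recsel("run config: gain_mode must be 'heritability_adjusted' or 'differential'")
  config$log_level <- config$log_level %||% "info"
  if (!config$log_level %in% c("quiet", "info"))
    stop_recsel("run config: log_level must be 'quiet' or 'info'")
  config
}

#' Default run configuration (simulated reference scenario)
#'
#' The configuration that [run_pipeline()] uses when pointed at no file:
#' the [default_study()] simulation with all five selection strategies,
#' 20% selection fraction, and a top-k grid of 10–40.
#'
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @return A validated run configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("recsel-run-")) {
  st <- default_study(seed)
  validate_run_config(list(
    mode = "simulate", design = st$design, traits = st$traits,
    genetic_corr = st$genetic_corr, depression = st$depression,
    weights = st$weights, directions = st$directions,
    selection_fraction = st$selection_fraction,
    strategies = c("BIA", "SHI", "MMI", "BLUP_GY", "BLUP_ID"),
    k_grid = c(10L, 20L, 30L, 40L), gain_mode = "heritability_adjusted",
    out_dir = out_dir, seed = as.integer(seed), log_level = "info"))
}
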