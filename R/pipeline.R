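#' Run the full recurrent-selection evaluation workflow
#'
#' Executes the study pipeline from one configuration: obtain the paired
#' S0/S1 trials (simulated or read from files), derive the
#' inbreeding-depression trait, estimate genetic parameters, fit the
#' REML/BLUP models for grain yield and inbreeding depression, score the
#' phenotypic indexes, truncate each strategy to the selected fraction,
#' compute predicted gains, and quantify agreement among the selected sets.
#' Every intermediate artifact is written to the output directory together
#' with a JSON manifest (inputs, seed, package version, per-stage status,
#' and MD5 checksums of all outputs). The same configuration and seed
#' reproduce every file, and therefore the manifest checksums, exactly.
#'
#' @param config A run configuration from [read_run_config()] or
#'   [default_run_config()].
#' @param out_dir Output directory (default: `config$out_dir`).
#' @param seed Root seed override (default: `config$seed`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = config$out_dir, seed = config$seed) {
  config <- validate_run_config(config)
  config$seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- tempfile("recsel-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (config$log_level != "quiet") message(line)
  }
  stages <- character()
  stage <- function(name, expr) {
    say("stage %s ...", name)
    res <- tryCatch(expr, error = function(e)
      stop_recsel("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                  name, conditionMessage(e), out_dir))
    stages[[name]] <<- "ok"
    res
  }
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }

  # -- data ------------------------------------------------------------
  dat <- stage("data", {
    if (config$mode == "simulate") {
      sim <- simulate_trial(config$design, config$traits, config$genetic_corr,
                            seed = config$seed)
      s1seed <- derive_seed(config$seed, "s1-trial")
      dep <- config$depression %||% list(depression_spec("GY", 43, 8))
      s1 <- simulate_s1(sim$trial, sim$truth, dep, seed = s1seed)
      write_trial(sim$trial, emit(file.path(out_dir, "s0_trial.csv")))
      write_trial(s1$trial, emit(file.path(out_dir, "s1_trial.csv")))
      utils::write.csv(s1$truth, emit(file.path(out_dir, "truth.csv")),
                       row.names = FALSE, quote = FALSE)
      list(s0 = sim$trial, s1 = s1$trial, truth = s1$truth,
           id_source = dep[[1]]$trait)
    } else {
      list(s0 = read_trial(config$paths$s0), s1 = read_trial(config$paths$s1),
           truth = NULL, id_source = config$paths$id_source %||% "GY")
    }
  })

  directions <- config$directions
  if (is.null(directions)) {
    directions <- stats::setNames(rep("maximize", 0), character())
    if (config$mode == "simulate")
      directions <- stats::setNames(
        vapply(config$traits, `[[`, "", "direction"),
        vapply(config$traits, `[[`, "", "name"))
    else {
      tn <- sort(unique(dat$s0$trait))
      directions <- stats::setNames(rep("maximize", length(tn)), tn)
    }
    directions <- c(directions, ID = "minimize")
  }
  weights <- config$weights %||% c(GY = 2, ID = 1)

  # -- inbreeding-depression trait ------------------------------------
  idt <- stage("id_trait", {
    x <- id_table(dat$s0, dat$s1, trait = dat$id_source, level = "rep",
                  id_trait = "ID")
    write_trial(x, emit(file.path(out_dir, "id_trait.csv")))
    x
  })
  combined <- rbind(as.data.frame(dat$s0), as.data.frame(idt))
  combined <- new_trial_table(combined)
  index_traits <- c(sort(unique(dat$s0$trait[dat$s0$entry_type == "progeny"])), "ID")

  # -- genetic parameters ---------------------------------------------
  params <- stage("genetic_params", {
    p <- estimate_PG(combined, traits = index_traits, directions = directions)
    utils::write.csv(data.frame(trait = p$traits, h2_family = p$h2_family,
                                row.names = NULL),
                     emit(file.path(out_dir, "heritabilities.csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(p$P), emit(file.path(out_dir, "P_matrix.csv")))
    utils::write.csv(as.data.frame(p$G), emit(file.path(out_dir, "G_matrix.csv")))
    p
  })
  fm <- family_means(combined, generation = c("S0", "S0S1"))

  # -- REML/BLUP fits ---------------------------------------------------
  blups <- stage("blup_fits", {
    s0sub <- dat$s0[dat$s0$trait == dat$id_source, ]
    rnd <- c("rep", "family")
    if (length(unique(paste(s0sub$rep, s0sub$block))) > length(unique(s0sub$rep)))
      rnd <- c("rep", "block", "family")
    fit_gy <- reml_fit(dat$s0, model_spec(dat$id_source, random_terms = rnd))
    fit_id <- reml_fit(idt, model_spec("ID", random_terms = "family"))
    write_blup(fit_gy, emit(file.path(out_dir, "blup_gy.csv")),
               emit(file.path(out_dir, "blup_gy_summary.json")))
    write_blup(fit_id, emit(file.path(out_dir, "blup_id.csv")),
               emit(file.path(out_dir, "blup_id_summary.json")))
    list(GY = fit_gy, ID = fit_id)
  })

  # -- indexes and selection -------------------------------------------
  selections <- stage("indexes", {
    res <- list()
    for (s in config$strategies) {
      r <- switch(s,
        BIA = base_index(fm, weights, directions, traits = index_traits),
        SHI = smith_hazel(fm, params, weights),
        MMI = rank_sum(fm, weights, directions, traits = index_traits),
        BLUP_GY = blup_selection(blups$GY, "BLUP_GY", "maximize"),
        BLUP_ID = blup_selection(blups$ID, "BLUP_ID", "minimize"))
      r <- select_top(r, fraction = config$selection_fraction)
      write_selection(r, emit(file.path(out_dir, paste0("selection_", s, ".csv"))))
      emit(file.path(out_dir, paste0("selection_", s, "_selected.txt")))
      res[[s]] <- r
    }
    res
  })

  # -- gains ------------------------------------------------------------
  gains <- stage("gains", {
    reports <- lapply(selections, function(r) {
      b <- switch(r$strategy, BLUP_GY = blups$GY, BLUP_ID = blups$ID, NULL)
      predicted_gain(r, fm, params, mode = config$gain_mode, blup = b,
                     traits = index_traits)
    })
    long <- do.call(rbind, reports)
    utils::write.csv(long, emit(file.path(out_dir, "predicted_gains.csv")),
                     row.names = FALSE, quote = FALSE)
    # wide layout: one row per trait, Xs and % per strategy
    wide <- data.frame(trait = index_traits)
    for (nm in names(reports)) {
      rr <- reports[[nm]]
      wide[[paste0(nm, "_Xs")]] <- rr$Xs[match(index_traits, rr$trait)]
      wide[[paste0(nm, "_pct")]] <- rr$PG_pct[match(index_traits, rr$trait)]
    }
    utils::write.csv(wide, emit(file.path(out_dir, "predicted_gains_wide.csv")),
                     row.names = FALSE, quote = FALSE)
    reports
  })

  # -- coincidence ------------------------------------------------------
  coin <- NULL
  if (length(selections) >= 2L) {
    coin <- stage("coincidence", {
      coll <- selection_collection(lapply(selections, `[[`, "ranking"),
                                   k_grid = config$k_grid)
      for (k in coll$k_grid) {
        utils::write.csv(as.data.frame(pairwise_matrix(coll, k, "jaccard")),
                         emit(file.path(out_dir, sprintf("coincidence_jaccard_k%d.csv", k))))
        utils::write.csv(as.data.frame(pairwise_matrix(coll, k, "ci")),
                         emit(file.path(out_dir, sprintf("coincidence_ci_k%d.csv", k))))
      }
      curve <- coincidence_curve(coll, "ci")
      utils::write.csv(curve, emit(file.path(out_dir, "coincidence_curve.csv")),
                       row.names = FALSE, quote = FALSE)
      k_sel <- selections[[1]]$k
      utils::write.csv(as.data.frame(membership_matrix(coll, k_sel)),
                       emit(file.path(out_dir, "membership_matrix.csv")))
      list(collection = coll, curve = curve)
    })
  } else {
    say("coincidence stage skipped: fewer than 2 strategies")
    stages[["coincidence"]] <- "skipped"
  }

  manifest <- list(
    package = "recsel",
    version = as.character(utils::packageVersion("recsel")),
    seed = config$seed,
    mode = config$mode,
    selection_fraction = config$selection_fraction,
    k_selected = selections[[1]]$k,
    strategies = names(selections),
    k_grid = config$k_grid,
    gain_mode = config$gain_mode,
    traits = index_traits,
    stages = as.list(stages),
    outputs = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d output files in %s", length(manifest$outputs), out_dir)

  invisible(structure(list(manifest = manifest, out_dir = out_dir,
                           selections = selections, gains = gains,
                           params = params, blups = blups, coincidence = coin,
                           family_means = fm, data = dat),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("recsel pipeline run (seed", x$manifest$seed, ")\n")
  cat("  strategies:", paste(x$manifest$strategies, collapse = ", "), "\n")
  cat("  selected per strategy:", x$manifest$k_selected, "\n")
  cat("  outputs:", length(x$manifest$outputs), "files in", x$out_dir, "\n")
  invisible(x)
}
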