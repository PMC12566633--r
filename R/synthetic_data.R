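#' Trait specification for trial simulation
#'
#' Describes one trait of a half-sib progeny trial: its base (population)
#' mean and the variance components of the generative model. Under the
#' half-sib model the variance among family effects equals one quarter of the
#' additive genetic variance, so `sigma2_family` plays the role of
#' \eqn{\sigma^2_A/4}.
#'
#' @param name Trait identifier (e.g. `"GY"` for grain yield).
#' @param base_mean Population mean on the trait scale (finite).
#' @param sigma2_family Variance among half-sib family effects (>= 0),
#'   squared trait units.
#' @param sigma2_plot Plot-error variance (>= 0). Plant-to-plant variation
#'   within the row plot is folded into this term.
#' @param sigma2_rep Replicate (superblock) variance (>= 0).
#' @param sigma2_block Variance of incomplete blocks nested in replicates
#'   (>= 0).
#' @param direction `"maximize"` if larger values are favourable (yield) or
#'   `"minimize"` if smaller values are favourable (inbreeding depression,
#'   plant height).
#' @return An object of class `trait_spec`.
#' @seealso [simulate_trial()]
#' @export
trait_spec <- function(name, base_mean, sigma2_family, sigma2_plot,
                       sigma2_rep = 0, sigma2_block = 0,
                       direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in c(base_mean, sigma2_family, sigma2_plot, sigma2_rep, sigma2_block)) {
    if (!is_number(v)) stop_recsel("trait_spec('%s'): all parameters must be finite numbers", name)
  }
  if (sigma2_family < 0 || sigma2_plot < 0 || sigma2_rep < 0 || sigma2_block < 0)
    stop_recsel("trait_spec('%s'): variances must be non-negative", name)
  structure(list(name = name, base_mean = base_mean,
                 sigma2_family = sigma2_family, sigma2_plot = sigma2_plot,
                 sigma2_rep = sigma2_rep, sigma2_block = sigma2_block,
                 direction = direction),
            class = "trait_spec")
}

#' Inbreeding-depression specification
#'
#' Describes the distribution of true per-family inbreeding depression
#' \eqn{\delta} applied to one trait when generating the selfed (S1) trial:
#' the S1 expected family mean is the S0 expected family mean times
#' \eqn{(1 - \delta/100)}. Simulated \eqn{\delta} values are truncated to
#' (-100, 100).
#'
#' @param trait Identifier of the depressed trait (must exist in the S0 trial).
#' @param mean_id Mean true inbreeding depression, percent (in `[0, 100)`).
#' @param sd_id Between-family standard deviation of true inbreeding
#'   depression, percent (>= 0).
#' @return An object of class `depression_spec`.
#' @export
depression_spec <- function(trait, mean_id, sd_id) {
  stopifnot(is.character(trait), length(trait) == 1L)
  if (!is_number(mean_id) || mean_id < 0 || mean_id >= 100)
    stop_recsel("depression_spec('%s'): mean_id must lie in [0, 100)", trait)
  if (!is_number(sd_id) || sd_id < 0)
    stop_recsel("depression_spec('%s'): sd_id must be >= 0", trait)
  structure(list(trait = trait, mean_id = mean_id, sd_id = sd_id),
            class = "depression_spec")
}

#' Trial design specification
#'
#' Field layout of a progeny trial: number of candidate progenies, check
#' entries, replicates, incomplete blocks per replicate, and ancestry groups.
#' The defaults describe a 14 x 14 triple lattice holding 194 half-sib
#' progenies plus two checks, with progenies tracing back to five ancestry
#' (background) groups.
#'
#' If the number of entries does not divide evenly into
#' `blocks_per_rep` blocks, the last block of each replicate is left short
#' and the generated trial carries the attribute `unbalanced_blocks = TRUE`.
#'
#' @param n_progenies Number of candidate progenies (> 0).
#' @param n_checks Number of check entries (>= 0). Checks carry no family
#'   effect: they are controls, not selection candidates.
#' @param n_reps Number of replicates (> 0).
#' @param blocks_per_rep Number of incomplete blocks nested in each replicate.
#' @param n_ancestry_groups Number of ancestry groups; progenies are assigned
#'   cyclically so groups are near-balanced.
#' @param seed Optional default random seed used by [simulate_trial()] when
#'   no seed is passed there.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_progenies, n_checks = 2L, n_reps = 3L,
                        blocks_per_rep = 14L, n_ancestry_groups = 5L,
                        seed = NULL) {
  for (v in list(n_progenies, n_checks, n_reps, blocks_per_rep, n_ancestry_groups)) {
    if (!is_number(v) || v != round(v)) stop_recsel("design_spec: counts must be integers")
  }
  if (n_progenies < 1) stop_recsel("design_spec: need at least one progeny")
  if (n_checks < 0 || n_reps < 1 || blocks_per_rep < 1 || n_ancestry_groups < 1)
    stop_recsel("design_spec: invalid design counts")
  structure(list(n_progenies = as.integer(n_progenies),
                 n_checks = as.integer(n_checks),
                 n_reps = as.integer(n_reps),
                 blocks_per_rep = as.integer(blocks_per_rep),
                 n_ancestry_groups = as.integer(n_ancestry_groups),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "design_spec")
}

as_trait_list <- function(traits) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (!length(traits) || !all(vapply(traits, inherits, TRUE, "trait_spec")))
    stop_recsel("`traits` must be a trait_spec or a list of trait_spec objects")
  names(traits) <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(names(traits))) stop_recsel("duplicate trait names")
  traits
}

check_corr_matrix <- function(C, t) {
  if (is.null(C)) C <- diag(t)
  C <- as.matrix(C)
  if (!all(dim(C) == c(t, t)))
    stop_recsel("genetic_corr must be %d x %d to match the trait list", t, t)
  if (max(abs(C - t(C))) > 1e-8) stop_recsel("genetic_corr must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8) stop_recsel("genetic_corr must have unit diagonal")
  lam_min <- min(eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < -1e-8)
    stop_recsel("genetic_corr is not positive semi-definite (smallest eigenvalue %.3e)", lam_min)
  C
}

# Correlated family effects: column j of the standard-normal matrix comes
# from its own substream keyed by the trait name, and the correlation is
# imposed with an (upper-triangular) Cholesky factor, so appending a trait
# leaves the effects of earlier traits untouched.
draw_family_effects <- function(n, traits, C, seed) {
  t <- length(traits)
  Z <- matrix(0, n, t)
  for (j in seq_len(t)) {
    Z[, j] <- local_seed(derive_seed(seed, paste0("fam:", names(traits)[j])), stats::rnorm(n))
  }
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) { # PSD but singular within tolerance: eigen square root
    ee <- eigen((C + t(C)) / 2, symmetric = TRUE)
    R <- diag(sqrt(pmax(ee$values, 0))) %*% t(ee$vectors)
  }
  F <- Z %*% R
  for (j in seq_len(t)) F[, j] <- F[, j] * sqrt(traits[[j]]$sigma2_family)
  colnames(F) <- names(traits)
  F
}

trial_columns <- c("progeny_id", "entry_type", "generation", "rep", "block",
                   "plot", "ancestry_group", "trait", "value")

new_trial_table <- function(df) {
  stopifnot(all(trial_columns %in% names(df)))
  df <- df[, trial_columns]
  class(df) <- c("trial_table", "data.frame")
  df
}

# Field layout shared by all traits of one generation: a random entry
# permutation per replicate, cut into blocks_per_rep consecutive blocks.
make_layout <- function(entry_ids, design, seed, stream) {
  n <- length(entry_ids)
  block_size <- ceiling(n / design$blocks_per_rep)
  block_of <- rep(seq_len(design$blocks_per_rep), each = block_size)[seq_len(n)]
  do.call(rbind, lapply(seq_len(design$n_reps), function(r) {
    perm <- local_seed(derive_seed(seed, sprintf("%s:layout:rep%d", stream, r)),
                       sample.int(n))
    data.frame(progeny_id = entry_ids[perm], rep = r, plot = seq_len(n),
               block = block_of, stringsAsFactors = FALSE)
  }))
}

#' Simulate a half-sib (S0) progeny trial with known genetic truth
#'
#' Generates plot-level phenotype records for a lattice-design half-sib
#' trial. Each observation is
#' `base_mean + rep effect + block-within-rep effect + family effect +
#' plot error`, with all effects drawn from zero-mean Gaussians at the
#' configured variances. Family effects of different traits share the
#' supplied genetic correlation matrix; check entries receive no family
#' effect. The same seed reproduces the table bit-for-bit.
#'
#' @param design A [design_spec()].
#' @param traits A list of [trait_spec()] objects (or a single one).
#' @param genetic_corr Genetic correlation matrix among the traits'
#'   family effects (symmetric, unit diagonal, positive semi-definite within
#'   `1e-8`). Defaults to the identity.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A list with components:
#'   \describe{
#'     \item{trial}{`trial_table` data frame with columns `progeny_id`,
#'       `entry_type`, `generation` (`"S0"`), `rep`, `block`, `plot`,
#'       `ancestry_group`, `trait`, `value`. Carries the design, trait list,
#'       correlation matrix and seed as attributes so that [simulate_s1()]
#'       can generate the paired selfed trial.}
#'     \item{truth}{`truth_table` data frame with one row per
#'       (progeny, trait): `true_family_effect`, `true_id` (filled by
#'       [simulate_s1()]), `ancestry_group`.}
#'   }
#' @examples
#' des <- design_spec(n_progenies = 20, n_checks = 2, n_reps = 3,
#'                    blocks_per_rep = 2, seed = 1)
#' gy <- trait_spec("GY", base_mean = 3950, sigma2_family = 9e4,
#'                  sigma2_plot = 3e5)
#' sim <- simulate_trial(des, gy)
#' head(sim$trial)
#' @export
simulate_trial <- function(design, traits, genetic_corr = NULL, seed = design$seed) {
  stopifnot(inherits(design, "design_spec"))
  traits <- as_trait_list(traits)
  if (is.null(seed)) stop_recsel("simulate_trial: a seed is required (argument or design$seed)")
  seed <- as.integer(seed)
  C <- check_corr_matrix(genetic_corr, length(traits))
  dimnames(C) <- list(names(traits), names(traits))

  n_prog <- design$n_progenies
  progeny_ids <- sprintf("P%03d", seq_len(n_prog))
  check_ids <- if (design$n_checks > 0) sprintf("CHK%d", seq_len(design$n_checks)) else character()
  entry_ids <- c(progeny_ids, check_ids)
  groups <- paste0("G", ((seq_len(n_prog) - 1L) %% design$n_ancestry_groups) + 1L)
  names(groups) <- progeny_ids
  group_of <- c(groups, stats::setNames(rep("G1", length(check_ids)), check_ids))

  fam <- draw_family_effects(n_prog, traits, C, seed)
  rownames(fam) <- progeny_ids

  layout <- make_layout(entry_ids, design, seed, "s0")
  pieces <- lapply(names(traits), function(tn) {
    sp <- traits[[tn]]
    rep_eff <- local_seed(derive_seed(seed, paste0("s0:rep:", tn)),
                          stats::rnorm(design$n_reps, 0, sqrt(sp$sigma2_rep)))
    blk_eff <- local_seed(derive_seed(seed, paste0("s0:block:", tn)),
                          matrix(stats::rnorm(design$n_reps * design$blocks_per_rep,
                                              0, sqrt(sp$sigma2_block)),
                                 design$n_reps, design$blocks_per_rep))
    err <- local_seed(derive_seed(seed, paste0("s0:plot:", tn)),
                      stats::rnorm(nrow(layout), 0, sqrt(sp$sigma2_plot)))
    fam_part <- fam[, tn][layout$progeny_id] # named lookup; NA for checks
    fam_part[is.na(fam_part)] <- 0
    data.frame(progeny_id = layout$progeny_id,
               entry_type = ifelse(layout$progeny_id %in% check_ids, "check", "progeny"),
               generation = "S0",
               rep = layout$rep, block = layout$block, plot = layout$plot,
               ancestry_group = unname(group_of[layout$progeny_id]),
               trait = tn,
               value = sp$base_mean + rep_eff[layout$rep] +
                 blk_eff[cbind(layout$rep, layout$block)] + fam_part + err,
               stringsAsFactors = FALSE)
  })
  trial <- new_trial_table(do.call(rbind, pieces))
  rownames(trial) <- NULL
  attr(trial, "design") <- design
  attr(trial, "traits") <- traits
  attr(trial, "genetic_corr") <- C
  attr(trial, "seed") <- seed
  attr(trial, "unbalanced_blocks") <-
    (length(entry_ids) %% design$blocks_per_rep) != 0L

  truth <- data.frame(
    progeny_id = rep(progeny_ids, times = length(traits)),
    trait = rep(names(traits), each = n_prog),
    true_family_effect = as.vector(fam),
    true_id = NA_real_,
    ancestry_group = rep(unname(groups), times = length(traits)),
    stringsAsFactors = FALSE)
  class(truth) <- c("truth_table", "data.frame")

  list(trial = trial, truth = truth)
}

#' Simulate the paired selfed (S1) progeny trial
#'
#' Generates the S1 trial grown alongside an S0 half-sib trial to expose
#' inbreeding depression. For each depressed trait the S1 expected family
#' mean is the S0 expected family mean multiplied by `(1 - true_id/100)`,
#' where each family's true inbreeding depression is drawn from the
#' [depression_spec()] distribution (truncated to (-100, 100)). Replicate,
#' block and plot effects of the S1 field are drawn independently of the S0
#' trial. Only progenies are grown (no checks).
#'
#' @param s0 The S0 `trial_table` produced by [simulate_trial()] (must carry
#'   its simulation attributes).
#' @param truth The matching `truth_table`.
#' @param depression A [depression_spec()] or list of them; traits not
#'   listed are simulated without depression (`true_id = 0`).
#' @param seed Integer seed for the S1 field (independent of the S0 seed).
#' @param selfed Optional character vector of progeny ids that were selfed;
#'   defaults to all progenies.
#' @return A list with `trial` (the S1 `trial_table`) and `truth` (the input
#'   truth table with `true_id` filled in).
#' @export
simulate_s1 <- function(s0, truth, depression, seed, selfed = NULL) {
  design <- attr(s0, "design")
  traits <- attr(s0, "traits")
  if (is.null(design) || is.null(traits))
    stop_recsel("simulate_s1: s0 must be a trial_table produced by simulate_trial()")
  if (inherits(depression, "depression_spec")) depression <- list(depression)
  if (!all(vapply(depression, inherits, TRUE, "depression_spec")))
    stop_recsel("`depression` must be depression_spec objects")
  dep_traits <- vapply(depression, `[[`, "", "trait")
  if (anyDuplicated(dep_traits)) stop_recsel("duplicate depression specs for one trait")
  unknown <- setdiff(dep_traits, names(traits))
  if (length(unknown))
    stop_recsel("depression references unknown trait(s): %s", paste(unknown, collapse = ", "))
  seed <- as.integer(seed)

  progeny_ids <- sprintf("P%03d", seq_len(design$n_progenies))
  if (is.null(selfed)) selfed <- progeny_ids
  if (!all(selfed %in% progeny_ids)) stop_recsel("selfed ids not present in the S0 trial")
  group_of <- truth$ancestry_group[match(progeny_ids, truth$progeny_id)]
  names(group_of) <- progeny_ids

  # true inbreeding depression per family, per depressed trait
  id_of <- matrix(0, length(progeny_ids), length(traits),
                  dimnames = list(progeny_ids, names(traits)))
  for (d in depression) {
    delta <- local_seed(derive_seed(seed, paste0("id:", d$trait)),
                        stats::rnorm(length(progeny_ids), d$mean_id, d$sd_id))
    id_of[, d$trait] <- pmin(pmax(delta, -100 + 1e-9), 100 - 1e-9)
  }
  for (tn in names(traits)) {
    sel <- truth$trait == tn
    truth$true_id[sel] <- if (tn %in% dep_traits)
      id_of[truth$progeny_id[sel], tn] else NA_real_
  }

  fam_mean <- matrix(NA_real_, length(progeny_ids), length(traits),
                     dimnames = list(progeny_ids, names(traits)))
  for (tn in names(traits)) {
    sel <- truth$trait == tn
    fam_mean[truth$progeny_id[sel], tn] <-
      traits[[tn]]$base_mean + truth$true_family_effect[sel]
  }

  s1_design <- design
  s1_design$n_checks <- 0L
  layout <- make_layout(selfed, s1_design, seed, "s1")
  pieces <- lapply(names(traits), function(tn) {
    sp <- traits[[tn]]
    rep_eff <- local_seed(derive_seed(seed, paste0("s1:rep:", tn)),
                          stats::rnorm(design$n_reps, 0, sqrt(sp$sigma2_rep)))
    blk_eff <- local_seed(derive_seed(seed, paste0("s1:block:", tn)),
                          matrix(stats::rnorm(design$n_reps * design$blocks_per_rep,
                                              0, sqrt(sp$sigma2_block)),
                                 design$n_reps, design$blocks_per_rep))
    err <- local_seed(derive_seed(seed, paste0("s1:plot:", tn)),
                      stats::rnorm(nrow(layout), 0, sqrt(sp$sigma2_plot)))
    mu1 <- fam_mean[layout$progeny_id, tn] * (1 - id_of[layout$progeny_id, tn] / 100)
    data.frame(progeny_id = layout$progeny_id,
               entry_type = "progeny", generation = "S1",
               rep = layout$rep, block = layout$block, plot = layout$plot,
               ancestry_group = unname(group_of[layout$progeny_id]),
               trait = tn,
               value = mu1 + rep_eff[layout$rep] +
                 blk_eff[cbind(layout$rep, layout$block)] + err,
               stringsAsFactors = FALSE)
  })
  trial <- new_trial_table(do.call(rbind, pieces))
  rownames(trial) <- NULL
  attr(trial, "design") <- s1_design
  attr(trial, "traits") <- traits
  attr(trial, "seed") <- seed
  list(trial = trial, truth = truth)
}

#' Default study conditions: traits, design and depression of a tropical
#' maize recurrent-selection evaluation
#'
#' Returns the simulation configuration the package uses as its reference
#' scenario: 194 half-sib progenies plus two checks in a 14 x 14 triple
#' lattice (three replicates, 14 incomplete blocks per replicate), five
#' ancestry groups, ten agronomic traits on tropical-maize scales (grain
#' yield around 3950 kg/ha, ear weight around 4800 kg/ha, flowering near 60
#' days, plant height near 2.3 m), moderate genetic correlations among the
#' yield components, and grain-yield inbreeding depression with mean 43% and
#' between-family SD 8%.
#'
#' @param seed Root seed stored in the design.
#' @return A list with elements `design`, `traits`, `genetic_corr`,
#'   `depression`, `weights` (economic weights: grain yield 2, inbreeding
#'   depression 1, all other traits 0), `directions`, and
#'   `selection_fraction` (0.20).
#' @export
default_study <- function(seed = 1L) {
  traits <- list(
    trait_spec("GY", 3950, sigma2_family = 9e4,  sigma2_plot = 3.6e5,
               sigma2_rep = 2e4, sigma2_block = 1e4),
    trait_spec("EW", 4800, sigma2_family = 1.3e5, sigma2_plot = 5.2e5,
               sigma2_rep = 3e4, sigma2_block = 1.5e4),
    trait_spec("NE", 14,   sigma2_family = 0.8,   sigma2_plot = 3.2,
               sigma2_rep = 0.2, sigma2_block = 0.1),
    trait_spec("ED", 14.2, sigma2_family = 0.12,  sigma2_plot = 0.5,
               sigma2_rep = 0.02, sigma2_block = 0.01),
    trait_spec("EL", 4.3,  sigma2_family = 0.02,  sigma2_plot = 0.08,
               sigma2_rep = 0.004, sigma2_block = 0.002),
    trait_spec("MF", 59.5, sigma2_family = 1.2,   sigma2_plot = 3.0,
               sigma2_rep = 0.3, sigma2_block = 0.1),
    trait_spec("FF", 58.5, sigma2_family = 1.2,   sigma2_plot = 3.0,
               sigma2_rep = 0.3, sigma2_block = 0.1),
    trait_spec("PH", 2.25, sigma2_family = 0.004, sigma2_plot = 0.016,
               sigma2_rep = 0.001, sigma2_block = 5e-4, direction = "minimize"),
    trait_spec("EH", 1.01, sigma2_family = 0.002, sigma2_plot = 0.008,
               sigma2_rep = 5e-4, sigma2_block = 2e-4, direction = "minimize"),
    trait_spec("GM", 18,   sigma2_family = 0.5,   sigma2_plot = 2.0,
               sigma2_rep = 0.1, sigma2_block = 0.05)
  )
  nm <- vapply(traits, `[[`, "", "name")
  C <- diag(length(nm)); dimnames(C) <- list(nm, nm)
  set_c <- function(a, b, r) { C[a, b] <<- r; C[b, a] <<- r }
  set_c("GY", "EW", 0.85); set_c("GY", "NE", 0.40); set_c("GY", "ED", 0.35)
  set_c("GY", "EL", 0.30); set_c("EW", "NE", 0.35); set_c("EW", "ED", 0.35)
  set_c("EW", "EL", 0.30); set_c("ED", "EL", 0.25); set_c("MF", "FF", 0.90)
  set_c("PH", "EH", 0.80); set_c("GY", "PH", 0.15); set_c("EW", "PH", 0.15)
  # nudge to exact PSD is unnecessary: smallest eigenvalue is comfortably > 0
  weights <- stats::setNames(rep(0, length(nm) + 1L), c(nm, "ID"))
  weights["GY"] <- 2; weights["ID"] <- 1
  directions <- stats::setNames(vapply(traits, `[[`, "", "direction"), nm)
  directions <- c(directions, ID = "minimize")
  list(design = design_spec(n_progenies = 194, n_checks = 2, n_reps = 3,
                            blocks_per_rep = 14, n_ancestry_groups = 5,
                            seed = as.integer(seed)),
       traits = traits, genetic_corr = C,
       depression = list(depression_spec("GY", mean_id = 43, sd_id = 8)),
       weights = weights, directions = directions,
       selection_fraction = 0.20)
}
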