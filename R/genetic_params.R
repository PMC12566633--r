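#' Family means of candidate progenies
#'
#' Computes per-progeny, per-trait means over available plots. Checks are
#' excluded by default: standardization constants and selection operate on
#' candidate progenies only.
#'
#' @param trial A `trial_table`.
#' @param generation Generation to use (default `"S0"`); `NULL` uses all
#'   rows.
#' @param include_checks Keep check entries (default `FALSE`).
#' @return A data frame of class `family_means` with columns `progeny`,
#'   `trait`, `mean`, `n_plots`.
#' @export
family_means <- function(trial, generation = "S0", include_checks = FALSE) {
  df <- as.data.frame(trial)
  if (!is.null(generation)) df <- df[df$generation %in% generation, , drop = FALSE]
  if (!include_checks) df <- df[df$entry_type == "progeny", , drop = FALSE]
  if (!nrow(df)) stop_recsel("no rows left after filtering the trial")
  agg <- stats::aggregate(value ~ progeny_id + trait, data = df,
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(progeny = agg$progeny_id, trait = agg$trait,
                    mean = agg$value[, "mean"], n_plots = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$trait, out$progeny), ]
  rownames(out) <- NULL
  class(out) <- c("family_means", "data.frame")
  out
}

#' Wide matrix of family means
#'
#' @param fm A `family_means` table.
#' @return A numeric matrix, progenies in rows, traits in columns (`NA`
#'   where a progeny lacks a trait).
#' @export
means_matrix <- function(fm) {
  progs <- sort(unique(fm$progeny))
  traits <- unique(fm$trait)
  M <- matrix(NA_real_, length(progs), length(traits),
              dimnames = list(progs, traits))
  M[cbind(match(fm$progeny, progs), match(fm$trait, traits))] <- fm$mean
  M
}

# Per-trait least-squares fit used both for mean squares and for plot-level
# residuals: value ~ rep (+ block within rep) + family, sequential sums of
# squares (family adjusted for the design terms: intra-block analysis).
trait_anova_fit <- function(df) {
  df$fam_f <- factor(df$progeny_id)
  df$rep_f <- factor(df$rep)
  df$blk_f <- factor(paste(df$rep, df$block, sep = ":"))
  has_rep <- nlevels(df$rep_f) > 1L
  has_blk <- nlevels(df$blk_f) > nlevels(df$rep_f)
  form <- if (has_rep && has_blk) value ~ rep_f + blk_f + fam_f
          else if (has_rep) value ~ rep_f + fam_f
          else value ~ fam_f
  fit <- stats::lm(form, data = df)
  list(fit = fit, df = df, has_rep = has_rep, has_blk = has_blk)
}

#' Half-sib variance components by the method of moments
#'
#' Estimates the between-family variance of one trait from the trial ANOVA:
#' in the balanced case \eqn{\hat\sigma^2_{family} = (MS_{family} -
#' MS_{error})/r} with \eqn{r} replicates; the unbalanced case uses the
#' standard coefficient \eqn{k_1} (weighted average family size). The family
#' mean square is adjusted for replicates and incomplete blocks (intra-block
#' analysis). Replicate and block components are returned as auxiliary
#' method-of-moments estimates. Negative estimates are truncated to 0 and
#' flagged in the `truncated` field.
#'
#' @param trial A `trial_table`.
#' @param trait Trait identifier.
#' @param generation Generation to analyse (default `"S0"`).
#' @return An object of class `variance_components`: `trait`,
#'   `sigma2_family`, `sigma2_rep`, `sigma2_block`, `sigma2_error`, `n_eff`
#'   (harmonic-mean plots per family, the effective replicate number of a
#'   family mean), `ms` (mean squares), `truncated`.
#' @export
anova_components <- function(trial, trait, generation = "S0") {
  df <- as.data.frame(trial)
  df <- df[df$trait == trait & df$entry_type == "progeny", , drop = FALSE]
  if (!is.null(generation)) df <- df[df$generation %in% generation, , drop = FALSE]
  if (!nrow(df)) stop_recsel("trait '%s' not found in the trial", trait)
  n_fam <- length(unique(df$progeny_id))
  if (n_fam < 2L) stop_recsel("anova_components: need at least 2 families")
  if (length(unique(df$rep)) < 2L) stop_recsel("anova_components: need at least 2 replicates")

  out <- list(trait = trait, sigma2_family = 0, sigma2_rep = 0,
              sigma2_block = 0, sigma2_error = 0,
              n_eff = NA_real_, ms = numeric(), truncated = character())
  n_i <- table(df$progeny_id)
  out$n_eff <- length(n_i) / sum(1 / n_i)

  if (stats::var(df$value) < .Machine$double.eps * max(1, mean(df$value)^2)) {
    warn_recsel("trait '%s' is constant: all variance components are 0", trait)
    class(out) <- "variance_components"
    return(out)
  }

  fa <- trait_anova_fit(df)
  tab <- stats::anova(fa$fit)
  ms <- stats::setNames(tab[["Mean Sq"]], rownames(tab))
  out$ms <- ms
  ms_err <- ms[["Residuals"]]
  out$sigma2_error <- ms_err

  N <- nrow(df)
  k1 <- (N - sum(n_i^2) / N) / (n_fam - 1L) # weighted average family size
  s2f <- (ms[["fam_f"]] - ms_err) / k1
  if (s2f < 0) { out$truncated <- c(out$truncated, "family"); s2f <- 0 }
  out$sigma2_family <- s2f

  if (fa$has_rep) {
    n_r <- table(df$rep)
    kr <- (N - sum(n_r^2) / N) / (length(n_r) - 1L)
    s2r <- (ms[["rep_f"]] - ms_err) / kr
    if (s2r < 0) { out$truncated <- c(out$truncated, "rep"); s2r <- 0 }
    out$sigma2_rep <- s2r
  }
  if (fa$has_blk) {
    n_b <- table(paste(df$rep, df$block))
    kb <- mean(n_b)
    s2b <- (ms[["blk_f"]] - ms_err) / kb
    if (s2b < 0) { out$truncated <- c(out$truncated, "block"); s2b <- 0 }
    out$sigma2_block <- s2b
  }
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components for '%s': family %.4g, rep %.4g, block %.4g, error %.4g (n_eff %.2f)\n",
              x$trait, x$sigma2_family, x$sigma2_rep, x$sigma2_block,
              x$sigma2_error, x$n_eff))
  if (length(x$truncated))
    cat("  truncated to 0:", paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

#' Phenotypic and genotypic covariance matrices of family means
#'
#' Builds the Smith–Hazel machinery: the phenotypic covariance matrix `P`
#' of progeny (family) means, the genotypic covariance matrix `G`, and
#' family-mean heritabilities. `P` is the empirical covariance of family
#' means; diagonal elements of `G` come from the half-sib ANOVA estimator
#' ([anova_components()]) and off-diagonals from between-family mean
#' cross-products corrected by the plot-level residual covariance divided by
#' the effective replicate number (the cross-trait analogue of the ANOVA
#' estimator). Residual covariances are computed from plot-matched residuals
#' (same generation, replicate and plot); trait pairs never measured on a
#' common plot get residual covariance 0.
#'
#' By default the matrices are computed on standardized, direction-adjusted
#' family means (each trait centred and scaled by the SD of its family means
#' over candidates, minimize-traits sign-flipped), the same scale on which
#' the selection indexes operate. `G` is conditioned to positive
#' semi-definiteness by eigenvalue bending (eigenvalues below
#' `bend_tol * largest` are raised to that floor); `P` likewise, and a `P`
#' still singular after bending is an error.
#'
#' @param trial A `trial_table` (may contain several generations; each
#'   trait is analysed within the generations where it occurs). Rows for a
#'   derived trait such as inbreeding depression can be appended to the S0
#'   rows before calling.
#' @param traits Traits to include (default: all in `trial`); at least two.
#' @param directions Named character vector (`"maximize"`/`"minimize"`) per
#'   trait; default all maximize.
#' @param standardize Standardize family means (default `TRUE`).
#' @param min_family_coverage Minimum fraction of families that must carry
#'   each trait (default 0.9).
#' @param bend_tol Eigenvalue-bending floor, relative to the largest
#'   eigenvalue (default `1e-6`).
#' @return An object of class `genetic_params`: `traits`, `directions`,
#'   `P`, `G`, `h2_family` (in `[0, 1]`), `components` (per-trait
#'   [anova_components()] on the raw scale), `scale` (centre/SD per trait),
#'   `n_families`, `bent`.
#' @export
estimate_PG <- function(trial, traits = NULL, directions = NULL,
                        standardize = TRUE, min_family_coverage = 0.9,
                        bend_tol = 1e-6) {
  df <- as.data.frame(trial)
  df <- df[df$entry_type == "progeny", , drop = FALSE]
  if (is.null(traits)) traits <- unique(df$trait)
  if (length(traits) < 2L)
    stop_recsel("estimate_PG needs at least 2 traits (got %d)", length(traits))
  missing <- setdiff(traits, unique(df$trait))
  if (length(missing))
    stop_recsel("trait(s) not in trial: %s", paste(missing, collapse = ", "))
  df <- df[df$trait %in% traits, , drop = FALSE]
  if (is.null(directions)) {
    directions <- stats::setNames(rep("maximize", length(traits)), traits)
  } else {
    if (!all(traits %in% names(directions)))
      stop_recsel("directions must name every trait")
    directions <- directions[traits]
  }
  sgn <- ifelse(directions == "minimize", -1, 1)

  fm <- family_means(df, generation = NULL)
  all_fams <- sort(unique(fm$progeny))
  cover <- tapply(fm$progeny, fm$trait, function(p) length(unique(p)))
  low <- cover / length(all_fams) < min_family_coverage
  if (any(low))
    stop_recsel("trait(s) below %.0f%% family coverage: %s",
                100 * min_family_coverage,
                paste(names(cover)[low], collapse = ", "))
  M <- means_matrix(fm)[, traits, drop = FALSE]
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  f <- nrow(M)
  if (f < 3L) stop_recsel("fewer than 3 families with all traits")

  center <- colMeans(M)
  sds <- apply(M, 2, stats::sd)
  if (any(sds <= 0))
    stop_recsel("zero variance among family means for: %s",
                paste(traits[sds <= 0], collapse = ", "))
  Z <- sweep(sweep(M, 2, center), 2, if (standardize) sds else rep(1, length(sds)), "/")
  Z <- sweep(Z, 2, sgn, "*")
  P <- stats::cov(Z)

  # per-trait components and plot-matched residuals
  comps <- list()
  resids <- list()
  dfr <- list()
  for (tn in traits) {
    sub <- df[df$trait == tn, , drop = FALSE]
    comps[[tn]] <- anova_components(sub, tn, generation = NULL)
    fa <- trait_anova_fit(sub)
    key <- paste(sub$generation, sub$rep, sub$plot, sep = "|")
    resids[[tn]] <- stats::setNames(stats::residuals(fa$fit), key)
    dfr[[tn]] <- stats::df.residual(fa$fit)
  }

  scl <- if (standardize) sds else rep(1, length(sds))
  t_n <- length(traits)
  SigE <- matrix(0, t_n, t_n, dimnames = list(traits, traits))
  Neff <- matrix(1, t_n, t_n, dimnames = list(traits, traits))
  for (i in seq_len(t_n)) for (j in i:t_n) {
    ti <- traits[i]; tj <- traits[j]
    if (i == j) {
      SigE[i, i] <- comps[[ti]]$sigma2_error / scl[i]^2
    } else {
      common <- intersect(names(resids[[ti]]), names(resids[[tj]]))
      if (length(common) >= 10L) {
        n_t <- length(resids[[ti]])
        dfp <- length(common) * mean(c(dfr[[ti]] / n_t,
                                       dfr[[tj]] / length(resids[[tj]])))
        cp <- sum(resids[[ti]][common] * resids[[tj]][common]) / dfp
        SigE[i, j] <- SigE[j, i] <-
          sgn[i] * sgn[j] * cp / (scl[i] * scl[j])
      } # else: never co-measured on a plot -> residual covariance 0
    }
    Neff[i, j] <- Neff[j, i] <- sqrt(comps[[ti]]$n_eff * comps[[tj]]$n_eff)
  }

  G <- P - SigE / Neff
  # diagonal from the ANOVA estimator on the (standardized) trait scale
  for (i in seq_len(t_n)) G[i, i] <- comps[[traits[i]]]$sigma2_family / scl[i]^2
  # truncation: genotypic variance within [0, phenotypic variance]
  for (i in seq_len(t_n)) G[i, i] <- min(max(G[i, i], 0), P[i, i])

  G <- bend_psd(G, bend_tol)
  g_bent <- attr(G, "bent")
  P2 <- bend_psd(P, bend_tol)
  p_bent <- attr(P2, "bent")
  if (p_bent)
    warn_recsel("P was rank-deficient (smallest eigenvalue %.3e); eigenvalue bending applied",
                attr(P2, "min_eigenvalue"))
  if (g_bent)
    warn_recsel("G conditioned to positive semi-definiteness by eigenvalue bending")
  P <- P2
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <=
      .Machine$double.eps * max(abs(P)))
    stop_recsel("P singular even after bending (smallest eigenvalue %.3e)",
                min(eigen(P, symmetric = TRUE, only.values = TRUE)$values))

  h2 <- pmin(pmax(diag(G) / diag(P), 0), 1)
  names(h2) <- traits

  structure(list(traits = traits, directions = directions, P = P, G = G,
                 h2_family = h2, components = comps,
                 scale = data.frame(trait = traits, center = center, sd = sds,
                                    sign = sgn, row.names = NULL),
                 standardized = standardize, n_families = f,
                 bent = c(P = p_bent, G = g_bent)),
            class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("Genetic parameters over %d families, %d traits (%s scale)\n",
              x$n_families, length(x$traits),
              if (x$standardized) "standardized" else "raw"))
  cat("  family-mean heritabilities:\n")
  print(round(x$h2_family, 3))
  invisible(x)
}
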