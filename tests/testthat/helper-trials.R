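# Shared fixtures: all built in code at test time.

# Minimal balanced trial data frame: one plot per (family, rep), one block
# per rep unless `blocks` given. `values` is an f x r matrix (families in
# rows) or NULL for N(mu, sd) draws.
make_trial <- function(f, r, values = NULL, trait = "Y", mu = 10, sd = 1,
                       groups = 1L, blocks = 1L, generation = "S0") {
  ids <- sprintf("F%02d", seq_len(f))
  if (is.null(values)) values <- matrix(rnorm(f * r, mu, sd), f, r)
  grp <- paste0("G", ((seq_len(f) - 1L) %% groups) + 1L)
  df <- do.call(rbind, lapply(seq_len(r), function(rep_i) {
    data.frame(progeny_id = ids, entry_type = "progeny",
               generation = generation, rep = rep_i,
               block = ((seq_len(f) - 1L) %% blocks) + 1L,
               plot = seq_len(f), ancestry_group = grp,
               trait = trait, value = values[, rep_i],
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("trial_table", "data.frame")
  df
}

# family_means table from a named-list of per-trait named mean vectors
make_means <- function(trait_means) {
  do.call(rbind, lapply(names(trait_means), function(tn) {
    v <- trait_means[[tn]]
    data.frame(progeny = names(v), trait = tn, mean = unname(v),
               n_plots = 1L, stringsAsFactors = FALSE)
  })) -> df
  class(df) <- c("family_means", "data.frame")
  df
}

# Hand-assembled genetic_params (identity scale so index scores act on the
# raw means), for worked-example tests of the Smith-Hazel solve.
make_params <- function(P, G, traits = colnames(P), h2 = NULL) {
  dimnames(P) <- dimnames(G) <- list(traits, traits)
  structure(list(traits = traits,
                 directions = setNames(rep("maximize", length(traits)), traits),
                 P = P, G = G,
                 h2_family = h2 %||% setNames(pmin(diag(G) / diag(P), 1), traits),
                 components = NULL,
                 scale = data.frame(trait = traits, center = 0, sd = 1, sign = 1),
                 standardized = FALSE, n_families = NA_integer_,
                 bent = c(P = FALSE, G = FALSE)),
            class = "genetic_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-assembled blup_result (for the genotypic-value identity and gains)
make_blup_result <- function(intercept, blups, trait = "GY", pev = NULL) {
  structure(list(trait = trait, intercept = intercept, blups = blups,
                 genotypic_values = intercept + blups,
                 pev = pev %||% (blups * 0), components = c(family = 1, error = 1),
                 fixed = c("(Intercept)" = intercept), converged = TRUE,
                 n_iter = 1L, loglik_trace = numeric(), n_obs = length(blups)),
            class = "blup_result")
}

# Independent GLS/BLUP oracle: direct inversion of the marginal covariance.
# Design matrices are rebuilt here from the raw table, independently of
# build_design().
gls_blup <- function(trial, trait, comps, random_terms = c("rep", "family"),
                     use_groups = FALSE) {
  df <- as.data.frame(trial)
  df <- df[df$trait == trait & df$entry_type == "progeny", ]
  df <- df[order(df$rep, df$plot), ]
  n <- nrow(df)
  X <- matrix(1, n, 1)
  if (use_groups && length(unique(df$ancestry_group)) > 1) {
    g <- factor(df$ancestry_group)
    X <- cbind(X, model.matrix(~g)[, -1, drop = FALSE])
  }
  V <- diag(comps[["error"]], n)
  Zf <- NULL
  for (term in random_terms) {
    fac <- switch(term,
                  family = factor(df$progeny_id),
                  rep = factor(df$rep),
                  block = factor(paste(df$rep, df$block)))
    Z <- model.matrix(~ 0 + fac)
    V <- V + comps[[term]] * tcrossprod(Z)
    if (term == "family") Zf <- Z
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% df$value)
  u <- comps[["family"]] * t(Zf) %*% Vi %*% (df$value - X %*% beta)
  list(beta = drop(beta),
       blups = setNames(drop(u), levels(factor(df$progeny_id))))
}

# Small multivariate-normal draw via Cholesky (test-side oracle helper)
rmvn <- function(n, Sigma) {
  matrix(rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
}
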