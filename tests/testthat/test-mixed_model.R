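test_that("design structures have the expected dimensions", {
  trial <- make_trial(2, 2)
  d <- build_design(trial, model_spec("Y", random_terms = c("rep", "family")))
  expect_equal(ncol(d$X), 1L) # single ancestry group: intercept only
  expect_equal(unname(d$q), c(2L, 2L))

  trial3 <- make_trial(9, 2, groups = 3L)
  d3 <- build_design(trial3, model_spec("Y", random_terms = c("rep", "family")))
  expect_equal(ncol(d3$X), 3L) # intercept + 2 group contrasts

  expect_error(build_design(trial, model_spec("nope")), "available traits")
  mixed_gen <- rbind(trial, transform(trial, generation = "S1"))
  expect_error(build_design(recsel:::new_trial_table(mixed_gen), model_spec("Y")),
               "generations")
})

test_that("a progeny cannot sit in two ancestry groups", {
  trial <- make_trial(4, 2, groups = 2L)
  trial$ancestry_group[1] <- "G2" # F01 now appears in G1 and G2
  expect_error(build_design(trial, model_spec("Y", random_terms = "family")),
               "more than one ancestry group")
})

test_that("balanced one-way BLUP equals the closed-form shrinkage", {
  set.seed(8)
  f <- 12
  y <- rnorm(f, 50, 4)
  trial <- make_trial(f, 1, matrix(y, f, 1))
  fit <- reml_fit(trial, model_spec("Y", random_terms = "family"),
                  components = c(family = 1, error = 1))
  expected <- 0.5 * (y - mean(y))
  expect_lt(max(abs(unname(fit$blups) - expected)), 1e-10)
  expect_equal(fit$intercept, mean(y), tolerance = 1e-10)
})

test_that("shrinkage grows with the noise-to-signal ratio", {
  set.seed(9)
  y <- rnorm(10, 0, 2)
  trial <- make_trial(10, 1, matrix(y, 10, 1))
  prev <- Inf
  for (s2e in c(0.5, 1, 2, 8)) {
    fit <- reml_fit(trial, model_spec("Y", random_terms = "family"),
                    components = c(family = 1, error = s2e))
    expect_true(all(abs(fit$blups) <= prev + 1e-12))
    prev <- abs(fit$blups)
  }
})

test_that("constant response collapses to zero components and BLUPs", {
  trial <- make_trial(6, 3, matrix(42, 6, 3))
  expect_warning(fit <- reml_fit(trial, model_spec("Y", random_terms = c("rep", "family"))),
                 "constant")
  expect_equal(fit$intercept, 42)
  expect_true(all(fit$blups == 0))
  expect_true(all(fit$components == 0))
})

test_that("Henderson's equations agree with direct GLS on random instances", {
  set.seed(101)
  for (i in 1:20) {
    f <- sample(4:8, 1); r <- sample(2:3, 1)
    use_grp <- i %% 2 == 0
    trial <- make_trial(f, r, mu = 20, sd = 3, groups = if (use_grp) 2L else 1L)
    comps <- c(rep = runif(1, .1, 2), family = runif(1, .1, 2),
               error = runif(1, .2, 2))
    spec <- model_spec("Y", random_terms = c("rep", "family"),
                       fixed_terms = if (use_grp) c("intercept", "ancestry_group")
                                     else "intercept")
    fit <- reml_fit(trial, spec, components = comps)
    oracle <- gls_blup(trial, "Y", comps, c("rep", "family"), use_groups = use_grp)
    expect_lt(max(abs(fit$blups - oracle$blups[names(fit$blups)])), 1e-8)
    expect_lt(max(abs(unname(fit$fixed) - oracle$beta)), 1e-8)
  }
})

test_that("EM-REML matches lme4 on a simulated trial", {
  skip_if_not_installed("lme4")
  des <- design_spec(n_progenies = 120, n_checks = 0, n_reps = 3,
                     blocks_per_rep = 1, n_ancestry_groups = 1)
  tr <- trait_spec("Y", 100, sigma2_family = 25, sigma2_plot = 50,
                   sigma2_rep = 5)
  sim <- simulate_trial(des, tr, seed = 55)
  fit <- reml_fit(sim$trial, model_spec("Y", random_terms = c("rep", "family"),
                                        convergence_tol = 1e-10, max_iter = 2000))
  expect_true(fit$converged)

  df <- as.data.frame(sim$trial)
  lmer_fit <- lme4::lmer(value ~ 1 + (1 | rep) + (1 | progeny_id), data = df,
                         REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$components["family"]), unname(ref["progeny_id"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$components["rep"]), unname(ref["rep"]),
               tolerance = 5e-2) # 3-level term: flattest likelihood direction
  expect_equal(unname(fit$components["error"]), unname(ref["Residual"]),
               tolerance = 1e-3)
  blup_ref <- lme4::ranef(lmer_fit)$progeny_id[, 1]
  names(blup_ref) <- rownames(lme4::ranef(lmer_fit)$progeny_id)
  expect_gt(cor(fit$blups, blup_ref[names(fit$blups)]), 0.99999)
})

test_that("the EM log-likelihood trace is non-decreasing", {
  des <- design_spec(n_progenies = 60, n_checks = 0, n_reps = 3,
                     blocks_per_rep = 1)
  tr <- trait_spec("Y", 10, 1, 4, sigma2_rep = 0.5)
  sim <- simulate_trial(des, tr, seed = 4)
  fit <- reml_fit(sim$trial, model_spec("Y", random_terms = c("rep", "family")))
  d <- diff(fit$loglik_trace)
  expect_true(all(d >= -1e-6 * pmax(abs(fit$loglik_trace[-1]), 1)))
})

test_that("BLUPs recover true family effects at the expected accuracy", {
  # family-mean h2 = 0.25: corr(BLUP, truth) should approach sqrt(0.25)
  des <- design_spec(n_progenies = 500, n_checks = 0, n_reps = 3,
                     blocks_per_rep = 1, n_ancestry_groups = 1)
  tr <- trait_spec("Y", 10, sigma2_family = 1, sigma2_plot = 9)
  sim <- simulate_trial(des, tr, seed = 61)
  fit <- reml_fit(sim$trial, model_spec("Y", random_terms = c("rep", "family"),
                                        convergence_tol = 1e-8))
  truth <- setNames(sim$truth$true_family_effect, sim$truth$progeny_id)
  acc <- cor(fit$blups, truth[names(fit$blups)])
  h2 <- 1 / (1 + 9 / 3)
  se <- (1 - h2) / sqrt(500) # crude large-sample SE for the correlation
  expect_lt(abs(acc - sqrt(h2)), 3 * se)
  expect_lt(abs(fit$components["family"] - 1), 3 * sqrt(2 / 500 * (1 + 9 / 3)^2))
  # balanced design: BLUPs centred at zero
  expect_lt(abs(mean(fit$blups)), 1e-6 * sd(fit$blups))
})

test_that("genotypic value minus BLUP is the constant reported base mean", {
  des <- design_spec(n_progenies = 50, n_checks = 2, n_reps = 3,
                     blocks_per_rep = 2, n_ancestry_groups = 3)
  tr <- trait_spec("Y", 10, 1, 2, sigma2_rep = .2, sigma2_block = .1)
  sim <- simulate_trial(des, tr, seed = 17)
  fit <- reml_fit(sim$trial, model_spec("Y"))
  gap <- fit$genotypic_values - fit$blups
  expect_true(all(abs(gap - fit$intercept) < 1e-12))
})

test_that("predicted genotypic values sort by direction with stable ties", {
  res <- make_blup_result(100, c(a = 5, b = -3, c = 5, d = 0))
  up <- predict_genotypic_values(res, "maximize")
  expect_identical(up$progeny, c("a", "c", "d", "b"))
  down <- predict_genotypic_values(res, "minimize")
  expect_identical(down$progeny, c("b", "d", "a", "c"))
  expect_equal(up$genotypic_value, up$blup + 100)
})

test_that("non-convergence is reported, not silent", {
  des <- design_spec(n_progenies = 40, n_checks = 0, n_reps = 3,
                     blocks_per_rep = 1)
  tr <- trait_spec("Y", 10, 1, 4)
  sim <- simulate_trial(des, tr, seed = 2)
  expect_warning(
    fit <- reml_fit(sim$trial, model_spec("Y", random_terms = "family",
                                          convergence_tol = 1e-14, max_iter = 3)),
    "did not converge")
  expect_false(fit$converged)
})
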