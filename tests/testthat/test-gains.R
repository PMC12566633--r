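test_that("inbreeding depression follows the relative-loss formula", {
  expect_equal(inbreeding_depression(100, 60), 40)
  expect_equal(inbreeding_depression(4000, 4000), 0)
  expect_equal(inbreeding_depression(4000, 4400), -10) # heterotic S1, kept
  expect_error(inbreeding_depression(0, 5), "m0 = 0")
  expect_error(inbreeding_depression(NA, 5), "finite")
})

test_that("inbreeding depression is scale-invariant", {
  set.seed(3)
  m0 <- runif(50, 1, 10); m1 <- runif(50, 1, 10)
  for (cc in c(0.001, 3, -7)) {
    expect_equal(inbreeding_depression(cc * m0, cc * m1),
                 inbreeding_depression(m0, m1), tolerance = 1e-12)
  }
})

test_that("rep-level depression pairs matching replicates", {
  vals0 <- matrix(c(100, 200, 80, 160), 2, 2) # families x reps
  vals1 <- matrix(c(50, 150, 60, 80), 2, 2)
  s0 <- make_trial(2, 2, vals0, trait = "GY")
  s1 <- make_trial(2, 2, vals1, trait = "GY", generation = "S1")
  idt <- id_table(s0, s1, "GY", level = "rep")
  expect_equal(nrow(idt), 4L)
  got <- idt$value[idt$progeny_id == "F01"]
  expect_equal(sort(got), sort(c(100 * (100 - 50) / 100, 100 * (80 - 60) / 80)))
  fam <- id_table(s0, s1, "GY", level = "family")
  expect_equal(fam$value[fam$progeny_id == "F02"],
               100 * (180 - 115) / 180)
})

test_that("selecting everyone gives zero differential gain", {
  m <- make_means(list(GY = setNames(1:10, sprintf("P%02d", 1:10))))
  rep <- predicted_gain(sprintf("P%02d", 1:10), m, mode = "differential")
  expect_equal(rep$PG_abs, 0)
  expect_equal(rep$PG_pct, 0)
})

test_that("heritability one makes both gain modes coincide", {
  ids <- sprintf("P%02d", 1:10)
  m <- make_means(list(GY = setNames(seq(10, 100, 10), ids),
                       ID = setNames(seq(50, 5, -5), ids)))
  p <- make_params(diag(2), diag(2), c("GY", "ID"),
                   h2 = c(GY = 1, ID = 1))
  sel <- ids[8:10]
  d <- predicted_gain(sel, m, p, mode = "differential")
  h <- predicted_gain(sel, m, p, mode = "heritability_adjusted")
  expect_equal(d$PG_abs, h$PG_abs)
  expect_equal(d$PG_pct, h$PG_pct)
})

test_that("percent gain is the absolute gain over the base mean", {
  ids <- sprintf("P%02d", 1:8)
  m <- make_means(list(GY = setNames(c(4, 4, 4, 4, 5, 5, 6, 8), ids)))
  rep <- predicted_gain(ids[7:8], m, mode = "differential")
  expect_equal(rep$Xs, 7)
  expect_equal(rep$X0, 5)
  expect_equal(rep$PG_abs, 2)
  expect_equal(rep$PG_pct, 100 * 2 / 5)
})

test_that("BLUP strategies report the mean of selected shrunken effects", {
  blups <- setNames(c(300, 200, 100, -100, -500), sprintf("P%02d", 1:5))
  fit <- make_blup_result(4000, blups, trait = "GY")
  ids <- sprintf("P%02d", 1:5)
  m <- make_means(list(GY = setNames(4000 + blups, ids)))
  p <- make_params(diag(1), diag(1), "GY", h2 = c(GY = 0.5))
  rep <- predicted_gain(ids[1:2], m, p, blup = fit)
  gy <- rep[rep$trait == "GY", ]
  expect_equal(gy$PG_abs, 250)
  expect_equal(gy$PG_pct, 100 * 250 / 4000)
  expect_equal(gy$mode, "blup")
})

test_that("heritability-adjusted gain requires heritabilities", {
  m <- make_means(list(GY = setNames(1:5, sprintf("P%02d", 1:5))))
  expect_error(predicted_gain("P05", m, mode = "heritability_adjusted"),
               "needs `params`")
})

test_that("aggregate percent gain sums absolute per-trait contributions", {
  ids <- sprintf("P%02d", 1:6)
  m <- make_means(list(GY = setNames(c(1, 2, 3, 4, 5, 6), ids),
                       ID = setNames(c(60, 50, 40, 30, 20, 10), ids)))
  dirs <- c(GY = "maximize", ID = "minimize")
  rep <- predicted_gain(ids[5:6], m, mode = "differential")
  expect_equal(attr(rep, "total_pct"), sum(abs(rep$PG_pct)))
  rep2 <- predicted_gain(ids[5:6], m, mode = "differential", total = "signed")
  expect_equal(attr(rep2, "total_pct"), sum(rep2$PG_pct))
})

test_that("realized gains compare populations against base and prediction", {
  pops <- make_trial(3, 3, matrix(c(5620, 5600, 5640,
                                    4760, 4770, 4750,
                                    4650, 4640, 4660), 3, 3, byrow = TRUE))
  pops$progeny_id <- rep(c("PopBLUP_GY", "PopBIA", "PopSHI"), 3)
  pops$trait <- "GY"
  pred <- data.frame(population = c("PopBLUP_GY", "PopBIA"),
                     trait = "GY", predicted = c(4025, 4597))
  rc <- realized_gain(pops, base_reference = c(GY = 4480), predicted = pred)
  blup_row <- rc[rc$population == "PopBLUP_GY", ]
  expect_equal(blup_row$realized_mean, 5620)
  expect_equal(blup_row$difference, 5620 - 4025)
  expect_equal(blup_row$gain_abs, 5620 - 4480)
  # realized equal to predicted -> zero difference
  rc2 <- realized_gain(pops, base_reference = c(GY = 4480),
                       predicted = data.frame(population = "PopSHI",
                                              trait = "GY", predicted = 4650))
  expect_equal(rc2$difference[rc2$population == "PopSHI"], 0)
  expect_error(realized_gain(pops, 0, populations = "PopXXX"), "absent")
})

test_that("a check trial can serve as the base reference", {
  pops <- make_trial(1, 2, matrix(c(5000, 5100), 1, 2), trait = "GY")
  pops$progeny_id <- "PopMMI"
  checks <- make_trial(2, 1, matrix(c(4400, 4600), 2, 1), trait = "GY")
  rc <- realized_gain(pops, base_reference = checks)
  expect_equal(rc$base_mean, 4500)
  expect_equal(rc$gain_abs, 5050 - 4500)
})

test_that("predicted gain approaches the realized genetic gain (breeder's equation)", {
  # heritability-adjusted gain for top-20% truncation vs the mean true
  # family effect of the selected set, averaged over 200 simulated trials
  des <- design_spec(n_progenies = 100, n_checks = 0, n_reps = 3,
                     blocks_per_rep = 1, n_ancestry_groups = 1)
  tr <- trait_spec("Y", 50, sigma2_family = 4, sigma2_plot = 12)
  dummy <- trait_spec("D", 0, 1, 1)
  pairs <- vapply(1:200, function(s) {
    sim <- simulate_trial(des, list(tr, dummy), seed = 3000 + s)
    pg <- estimate_PG(sim$trial, standardize = FALSE)
    fm <- family_means(sim$trial)
    sel <- select_top(base_index(fm, c(Y = 1), traits = c("Y", "D")),
                      fraction = 0.2)
    rep <- predicted_gain(sel, fm, pg, mode = "heritability_adjusted",
                          traits = "Y")
    truth <- setNames(sim$truth$true_family_effect[sim$truth$trait == "Y"],
                      sim$truth$progeny_id[sim$truth$trait == "Y"])
    c(pred = rep$PG_abs, real = mean(truth[sel$selected]))
  }, c(pred = 0, real = 0))
  d <- pairs["pred", ] - pairs["real", ]
  se <- sd(d) / sqrt(ncol(pairs))
  expect_lt(abs(mean(d)), 3 * se)
})
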