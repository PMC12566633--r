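means3 <- make_means(list(
  GY = c(A = 5, B = 4, C = 3),
  ID = c(A = 30, B = 40, C = 50)))

test_that("single-trait base index ranks like the raw means", {
  m <- make_means(list(GY = c(A = 5, B = 3, C = 4, D = 6)))
  r <- base_index(m, c(GY = 1))
  expect_identical(r$ranking, c("D", "A", "C", "B"))
  z <- (c(A = 5, B = 3, C = 4, D = 6) - 4.5) / sd(c(5, 3, 4, 6))
  expect_equal(r$scores[names(z)], z)
})

test_that("base index is the weighted sum of direction-adjusted z-scores", {
  # hand-built case: progeny with GY z = +1 and ID z = -0.5 (minimized)
  # must score 2 * 1 + 1 * 0.5 = 2.5
  m <- means3
  dirs <- c(GY = "maximize", ID = "minimize")
  r <- base_index(m, c(GY = 2, ID = 1), dirs)
  zg <- (5 - 4) / 1 # sd of (5,4,3) is 1
  zi <- -(30 - 40) / 10 # sd of (30,40,50) is 10, sign-flipped
  expect_equal(unname(r$scores["A"]), 2 * zg + 1 * zi)
  expect_identical(r$ranking, c("A", "B", "C"))
})

test_that("a lone minimize-trait reverses the raw-mean ranking", {
  m <- make_means(list(ID = c(A = 30, B = 40, C = 50)))
  r <- base_index(m, c(ID = 1), c(ID = "minimize"))
  expect_identical(r$ranking, c("A", "B", "C"))
  r2 <- base_index(m, c(ID = 1), c(ID = "maximize"))
  expect_identical(r2$ranking, rev(r$ranking))
})

test_that("zero-SD traits with selection weight are rejected", {
  m <- make_means(list(GY = c(A = 5, B = 5, C = 5)))
  expect_error(base_index(m, c(GY = 1)), "zero SD")
  expect_error(base_index(means3, c(GY = 0, ID = 0)), "nonzero")
})

test_that("identity P and G hand the economic weights straight through", {
  p <- make_params(diag(2), diag(2), c("GY", "ID"))
  r <- smith_hazel(means3, p, c(GY = 2, ID = 1))
  expect_equal(unname(r$b), c(2, 1))
  # identity scale constants: scores act on the raw means, 2*GY + ID
  raw <- 2 * c(A = 5, B = 4, C = 3) + c(A = 30, B = 40, C = 50)
  expect_identical(r$ranking, names(sort(-raw)))
})

test_that("the worked 2x2 Smith-Hazel system solves to b = (1, 0.5)", {
  P <- matrix(c(4, 1, 1, 2), 2)
  G <- matrix(c(2, 0.5, 0.5, 1), 2)
  p <- make_params(P, G, c("GY", "ID"))
  r <- smith_hazel(means3, p, c(GY = 2, ID = 1))
  expect_equal(unname(r$b), c(1, 0.5), tolerance = 1e-12)
})

test_that("the index solve matches brute-force inversion on random PD systems", {
  set.seed(33)
  m <- make_means(list(GY = c(A = 1, B = 2, C = 3), ID = c(A = 3, B = 2, C = 1)))
  for (i in 1:50) {
    L <- matrix(rnorm(4), 2); P <- crossprod(L) + diag(2) * .1
    Lg <- matrix(rnorm(4), 2); G <- crossprod(Lg)
    a <- rnorm(2)
    names(a) <- c("GY", "ID")
    p <- make_params(P, G, c("GY", "ID"))
    r <- smith_hazel(m, p, a)
    expect_lt(max(abs(r$b - drop(solve(P) %*% G %*% a))), 1e-10)
  }
})

test_that("a zero G matrix yields zero index scores with a warning", {
  p <- make_params(diag(2), matrix(0, 2, 2), c("GY", "ID"))
  expect_warning(r <- smith_hazel(means3, p, c(GY = 2, ID = 1)),
                 "no heritable variation")
  expect_true(all(r$scores == 0))
})

test_that("rank summation reproduces the brute-force weighted rank sums", {
  dirs <- c(GY = "maximize", ID = "minimize")
  r <- rank_sum(means3, c(GY = 2, ID = 1), dirs)
  expect_equal(unname(r$scores[c("A", "B", "C")]), c(3, 6, 9))
  expect_identical(r$ranking, c("A", "B", "C"))
})

test_that("rank summation averages ties and breaks equal totals by identifier", {
  m <- make_means(list(GY = c(A = 5, B = 5, C = 3)))
  r <- rank_sum(m, c(GY = 1))
  expect_equal(unname(r$scores[c("A", "B", "C")]), c(1.5, 1.5, 3))
  expect_identical(r$ranking[1:2], c("A", "B")) # identifier order on the tie
})

test_that("rank summation is invariant to monotone per-trait transforms", {
  set.seed(12)
  v1 <- setNames(runif(15, 1, 9), sprintf("P%02d", 1:15))
  v2 <- setNames(runif(15, 1, 9), sprintf("P%02d", 1:15))
  m <- make_means(list(A = v1, B = v2))
  mt <- make_means(list(A = exp(v1), B = v2^3))
  dirs <- c(A = "maximize", B = "minimize")
  expect_identical(rank_sum(m, c(A = 2, B = 1), dirs)$ranking,
                   rank_sum(mt, c(A = 2, B = 1), dirs)$ranking)
})

test_that("index scores are invariant to affine rescaling of trait units", {
  set.seed(77)
  v1 <- setNames(rnorm(20, 4000, 300), sprintf("P%02d", 1:20))
  v2 <- setNames(rnorm(20, 40, 8), sprintf("P%02d", 1:20))
  m <- make_means(list(GY = v1, ID = v2))
  m2 <- make_means(list(GY = 0.001 * v1 + 5, ID = 10 * v2 - 3))
  dirs <- c(GY = "maximize", ID = "minimize")
  a <- c(GY = 2, ID = 1)
  expect_equal(base_index(m, a, dirs)$scores, base_index(m2, a, dirs)$scores,
               tolerance = 1e-10)
})

test_that("select_top honours fraction flooring and bounds", {
  scores <- setNames(rnorm(194), sprintf("P%03d", 1:194))
  r <- recsel:::new_selection_result("BIA", scores,
                                     recsel:::order_scores(scores, TRUE), TRUE)
  expect_equal(select_top(r, fraction = 0.20)$k, 38L)
  expect_length(select_top(r, fraction = 0.20)$selected, 38L)
  expect_identical(select_top(r, k = 194)$selected, r$ranking)
  expect_identical(select_top(r, k = 1)$selected, r$ranking[1])
  expect_error(select_top(r, k = 195), "out of range")
  expect_identical(select_top(r, fraction = 0.001)$k, 1L) # floor bounded at 1
})

test_that("Smith-Hazel beats the base index on expected aggregate genotype", {
  # truncation on SHI scores should realize at least the aggregate
  # genetic merit of base-index truncation (within Monte-Carlo error)
  set.seed(2024)
  G <- matrix(c(1, .2, .2, .5), 2)
  E <- matrix(c(2, -.6, -.6, 1), 2)
  P <- G + E
  a <- c(GY = 2, ID = 1)
  p <- make_params(P, G, c("GY", "ID"))
  diffs <- replicate(200, {
    g <- rmvn(100, G); e <- rmvn(100, E)
    x <- g + e
    ids <- sprintf("P%03d", 1:100)
    m <- make_means(list(GY = setNames(x[, 1], ids), ID = setNames(x[, 2], ids)))
    shi <- select_top(smith_hazel(m, p, a), k = 20)
    bia <- select_top(base_index(m, a), k = 20)
    agg <- function(sel) mean(g[match(sel$selected, ids), ] %*% c(2, 1))
    agg(shi) - agg(bia)
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_gt(mean(diffs), -3 * se)
})

test_that("selection files round-trip", {
  scores <- setNames(rnorm(10), sprintf("P%02d", 1:10))
  r <- recsel:::new_selection_result("MMI", scores,
                                     recsel:::order_scores(scores, FALSE), FALSE)
  r <- select_top(r, k = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_selection(r, csv)
  ids <- read_selection_ids(sub("\\.csv$", "_selected.txt", csv))
  expect_identical(ids, r$selected)
  tab <- read.csv(csv, colClasses = c(progeny = "character"))
  expect_identical(tab$progeny[tab$selected], r$selected)
})
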