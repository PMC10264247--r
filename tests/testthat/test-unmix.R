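test_that("mixture log-likelihood evaluates the two-multinomial model", {
  # identical profiles: likelihood is flat in w
  for (w in c(0, 0.3, 1))
    expect_equal(mixture_loglik(c(2, 2), c(0.5, 0.5), c(0.5, 0.5), w),
                 4 * log(0.5), tolerance = 1e-12)
  # w = 1 reduces to a pure mark-1 multinomial
  y <- c(3, 0, 5); p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.2, 0.2)
  expect_equal(mixture_loglik(y, p, q, 1), sum(y * log(p)),
               tolerance = 1e-12)
  expect_equal(mixture_loglik(c(3, 1), c(0.9, 0.1), c(0.2, 0.8), 0.5),
               3 * log(0.55) + log(0.45), tolerance = 1e-12)
  # positive counts at zero mixture mass: -Inf, flagged
  ll0 <- mixture_loglik(c(0, 4), c(1, 0), c(1, 0), 1)
  expect_true(is.infinite(ll0) && ll0 < 0)
  expect_true(attr(ll0, "flagged"))
  expect_equal(mixture_loglik(c(4, 0), c(1, 0), c(1, 0), 1), 4 * log(1))
})

test_that("w estimation finds boundary optima and flags flat likelihoods", {
  # support only where q = 0 forces w to 1
  y <- c(5, 7, 0); p <- c(0.5, 0.4, 0.1); q <- c(0, 0, 1)
  fit <- estimate_w(y, p, q)
  expect_equal(fit$w_hat, 1, tolerance = 1e-6)
  flat <- estimate_w(c(2, 3), c(0.4, 0.6), c(0.4, 0.6))
  expect_true(flat$flagged)
  expect_equal(flat$w_hat, 0.5)
  # simulated mixture at known w is recovered
  set.seed(101)
  p <- rsimplex(100); q <- rsimplex(100)
  y <- rmix_counts(10000, p, q, 0.3)
  expect_lt(abs(estimate_w(y, p, q)$w_hat - 0.3), 0.02)
})

test_that("profiled likelihood in w is unimodal on a grid", {
  set.seed(7)
  for (rep in 1:20) {
    p <- rsimplex(30); q <- rsimplex(30)
    y <- rmix_counts(500, p, q, stats::runif(1))
    ll <- vapply(seq(0, 1, length.out = 101),
                 function(w) mixture_loglik(y, p, q, w), numeric(1))
    d <- diff(ll) > 0
    # once the likelihood starts decreasing it never rises again
    expect_lte(sum(diff(d) == 1), 0)
  }
})

test_that("assignment probabilities follow the posterior odds formula", {
  expect_equal(assignment_probabilities(0.2, 0.2, 0.5), 0.5)
  expect_equal(assignment_probabilities(0.3, 0, 0.7), 1)
  expect_equal(assignment_probabilities(0.1, 0.3, 0.7),
               0.07 / (0.07 + 0.09), tolerance = 1e-12)
  masked <- assignment_probabilities(c(0, 0.5), c(0, 0.5), 0.5)
  expect_true(is.na(masked[1]) && masked[2] == 0.5)
})

test_that("count splitting conserves reads and honors the mode", {
  y <- c(4, 0, 9)
  all1 <- split_counts(y, c(1, NA, 1), seed = 2)
  expect_equal(all1$y1, y)
  expect_equal(all1$y2, rep(0, 3))
  set.seed(3)
  for (rep in 1:10) {
    yy <- stats::rpois(50, 4)
    P <- stats::runif(50)
    sp <- split_counts(yy, P, seed = rep)
    expect_identical(sp$y1 + sp$y2, as.numeric(yy))
    expect_true(all(sp$y1 == round(sp$y1) & sp$y1 >= 0))
  }
  ex <- split_counts(c(10, 10), c(0.25, 0.75), mode = "expected")
  expect_equal(ex$y1, c(2.5, 7.5))
  expect_equal(ex$y2, c(7.5, 2.5))
  expect_error(split_counts(c(1, 2), c(NA, 0.5)), "undefined")
})

test_that("mark ratio is the log2 balance of unmixed totals", {
  expect_equal(mark_ratio(list(y1 = c(5, 5), y2 = c(7, 3)),
                          pseudocount = 0), 0)
  expect_equal(mark_ratio(list(y1 = 200, y2 = 50), pseudocount = 0), 2)
  expect_error(mark_ratio(list(y1 = 10, y2 = 0), pseudocount = 0),
               "zero")
})

test_that("pair selection maximizes the profiled likelihood", {
  fx <- tiny_benchmark()
  # single-cluster profiles: only one pair exists, chosen with certainty
  one1 <- structure(list(P = fx$prof1$P[, 1, drop = FALSE],
                         labels = "a"), class = "cluster_profiles")
  one2 <- structure(list(P = fx$prof2$P[, 1, drop = FALSE],
                         labels = "b"), class = "cluster_profiles")
  y <- as.numeric(fx$sim$double$counts[, 1])
  fit1 <- select_pair(y, one1, one2)
  expect_identical(unname(fit1$pair), c(colnames(one1$P),
                                        colnames(one2$P)))
  expect_equal(fit1$confidence, 1)
  # a deep draw from a specific pair mixture selects that pair
  set.seed(11)
  y_deep <- rmix_counts(1e5, fx$prof1$P[, 2], fx$prof2$P[, 1], 0.5)
  fit2 <- select_pair(y_deep, fx$prof1, fx$prof2)
  expect_identical(unname(fit2$pair),
                   c(colnames(fx$prof1$P)[2], colnames(fx$prof2$P)[1]))
  expect_equal(sum(fit2$loglik_table$posterior), 1, tolerance = 1e-12)
})

test_that("dataset-level unmixing conserves cells and counts", {
  fx <- tiny_benchmark()
  dbl <- subset_cells(fx$sim$double, 1:30)
  res <- unmix_dataset(dbl, fx$model1, fx$model2,
                       fx$sim$mark1$cells$celltype,
                       fx$sim$mark2$cells$celltype,
                       confidence_threshold = 0, seed = 5)
  expect_identical(nrow(res$fits), 30L)
  expect_false(any(res$fits$flagged))  # threshold 0 removes nothing
  expect_equal(as.matrix(res$unmixed1$counts + res$unmixed2$counts),
               as.matrix(dbl$counts))
  expect_identical(nrow(res$latent1), 30L)
  expect_identical(ncol(res$latent1), fx$model1$K)
  # a strict threshold retains flagged cells in the report
  res99 <- unmix_dataset(dbl, fx$model1, fx$model2,
                         fx$sim$mark1$cells$celltype,
                         fx$sim$mark2$cells$celltype,
                         confidence_threshold = 1 + 1e-9, seed = 5)
  expect_identical(nrow(res99$fits), 30L)
  expect_true(all(res99$fits$flagged))
  expect_null(res99$latent1)
})

test_that("assignment probabilities are calibrated on deep double cells", {
  fx <- tiny_benchmark()
  p <- fx$prof1$P[, 1]; q <- fx$prof2$P[, 1]
  set.seed(21)
  y1 <- as.numeric(stats::rmultinom(1, 5e6, p))
  y2 <- as.numeric(stats::rmultinom(1, 5e6, q))
  y <- y1 + y2
  P <- assignment_probabilities(p, q, 0.5)
  keep <- y > 20000
  expect_gt(sum(keep), 20)
  emp <- y1[keep] / y[keep]
  expect_lt(max(abs(emp - P[keep])), 0.02)
})
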