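test_that("fitted factors live on the simplex and fits are reproducible", {
  fx <- tiny_benchmark()
  m <- fx$model1
  expect_equal(unname(colSums(m$V)), rep(1, m$K), tolerance = 1e-9)
  expect_equal(unname(colSums(m$U)), rep(1, ncol(m$U)), tolerance = 1e-9)
  expect_true(all(m$V >= 0) && all(m$U >= 0))
  expect_identical(eval(formals(fit_lda)$K), 30L)
  expect_identical(formals(fit_lda)$alpha, 1.67)
  expect_identical(formals(fit_lda)$delta, 0.1)
  refit <- fit_lda(fx$sim$mark1, K = 4, n_iter = 120, burn_in = 60,
                   seed = 21, estimate = "average")
  expect_identical(refit$V, m$V)
  expect_identical(refit$U, m$U)
  empty <- fx$sim$mark1
  empty$counts[, 3] <- 0
  expect_error(fit_lda(empty, K = 4, n_iter = 10, seed = 1),
               "zero total counts")
})

test_that("single-topic fit degenerates to smoothed pooled frequencies", {
  fx <- tiny_benchmark()
  counts <- fx$sim$mark1$counts[, 1:20]
  m <- fit_lda(counts, K = 1, n_iter = 5, seed = 3)
  G <- nrow(counts)
  expected <- (Matrix::rowSums(counts) + 0.1) / (sum(counts) + G * 0.1)
  expect_equal(unname(m$V[, 1]), as.numeric(expected), tolerance = 1e-12)
  expect_true(all(m$U == 1))
})

test_that("disjoint-support topics are recovered from generated data", {
  G <- 200; n <- 200; depth <- 400
  V_true <- cbind(c(rep(1 / 100, 100), rep(0, 100)),
                  c(rep(0, 100), rep(1 / 100, 100)))
  set.seed(42)
  U_true <- t(sapply(seq_len(n), function(i) rsimplex(2)))
  counts <- sapply(seq_len(n), function(i)
    stats::rmultinom(1, depth, V_true %*% U_true[i, ]))
  m <- fit_lda(counts, K = 2, n_iter = 300, burn_in = 100, seed = 9)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim_mat <- outer(1:2, 1:2, Vectorize(function(i, j)
    cos(m$V[, i], V_true[, j])))
  best <- max(sim_mat[1, 1] + sim_mat[2, 2], sim_mat[1, 2] + sim_mat[2, 1])
  expect_gt(best / 2, 0.95)
  # the fitted model explains held-out structure better than a null model
  ll_model <- sum(sapply(seq_len(n), function(i)
    sum(counts[, i] * log(m$V %*% m$U[, i]))))
  ll_null <- sum(counts * log(1 / G))
  expect_gt(ll_model, ll_null)
})

test_that("fold-in reproduces training cells and pure-topic cells", {
  fx <- tiny_benchmark()
  m <- fx$model1
  U_new <- fold_in(m, subset_cells(fx$sim$mark1, 1:10), n_iter = 150,
                   seed = 4)
  tv <- sapply(1:10, function(i) 0.5 * sum(abs(U_new[, i] - m$U[, i])))
  expect_lt(max(tv), 0.05)
  # a deep cell drawn from one topic's distribution loads on that topic
  k_star <- which.max(apply(m$U, 1, max))
  y <- stats::rmultinom(1, 50000, m$V[, k_star])
  u <- fold_in(m, mark_counts(y, regions = m$regions), n_iter = 200,
               seed = 5)
  expect_gt(u[k_star, 1], 0.9)
  empty <- fold_in(m, fx$sim$mark1$counts[, integer(0), drop = FALSE])
  expect_identical(ncol(empty), 0L)
  wrong <- fx$sim$mark1
  wrong$regions <- wrong$regions[c(2:nrow(wrong$regions), 1), ]
  expect_error(fold_in(m, wrong), "region sets")
})

test_that("cluster profiles implement the cell-averaged reconstruction", {
  V <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  U <- cbind(c(1, 0), c(0.5, 0.5), c(0.2, 0.8))
  dimnames(V) <- list(NULL, c("topic1", "topic2"))
  dimnames(U) <- list(c("topic1", "topic2"), c("a", "b", "c"))
  model <- structure(list(V = V, U = U, K = 2L, alpha = 1.67, delta = 0.1,
                          regions = chromunmix:::fabricate_regions(3),
                          barcodes = c("a", "b", "c")),
                     class = "topic_model")
  pr <- cluster_profiles(model, c("x", "x", "y"))
  hand_x <- (V %*% U[, 1] + V %*% U[, 2]) / 2
  expect_equal(unname(pr$P[, "x"]), as.numeric(hand_x), tolerance = 1e-12)
  expect_equal(unname(pr$P[, "y"]), as.numeric(V %*% U[, 3]),
               tolerance = 1e-12)
  expect_equal(unname(colSums(pr$P)), c(1, 1), tolerance = 1e-9)
  # invariant to cell order within a cluster
  pr_rev <- cluster_profiles(model, stats::setNames(c("y", "x", "x"),
                                                    c("c", "b", "a")))
  expect_equal(pr_rev$P, pr$P, tolerance = 1e-12)
  expect_error(cluster_profiles(model, c("x", "x")), "one cluster label")
  expect_error(cluster_profiles(model, stats::setNames(c("x", "y"),
                                                       c("a", "b"))),
               "no cluster label")
})

test_that("top bins are ranked by loading with index tie-breaks", {
  P <- cbind(cl1 = c(0.5, 0.1, 0.4), cl2 = rep(1 / 3, 3))
  pr <- structure(list(P = P, labels = colnames(P)),
                  class = "cluster_profiles")
  top <- top_cluster_bins(pr, n_top = 2)
  expect_identical(top$cl1, c(1L, 3L))
  expect_identical(top$cl2, c(1L, 2L))   # equal loadings: first by index
  expect_error(top_cluster_bins(pr, n_top = 4), "exceeds")
  expect_identical(eval(formals(top_cluster_bins)$n_top), 150L)
})

test_that("latent coordinates are row-stochastic cell coordinates", {
  fx <- tiny_benchmark()
  lc <- latent_coordinates(fx$model1)
  expect_identical(dim(lc), c(ncol(fx$model1$U), fx$model1$K))
  expect_equal(unname(rowSums(lc)), rep(1, nrow(lc)), tolerance = 1e-9)
})
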