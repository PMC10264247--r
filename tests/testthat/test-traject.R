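test_that("pseudotime is min-max scaled PC1 with orientation control", {
  two <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_setequal(pseudotime_from_latent(two), c(0, 1))
  set.seed(4)
  lat <- cbind(seq(0, 1, length.out = 40) + rnorm(40, 0, 0.01),
               rnorm(40, 0, 0.01))
  anchor <- seq_len(40)
  t_fwd <- pseudotime_from_latent(lat, anchor)
  t_rev <- pseudotime_from_latent(lat, rev(anchor))
  expect_equal(t_rev, 1 - t_fwd, tolerance = 1e-12)
  expect_gt(stats::cor(t_fwd, anchor, method = "spearman"), 0.95)
  expect_error(pseudotime_from_latent(matrix(0.5, 10, 3)), "constant")
})

test_that("pseudotime recovers the course ordering from topic space", {
  kin <- data.frame(y0 = runif(80, 0.5, 1), A = runif(80, 1, 2),
                    gamma = runif(80, 2, 5))
  centers <- seq(0.1, 0.9, length.out = 80)
  rising <- rep(c(TRUE, FALSE), length.out = 80)
  driver <- function(t) outer(seq_len(80), t, function(g, x) {
    s <- 1 / (1 + exp(-(x - centers[g]) / 0.08))
    20 * (0.2 + ifelse(rising[g], s, 1 - s))
  })
  crs <- simulate_pseudotime_course(150, 80, kin, driver, seed = 8)
  model <- fit_lda(crs$mark1, K = 6, n_iter = 300, burn_in = 150,
                   seed = 2, estimate = "average")
  t_hat <- pseudotime_from_latent(model, anchor = crs$t)
  expect_gt(stats::cor(t_hat, crs$t, method = "spearman"), 0.95)
})

test_that("smoothed profiles are simplex columns tracking the signal", {
  set.seed(5)
  n <- 500
  t <- sort(runif(n))
  # two regions: one sigmoid in time, one constant
  sig <- 1 / (1 + exp(-(t - 0.5) / 0.1))
  m <- rbind(40 * sig + 1, rep(20, n), rep(20, n))
  sp <- fit_smooth_profiles(m, t, span = 0.1, grid_size = 101)
  expect_equal(unname(colSums(sp$P)), rep(1, 101), tolerance = 1e-9)
  truth <- rbind(40 / (1 + exp(-(sp$grid - 0.5) / 0.1)) + 1,
                 rep(20, 101), rep(20, 101))
  truth <- sweep(truth, 2, colSums(truth), "/")
  err <- abs(sp$P[1, ] - truth[1, ])
  expect_lt(max(err) / diff(range(truth[1, ])), 0.01)
  # constant region stays near its average simplex share
  expect_lt(max(abs(sp$P[2, ] - truth[2, ])) / max(truth[2, ]), 0.1)
  expect_error(fit_smooth_profiles(m[, 1:4], t[1:4], span = 0.3), "few")
})

test_that("profile interpolation is linear between grid columns", {
  P <- cbind(c(0.2, 0.8), c(0.6, 0.4))
  sp <- structure(list(grid = c(0, 1), P = P, span = 0.3),
                  class = "smooth_profiles")
  expect_equal(profile_at(sp, 0.25), 0.75 * P[, 1] + 0.25 * P[, 2])
  single <- structure(list(grid = 0.5, P = P[, 1, drop = FALSE],
                           span = 0.3), class = "smooth_profiles")
  expect_equal(profile_at(single, 0.9), P[, 1])
})

test_that("single-grid-point profiles reduce to the discrete likelihood", {
  fx <- tiny_benchmark()
  p <- fx$prof1$P[, 1]; q <- fx$prof2$P[, 2]
  sp1 <- structure(list(grid = 0.5, P = matrix(p, ncol = 1), span = 0.3),
                   class = "smooth_profiles")
  sp2 <- structure(list(grid = 0.5, P = matrix(q, ncol = 1), span = 0.3),
                   class = "smooth_profiles")
  y <- as.numeric(fx$sim$double$counts[, 3])
  for (w in c(0.2, 0.5, 0.9))
    expect_equal(trajectory_loglik(y, sp1, sp2, 0.1, 0.9, w),
                 mixture_loglik(y, p, q, w), tolerance = 1e-12)
})

test_that("neighbor pooling sums counts over latent neighborhoods", {
  fx <- tiny_benchmark()
  dbl <- subset_cells(fx$sim$double, 1:20)
  lat <- matrix(runif(40), 20, 2)
  expect_identical(eval(formals(pool_neighbors)$k), 25L)
  same <- pool_neighbors(dbl, lat, k = 1)
  expect_equal(as.matrix(same$counts), as.matrix(dbl$counts))
  pooled <- pool_neighbors(dbl, lat, k = 4)
  D <- as.matrix(dist(lat))
  m <- as.matrix(dbl$counts)
  for (i in c(1, 7, 20)) {
    nb <- order(D[i, ], seq_len(20))[1:4]
    expect_equal(unname(pooled$counts[, i]),
                 unname(rowSums(m[, nb])))
  }
  expect_error(pool_neighbors(dbl, lat, k = 21), "exceeds")
})

test_that("joint pseudotime estimation recovers deep noiseless cells", {
  pr <- course_profiles(grid_size = 1001)
  # noiseless expected counts of a deep double-incubated cell
  mix <- 0.5 * profile_at(pr$p1, 0.3) + 0.5 * profile_at(pr$p2, 0.7)
  fit <- estimate_pseudotimes(20000 * mix, pr$p1, pr$p2)
  expect_lt(abs(fit$t1_hat - 0.3), 0.05)
  expect_lt(abs(fit$t2_hat - 0.7), 0.05)
  expect_false(fit$non_identifiable)
  expect_true(fit$se_t1 > 0 && fit$se_t2 > 0)
  # a finite multinomial draw stays close to truth
  set.seed(9)
  y <- as.numeric(stats::rmultinom(1, 20000, mix))
  fit2 <- estimate_pseudotimes(y, pr$p1, pr$p2)
  expect_lt(abs(fit2$t1_hat - 0.3), 0.1)
  expect_lt(abs(fit2$t2_hat - 0.7), 0.1)
  # flat profiles leave the pseudotimes unidentifiable
  flatP <- matrix(rep(rsimplex(60), 101), ncol = 101)
  flat <- structure(list(grid = seq(0, 1, length.out = 101), P = flatP,
                         span = 0.3), class = "smooth_profiles")
  ffit <- estimate_pseudotimes(y, flat, flat)
  expect_true(ffit$non_identifiable)
})

test_that("standard errors shrink as the square root of depth", {
  pr <- course_profiles(grid_size = 1001)
  mix <- 0.5 * profile_at(pr$p1, 0.4) + 0.5 * profile_at(pr$p2, 0.6)
  f_lo <- estimate_pseudotimes(2000 * mix, pr$p1, pr$p2)
  f_hi <- estimate_pseudotimes(20000 * mix, pr$p1, pr$p2)
  ratio <- c(f_lo$se_t1 / f_hi$se_t1, f_lo$se_t2 / f_hi$se_t2)
  expect_true(all(ratio > 2.5 & ratio < 4))
})

test_that("daily progression differences come from the day-mean model", {
  day <- rep(0:7, each = 20)
  t_exact <- day / 7
  prog <- suppressWarnings(estimate_daily_progression(t_exact, day))
  expect_equal(prog$estimate, rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(prog$ci_hi - prog$ci_lo, rep(0, 7), tolerance = 1e-9)
  set.seed(12)
  day2 <- rep(0:7, each = 200)
  t_noisy <- day2 / 7 + rnorm(length(day2), 0, 0.01)
  prog2 <- estimate_daily_progression(t_noisy, day2)
  expect_true(all(prog2$ci_lo <= 1 / 7 & 1 / 7 <= prog2$ci_hi))
  # identical distributions across days: differences straddle zero
  set.seed(15)
  shared <- stats::runif(80)
  prog3 <- estimate_daily_progression(rep(shared, 2),
                                      rep(0:1, each = 80))
  expect_true(all(prog3$ci_lo <= 0 & 0 <= prog3$ci_hi))
  expect_error(estimate_daily_progression(c(0.1, 0.2, 0.3),
                                          c(1, 1, 2)), "fewer than 2")
})

test_that("pooling improves pseudotime recovery on noisy cells", {
  pr <- course_profiles()
  set.seed(14)
  n <- 60
  t_true <- sort(runif(n, 0.15, 0.85))
  y <- sapply(t_true, function(tt) {
    mix <- 0.5 * profile_at(pr$p1, tt) + 0.5 * profile_at(pr$p2, tt)
    as.numeric(stats::rmultinom(1, 150, mix))
  })
  counts <- mark_counts(y)
  lat <- cbind(t_true, 0) + matrix(rnorm(2 * n, 0, 0.02), n, 2)
  pooled <- pool_neighbors(counts, lat, k = 15)
  err <- function(m) stats::median(abs(sapply(seq_len(n), function(i)
    estimate_pseudotimes(as.numeric(m$counts[, i]), pr$p1,
                         pr$p2, n_starts = 3)$t1_hat) - t_true))
  expect_lte(err(pooled), err(counts))
})

test_that("lagging mark-2 dynamics yield earlier mark-2 pseudotimes", {
  pr <- course_profiles()
  # mark 2 state lags: its profile corresponds to an earlier pseudotime
  lag <- 0.25
  for (tt in c(0.3, 0.45, 0.6)) {
    mix <- 0.5 * profile_at(pr$p1, tt) +
      0.5 * profile_at(pr$p2, max(tt - lag, 0))
    y <- round(40000 * mix)
    fit <- estimate_pseudotimes(y, pr$p1, pr$p2)
    expect_gt(fit$t1_hat, fit$t2_hat)
  }
})
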