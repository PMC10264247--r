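# Shared fixture builders. Everything is generated in code under fixed
# seeds; sizes are kept small enough that the whole suite runs in minutes.

# Tiny two-cell-type benchmark with trained models, used by several tests.
tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_loci = 300, n_cells_per_condition = 40,
                        n_celltypes = 2, swap_fraction = 0.4, seed = 11)
      sim <- simulate_benchmark(cfg)
      m1 <- fit_lda(sim$mark1, K = 4, n_iter = 120, burn_in = 60,
                    seed = 21, estimate = "average")
      m2 <- fit_lda(sim$mark2, K = 4, n_iter = 120, burn_in = 60,
                    seed = 22, estimate = "average")
      cache <<- list(sim = sim, model1 = m1, model2 = m2,
                     prof1 = cluster_profiles(m1, sim$mark1$cells$celltype),
                     prof2 = cluster_profiles(m2, sim$mark2$cells$celltype))
    }
    cache
  }
})

# Random simplex vector.
rsimplex <- function(G) {
  x <- stats::rgamma(G, 1)
  x / sum(x)
}

# Draw a multinomial count vector from a two-profile mixture.
rmix_counts <- function(n, p, q, w) {
  as.numeric(stats::rmultinom(1, n, w * p + (1 - w) * q))
}

# Independent grid-search maximizer of the mixture likelihood over w.
grid_w <- function(y, p, q, step = 1e-4) {
  ws <- seq(0, 1, by = step)
  ll <- vapply(ws, function(w) {
    idx <- y > 0
    mix <- w * p[idx] + (1 - w) * q[idx]
    if (any(mix == 0)) return(-Inf)
    sum(y[idx] * log(mix))
  }, numeric(1))
  list(w = ws[which.max(ll)], loglik = max(ll))
}

# Smooth-profile pair with known pseudotime structure: regions switch on
# or off as sigmoids at staggered times, so both marks are identifiable
# over all of [0, 1]. Mark 2 uses its own centers and mixed directions.
course_profiles <- function(n_regions = 60, grid_size = 101) {
  grid <- seq(0, 1, length.out = grid_size)
  sig <- function(centers, scale, rising) {
    t(vapply(seq_along(centers), function(g) {
      s <- 1 / (1 + exp(-(grid - centers[g]) / scale))
      0.2 + if (rising[g]) s else 1 - s
    }, numeric(grid_size)))
  }
  c1 <- seq(0.05, 0.95, length.out = n_regions)
  c2 <- seq(0.95, 0.05, length.out = n_regions)
  P1 <- sig(c1, 0.08, rep(c(TRUE, FALSE), length.out = n_regions))
  P2 <- sig(c2, 0.1, rep(c(FALSE, TRUE), length.out = n_regions))
  # mark-specific static fingerprints keep the mixing weight identifiable
  set.seed(81)
  P1 <- P1 + stats::runif(n_regions, 0, 1.5)
  P2 <- P2 + stats::runif(n_regions, 0, 1.5)
  norm <- function(M) {
    M[M < 0] <- 0
    sweep(M, 2, colSums(M), "/")
  }
  list(p1 = structure(list(grid = grid, P = norm(P1), span = 0.3,
                           regions = NULL), class = "smooth_profiles"),
       p2 = structure(list(grid = grid, P = norm(P2), span = 0.3,
                           regions = NULL), class = "smooth_profiles"))
}

# Region signals exactly consistent with first-order kinetics driven by a
# constant per-region driver: K36(t) = y0 + A (1 - exp(-gamma t)) with
# K4 = gamma * (y0 + A). Returns regions x grid matrices.
ode_course <- function(n_regions = 40, grid_size = 101, seed = 1) {
  set.seed(seed)
  grid <- seq(0, 1, length.out = grid_size)
  y0 <- runif(n_regions, 0.2, 1)
  A <- runif(n_regions, 0.5, 2)
  gamma <- runif(n_regions, 1.5, 5)
  K36 <- t(vapply(seq_len(n_regions), function(g)
    y0[g] + A[g] * (1 - exp(-gamma[g] * grid)), numeric(grid_size)))
  K4 <- matrix(gamma * (y0 + A), n_regions, grid_size)
  list(grid = grid, K36 = K36, K4 = K4, y0 = y0, A = A, gamma = gamma)
}
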