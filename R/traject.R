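#' Pseudotime from latent topic coordinates
#'
#' PCA on the per-cell topic weights; the first principal component,
#' min-max rescaled to `[0, 1]`, is taken as pseudotime. The sign is
#' oriented so that pseudotime correlates positively with `anchor` when
#' given (e.g. collection day); otherwise by the convention that the first
#' cell's value is not larger than the last cell's.
#'
#' @param latent cells x K matrix ([latent_coordinates()]) or a
#'   `topic_model`.
#' @param anchor optional per-cell ordinal labels for orientation.
#' @return Numeric pseudotime per cell in `[0, 1]`.
#' @export
pseudotime_from_latent <- function(latent, anchor = NULL) {
  if (inherits(latent, "topic_model")) latent <- latent_coordinates(latent)
  latent <- as.matrix(latent)
  if (nrow(latent) < 2) stop("need at least 2 cells")
  pc <- stats::prcomp(latent, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < .Machine$double.eps * 100)
    stop("latent coordinates are constant across cells")
  x <- pc$x[, 1]
  t <- (x - min(x)) / (max(x) - min(x))
  flip <- if (!is.null(anchor)) {
    stats::cor(t, as.numeric(as.factor(anchor)),
               method = "spearman") < 0
  } else {
    t[1] > t[length(t)]
  }
  if (isTRUE(flip)) t <- 1 - t
  names(t) <- rownames(latent)
  t
}

#' Smooth mark profiles along pseudotime
#'
#' Per region, the depth-normalized signal is smoothed against pseudotime
#' with a lowess curve and evaluated on a regular grid over `[0, 1]`.
#' Negative fitted values are clipped to 0 and each grid column is
#' renormalized to the probability simplex, giving the continuous profile
#' `p_g(t)` of the pseudotime mixture likelihood.
#'
#' @param counts [mark_counts()] or region x cell matrix.
#' @param t per-cell pseudotime in `[0, 1]`.
#' @param span lowess smoother span (default 0.3).
#' @param grid_size number of grid points (default 101).
#' @return A `smooth_profiles`: `grid`, matrix `P` (regions x grid,
#'   columns on the simplex), `span`.
#' @export
fit_smooth_profiles <- function(counts, t, span = 0.3, grid_size = 101L) {
  obj <- as_mark_counts_any(counts)
  m <- as.matrix(obj$counts)
  n <- ncol(m)
  if (length(t) != n) stop("need one pseudotime per cell")
  if (any(t < 0 | t > 1)) stop("pseudotime must be in [0, 1]")
  if (floor(span * n) < 2)
    stop("too few cells (", n, ") for span ", span)
  depth <- colSums(m)
  if (any(depth == 0)) stop("cells with zero total counts")
  norm <- sweep(m, 2, depth, "/")
  grid <- seq(0, 1, length.out = grid_size)
  ord <- order(t)
  ts <- t[ord]
  P <- matrix(0, nrow(m), grid_size)
  for (g in seq_len(nrow(m))) {
    lw <- stats::lowess(ts, norm[g, ord], f = span)
    P[g, ] <- stats::approx(lw$x, lw$y, xout = grid, rule = 2,
                            ties = mean)$y
  }
  P[P < 0] <- 0
  cs <- colSums(P)
  if (any(cs == 0)) stop("degenerate all-zero profile column")
  P <- sweep(P, 2, cs, "/")
  rownames(P) <- rownames(m)
  structure(list(grid = grid, P = P, span = span, regions = obj$regions),
            class = "smooth_profiles")
}

as_mark_counts_any <- function(x) {
  if (inherits(x, "mark_counts")) return(x)
  mark_counts(x, real_valued = TRUE)
}

#' Evaluate smooth profiles at a pseudotime
#'
#' Linear interpolation between the grid columns of a `smooth_profiles`
#' object. A single-grid-point profile set is constant in `t`, recovering
#' the discrete-cluster likelihood as a special case.
#'
#' @param profiles a `smooth_profiles`.
#' @param t scalar pseudotime in `[0, 1]`.
#' @return Probability vector over regions.
#' @export
profile_at <- function(profiles, t) {
  stopifnot(inherits(profiles, "smooth_profiles"))
  g <- profiles$grid
  if (length(g) == 1) return(profiles$P[, 1])
  t <- min(max(t, g[1]), g[length(g)])
  j <- findInterval(t, g, rightmost.closed = TRUE)
  if (j >= length(g)) return(profiles$P[, length(g)])
  a <- (t - g[j]) / (g[j + 1] - g[j])
  (1 - a) * profiles$P[, j] + a * profiles$P[, j + 1]
}

#' Pseudotime mixture log-likelihood
#'
#' The continuous-pseudotime extension of [mixture_loglik()]:
#' `sum_g y_g * log(w * p_g(t1) + (1 - w) * q_g(t2))` with the profiles
#' evaluated by linear interpolation along their grids.
#'
#' @param y count vector.
#' @param profiles1,profiles2 `smooth_profiles` for the two marks.
#' @param t1,t2 pseudotimes in `[0, 1]`.
#' @param w mixing fraction in `[0, 1]`.
#' @return Scalar log-likelihood (up to the multinomial constant).
#' @export
trajectory_loglik <- function(y, profiles1, profiles2, t1, t2, w) {
  p <- profile_at(profiles1, t1)
  q <- profile_at(profiles2, t2)
  mixture_loglik(y, p, q, w)
}

#' Pool counts over latent-space nearest neighbors
#'
#' Per double-incubated cell, counts are summed over its `k` nearest
#' neighbors (Euclidean distance in the latent topic space, self
#' included), reducing the noise of single-cell pseudotime estimates.
#'
#' @param double_counts [mark_counts()] of double-incubated cells.
#' @param latent_double cells x K latent coordinates for the same cells
#'   (typically from an LDA fit on the double-incubated matrix itself).
#' @param k neighborhood size including self (default 25).
#' @return A `mark_counts` of pooled counts (same cells and regions).
#' @export
pool_neighbors <- function(double_counts, latent_double, k = 25L) {
  obj <- as_mark_counts_any(double_counts)
  latent_double <- as.matrix(latent_double)
  n <- ncol(obj$counts)
  if (nrow(latent_double) != n)
    stop("latent coordinates do not match the cells")
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of cells")
  if (k == 1) return(obj)
  D <- as.matrix(stats::dist(latent_double))
  m <- as.matrix(obj$counts)
  pooled <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]
    rowSums(m[, nb, drop = FALSE])
  }, numeric(nrow(m)))
  out <- mark_counts(Matrix::Matrix(pooled, sparse = TRUE),
                     regions = obj$regions, cells = obj$cells,
                     real_valued = obj$real_valued)
  out
}

#' Jointly infer the two pseudotimes of a double-incubated cell
#'
#' Maximizes the pseudotime mixture log-likelihood over
#' `(t1, t2, w)` in the unit box, by bounded quasi-Newton (L-BFGS-B)
#' started from a coarse multistart grid over `(t1, t2)`. Standard errors
#' of `t1` and `t2` are the square roots of the diagonal of the inverse
#' numerical Hessian (central finite differences) of the negative
#' log-likelihood at the optimum; they are flagged unreliable when the
#' optimum sits on the box boundary or the Hessian is not positive
#' definite.
#'
#' @param y count vector of one (possibly neighbor-pooled) cell.
#' @param profiles1,profiles2 `smooth_profiles` for the two marks.
#' @param n_starts multistart grid resolution per axis (default 5).
#' @param cell_id optional identifier.
#' @return A `trajectory_fit`: `t1_hat`, `t2_hat`, `w_hat`, `se_t1`,
#'   `se_t2`, `loglik`, `at_boundary`, `non_identifiable`, `pooled`.
#' @export
estimate_pseudotimes <- function(y, profiles1, profiles2, n_starts = 5L,
                                 cell_id = NA_character_) {
  stopifnot(inherits(profiles1, "smooth_profiles"),
            inherits(profiles2, "smooth_profiles"))
  idx <- which(y > 0)
  if (!length(idx)) stop("empty count vector")
  negll <- function(par) {
    p <- profile_at(profiles1, par[1])[idx]
    q <- profile_at(profiles2, par[2])[idx]
    mix <- pmax(par[3] * p + (1 - par[3]) * q, 1e-300)
    -sum(y[idx] * log(mix))
  }
  starts <- expand.grid(t1 = seq(0.1, 0.9, length.out = n_starts),
                        t2 = seq(0.1, 0.9, length.out = n_starts))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$t1[r], starts$t2[r], 0.5), negll,
                   method = "L-BFGS-B", lower = c(0, 0, 0),
                   upper = c(1, 1, 1)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("likelihood could not be evaluated")
  par <- best$par
  # identifiability: scan t at the fitted w; a flat profile gives a flat scan
  scan <- vapply(seq(0, 1, length.out = 11), function(tt)
    -negll(c(tt, par[2], par[3])) - (-negll(par)), numeric(1))
  scan2 <- vapply(seq(0, 1, length.out = 11), function(tt)
    -negll(c(par[1], tt, par[3])) - (-negll(par)), numeric(1))
  non_ident <- (max(abs(scan)) < 1e-9) || (max(abs(scan2)) < 1e-9)
  at_boundary <- any(par < 1e-6) || any(par > 1 - 1e-6)
  se <- c(NA_real_, NA_real_)
  if (!non_ident) {
    H <- numeric_hessian(negll, par, h = 1e-4, lower = rep(0, 3),
                         upper = rep(1, 3))
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)[1:2]
      ok <- is.finite(d) & d > 0
      se[ok] <- sqrt(d[ok])
    }
  }
  structure(list(cell_id = cell_id, t1_hat = par[1], t2_hat = par[2],
                 w_hat = par[3], se_t1 = se[1], se_t2 = se[2],
                 loglik = -best$value, at_boundary = at_boundary,
                 non_identifiable = non_ident, pooled = FALSE),
            class = "trajectory_fit")
}

# Central-difference Hessian, with steps shrunk at the box boundary so all
# evaluation points stay inside the box.
numeric_hessian <- function(f, x, h = 1e-4, lower = NULL, upper = NULL) {
  n <- length(x)
  hs <- rep(h, n)
  if (!is.null(lower) && !is.null(upper))
    hs <- pmin(hs, (x - lower) / 2 + 1e-12, (upper - x) / 2 + 1e-12)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- rep(0, n); ei[i] <- hs[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- rep(0, n); ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "trajectory_fit %s: t1 = %.3f (se %.3g), t2 = %.3f (se %.3g), w = %.3f\n",
    x$cell_id, x$t1_hat, x$se_t1, x$t2_hat, x$se_t2, x$w_hat))
  invisible(x)
}

#' Mean pseudotime progression between consecutive days
#'
#' Fits a cell-level linear model of pseudotime on day indicators and
#' reports, for each consecutive pair of days, the difference of day means
#' with its 95% confidence interval.
#'
#' @param t per-cell pseudotime.
#' @param day per-cell day labels (sortable; >= 2 days, >= 2 cells each).
#' @return data.frame with `from`, `to`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`.
#' @export
estimate_daily_progression <- function(t, day) {
  stopifnot(length(t) == length(day))
  days <- sort(unique(day))
  if (length(days) < 2) stop("need at least 2 days")
  tab <- table(day)
  if (any(tab < 2))
    stop("day(s) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  fd <- factor(day, levels = days)
  fit <- stats::lm(t ~ 0 + fd)
  mu <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- fit$df.residual
  out <- lapply(seq_len(length(days) - 1), function(i) {
    est <- mu[i + 1] - mu[i]
    se <- sqrt(V[i, i] + V[i + 1, i + 1] - 2 * V[i, i + 1])
    ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
    data.frame(from = as.character(days[i]), to = as.character(days[i + 1]),
               estimate = unname(est), se = unname(se),
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
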