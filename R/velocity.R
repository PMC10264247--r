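#' Fit first-order relaxation kinetics to a region's pseudotime signal
#'
#' Models the downstream mark's smoothed signal as exponential relaxation
#' `y(t) = y0 + A * (1 - exp(-gamma * t))`, the solution of the
#' first-order kinetics `dy/dt = k(t) - gamma * y` under a step-like
#' driver: `y0` is the signal at `t = 0`, `y0 + A` the asymptote, and
#' `gamma > 0` the rate constant per pseudotime unit. Fitted by
#' Levenberg-Marquardt nonlinear least squares with `gamma` bounded away
#' from 0; non-convergence is reported, not raised.
#'
#' @param signal numeric signal values along the pseudotime grid.
#' @param t pseudotime grid in `[0, 1]`; defaults to an even grid.
#' @param region_id optional identifier.
#' @return A `relaxation_fit`: `y0`, `A`, `gamma`, `rss`, `converged`,
#'   `degenerate`.
#' @export
fit_relaxation <- function(signal, t = NULL, region_id = NA_character_) {
  n <- length(signal)
  if (n < 4) stop("need at least 4 points")
  if (is.null(t)) t <- seq(0, 1, length.out = n)
  stopifnot(length(t) == n, all(t >= 0 & t <= 1))
  rng <- diff(range(signal))
  if (rng < .Machine$double.eps * 100 * max(1, abs(signal[1]))) {
    return(structure(list(region_id = region_id, y0 = signal[1], A = 0,
                          gamma = NA_real_, rss = 0, converged = FALSE,
                          degenerate = TRUE),
                     class = "relaxation_fit"))
  }
  df <- data.frame(t = t, y = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * (1 - exp(-g * t)), data = df,
                      start = list(y0 = signal[1],
                                   A = signal[n] - signal[1], g = 1),
                      lower = c(-Inf, -Inf, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(region_id = region_id, y0 = NA_real_,
                          A = NA_real_, gamma = NA_real_, rss = NA_real_,
                          converged = FALSE, degenerate = FALSE),
                     class = "relaxation_fit"))
  }
  co <- stats::coef(fit)
  structure(list(region_id = region_id, y0 = unname(co["y0"]),
                 A = unname(co["A"]), gamma = unname(co["g"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, degenerate = FALSE),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "relaxation_fit %s: y0 = %.4g, A = %.4g, gamma = %.4g (rss %.3g%s)\n",
    x$region_id, x$y0, x$A, x$gamma, x$rss,
    if (x$degenerate) ", degenerate" else if (!x$converged)
      ", not converged" else ""))
  invisible(x)
}

#' Evaluate a fitted relaxation curve
#' @param fit a `relaxation_fit`.
#' @param t pseudotime values.
#' @return Fitted signal values.
#' @export
relaxation_curve <- function(fit, t) {
  fit$y0 + fit$A * (1 - exp(-fit$gamma * t))
}

#' Fit relaxation kinetics for every region of a profile matrix
#'
#' @param signal_matrix regions x grid matrix of smoothed signal.
#' @param t pseudotime grid.
#' @return data.frame with one row per region: `region`, `y0`, `A`,
#'   `gamma`, `rss`, `converged`, `degenerate`.
#' @export
fit_relaxation_all <- function(signal_matrix, t = NULL) {
  ids <- rownames(signal_matrix)
  if (is.null(ids)) ids <- sprintf("region_%d", seq_len(nrow(signal_matrix)))
  rows <- lapply(seq_len(nrow(signal_matrix)), function(g) {
    f <- fit_relaxation(signal_matrix[g, ], t = t, region_id = ids[g])
    data.frame(region = ids[g], y0 = f$y0, A = f$A, gamma = f$gamma,
               rss = f$rss, converged = f$converged,
               degenerate = f$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One Euler step of the first-order kinetics
#'
#' Predicts the downstream mark's level a short pseudotime step ahead:
#' `k36_next = k36_now + h * (k4_now - gamma * k36_now)`, elementwise over
#' regions (and cells, if matrices are supplied).
#'
#' @param k36_now current downstream-mark signal.
#' @param k4_now current driver-mark signal.
#' @param gamma per-region rate constant(s).
#' @param h pseudotime step (default 0.02).
#' @return Predicted signal, same shape as `k36_now`.
#' @export
euler_predict <- function(k36_now, k4_now, gamma, h = 0.02) {
  if (h <= 0) stop("h must be positive")
  k36_now + h * (k4_now - gamma * k36_now)
}

#' Select dynamic regions from a smoothed profile matrix
#'
#' Regions whose smoothed signal range along pseudotime exceeds
#' `factor` times the median range across regions.
#'
#' @param signal_matrix regions x grid matrix.
#' @param factor multiple of the median range (default 2).
#' @return Integer indices of dynamic regions.
#' @export
dynamic_regions <- function(signal_matrix, factor = 2) {
  rng <- apply(signal_matrix, 1, function(x) diff(range(x)))
  which(rng > factor * stats::median(rng))
}

#' Two-dimensional velocity vector field
#'
#' PCA is fitted on the current per-cell region signals; the predicted
#' (Euler-stepped) signals are projected with the same centering and
#' loadings, and the per-cell displacement in PC space is summarized as
#' Gaussian-kernel-weighted mean arrows on a regular grid. Arrows are
#' reported only for grid boxes containing at least one cell.
#'
#' @param current cells x regions matrix of current signals.
#' @param predicted cells x regions matrix of predicted signals (same
#'   cells and regions).
#' @param n_components number of PCs (default 2).
#' @param grid_n grid resolution per axis (default 20).
#' @param bandwidth Gaussian kernel bandwidth; default half the grid
#'   spacing.
#' @return A `velocity_field`: `coords` (cells x 2), `displacement`
#'   (cells x 2), `arrows` (data.frame grid_x, grid_y, dx, dy, n_cells),
#'   `rotation`, `center`.
#' @export
velocity_field <- function(current, predicted, n_components = 2L,
                           grid_n = 20L, bandwidth = NULL) {
  current <- as.matrix(current)
  predicted <- as.matrix(predicted)
  if (!all(dim(current) == dim(predicted)))
    stop("current and predicted must share cells and regions")
  if (nrow(current) < 3) stop("need at least 3 cells")
  pc <- stats::prcomp(current, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  proj_pred <- sweep(predicted, 2, pc$center) %*% rot
  disp <- proj_pred - coords
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  gx <- seq(rx[1], rx[2], length.out = grid_n + 1)
  gy <- seq(ry[1], ry[2], length.out = grid_n + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  if (is.null(bandwidth))
    bandwidth <- max(diff(cx)[1], diff(cy)[1], .Machine$double.eps) / 2
  ix <- pmin(pmax(findInterval(coords[, 1], gx, rightmost.closed = TRUE),
                  1), grid_n)
  iy <- pmin(pmax(findInterval(coords[, 2], gy, rightmost.closed = TRUE),
                  1), grid_n)
  occupied <- unique(data.frame(ix = ix, iy = iy))
  arrows <- lapply(seq_len(nrow(occupied)), function(r) {
    cxr <- cx[occupied$ix[r]]; cyr <- cy[occupied$iy[r]]
    d2 <- (coords[, 1] - cxr)^2 + (coords[, 2] - cyr)^2
    wgt <- exp(-d2 / (2 * bandwidth^2))
    wgt <- wgt / sum(wgt)
    data.frame(grid_x = cxr, grid_y = cyr,
               dx = sum(wgt * disp[, 1]), dy = sum(wgt * disp[, 2]),
               n_cells = sum(ix == occupied$ix[r] & iy == occupied$iy[r]))
  })
  arrows <- do.call(rbind, arrows)
  structure(list(coords = coords, displacement = disp, arrows = arrows,
                 rotation = rot, center = pc$center,
                 bandwidth = bandwidth),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d cells, %d grid arrows\n",
              nrow(x$coords), nrow(x$arrows)))
  invisible(x)
}
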