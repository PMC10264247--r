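#' Log-likelihood of a two-multinomial mixture
#'
#' For a double-incubated cell with count vector `y`, cluster profiles `p`
#' (mark 1) and `q` (mark 2) and mixing fraction `w`, computes, up to the
#' multinomial constant, `sum_g y_g * log(w * p_g + (1 - w) * q_g)`.
#' Regions with `y_g = 0` contribute nothing even when the mixture
#' probability there is 0. If a region has `y_g > 0` but zero mixture
#' probability, `-Inf` is returned with attribute `flagged = TRUE`.
#'
#' @param y non-negative count vector.
#' @param p,q probability vectors of the same length.
#' @param w mixing fraction in `[0, 1]` (share of mark 1).
#' @return Scalar log-likelihood (up to an additive constant).
#' @export
mixture_loglik <- function(y, p, q, w) {
  stopifnot(length(y) == length(p), length(p) == length(q),
            w >= 0, w <= 1)
  idx <- which(y > 0)
  mix <- w * p[idx] + (1 - w) * q[idx]
  if (any(mix == 0)) {
    out <- -Inf
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(y[idx] * log(mix))
}

#' Maximum-likelihood mixing fraction for a cluster pair
#'
#' One-dimensional bounded maximization of [mixture_loglik()] over
#' `w` in `[0, 1]` (Brent's method; the objective is concave in `w`, so
#' the optimum is unique unless `p = q` on the support of `y`). Boundary
#' candidates `w = 0` and `w = 1` are compared against the interior
#' optimum. When `p` and `q` coincide on the support the likelihood is
#' flat; `w = 0.5` is returned with `flagged = TRUE`.
#'
#' @inheritParams mixture_loglik
#' @param tol convergence tolerance on `w` (default 1e-8).
#' @return list with `w_hat`, `loglik`, `flagged`.
#' @export
estimate_w <- function(y, p, q, tol = 1e-8) {
  stopifnot(length(y) == length(p), length(p) == length(q))
  idx <- which(y > 0)
  if (!length(idx)) stop("empty count vector")
  ys <- y[idx]; ps <- p[idx]; qs <- q[idx]
  if (all(ps == qs)) {
    return(list(w_hat = 0.5,
                loglik = mixture_loglik(y, p, q, 0.5),
                flagged = TRUE))
  }
  f <- function(w) {
    mix <- w * ps + (1 - w) * qs
    if (any(mix <= 0)) return(-Inf)
    sum(ys * log(mix))
  }
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand_w <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, f(0), f(1))
  best <- which.max(cand_ll)
  list(w_hat = cand_w[best], loglik = cand_ll[best], flagged = FALSE)
}

#' Select the most likely cluster pair for a double-incubated cell
#'
#' The mixing fraction is profiled out per candidate pair: for every
#' cluster pair `(c, d)` the likelihood is maximized over `w`, and the
#' pair with the highest profiled log-likelihood is selected (ties broken
#' by cluster index order). The confidence is the posterior probability of
#' the selected pair under a uniform prior over pairs (softmax of the
#' profiled log-likelihoods).
#'
#' @param y count vector of one double-incubated cell.
#' @param profiles1,profiles2 `cluster_profiles` for marks 1 and 2.
#' @param cell_id optional identifier stored in the result.
#' @return A `pair_fit`: `pair` (labels `c`, `d`), `w_hat`, `loglik`,
#'   `confidence`, and `loglik_table` over all pairs.
#' @export
select_pair <- function(y, profiles1, profiles2, cell_id = NA_character_) {
  stopifnot(inherits(profiles1, "cluster_profiles"),
            inherits(profiles2, "cluster_profiles"))
  P1 <- profiles1$P; P2 <- profiles2$P
  if (nrow(P1) != length(y) || nrow(P2) != length(y))
    stop("profile region sets do not match the count vector")
  if (any(colSums(P1) == 0) || any(colSums(P2) == 0))
    stop("degenerate (all-zero) profile column")
  grid <- expand.grid(d = seq_len(ncol(P2)), c = seq_len(ncol(P1)))
  grid <- grid[order(grid$c, grid$d), ]
  fits <- lapply(seq_len(nrow(grid)), function(r) {
    estimate_w(y, P1[, grid$c[r]], P2[, grid$d[r]])
  })
  tab <- data.frame(c = colnames(P1)[grid$c], d = colnames(P2)[grid$d],
                    c_index = grid$c, d_index = grid$d,
                    w_hat = vapply(fits, `[[`, numeric(1), "w_hat"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    stringsAsFactors = FALSE)
  best <- order(-tab$loglik, tab$c_index, tab$d_index)[1]
  rel <- exp(tab$loglik - max(tab$loglik))
  tab$posterior <- rel / sum(rel)
  structure(list(cell_id = cell_id,
                 pair = c(c = tab$c[best], d = tab$d[best]),
                 w_hat = tab$w_hat[best],
                 loglik = tab$loglik[best],
                 confidence = tab$posterior[best],
                 loglik_table = tab),
            class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("pair_fit %s: (%s, %s), w = %.4f, confidence = %.4f\n",
              x$cell_id, x$pair[["c"]], x$pair[["d"]], x$w_hat,
              x$confidence))
  invisible(x)
}

#' Per-region mark-1 assignment probabilities
#'
#' Given the fitted cluster pair profiles and mixing fraction, the
#' probability that a read at region `g` belongs to mark 1 is
#' `P_g = w * p_g / (w * p_g + (1 - w) * q_g)`. Regions where the mixture
#' probability is 0 are undefined and returned as `NA`.
#'
#' @param p,q profile vectors of the fitted cluster pair.
#' @param w mixing fraction in `[0, 1]`.
#' @return Numeric vector of probabilities in `[0, 1]` (with `NA` masks).
#' @export
assignment_probabilities <- function(p, q, w) {
  stopifnot(length(p) == length(q), w >= 0, w <= 1)
  num <- w * p
  den <- num + (1 - w) * q
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Split a double-incubated count vector into two mark-specific vectors
#'
#' In `"sampled"` mode each region's reads are assigned to mark 1 by a
#' binomial draw with the region's assignment probability, giving integer
#' vectors with `y1 + y2 = y` exactly. In `"expected"` mode the fractional
#' expected split `y1 = P * y` is returned.
#'
#' @param y count vector.
#' @param probs assignment probabilities from
#'   [assignment_probabilities()] (`NA` allowed only where `y = 0`).
#' @param mode `"sampled"` (default) or `"expected"`.
#' @param seed integer seed for sampled mode.
#' @return An `unmixed_cell`: `y1`, `y2`, `mode`, `seed`.
#' @export
split_counts <- function(y, probs, mode = c("sampled", "expected"),
                         seed = 1L, cell_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(y) == length(probs))
  bad <- which(y > 0 & is.na(probs))
  if (length(bad))
    stop("counts at regions with undefined assignment probability: ",
         paste(utils::head(bad, 5), collapse = ", "))
  y1 <- numeric(length(y))
  idx <- which(y > 0)
  if (mode == "sampled") {
    y1[idx] <- with_seed(seed, stats::rbinom(length(idx), y[idx],
                                             probs[idx]))
  } else {
    y1[idx] <- probs[idx] * y[idx]
  }
  structure(list(cell_id = cell_id, y1 = y1, y2 = y - y1, mode = mode,
                 seed = if (mode == "sampled") as.integer(seed) else NA),
            class = "unmixed_cell")
}

#' Log ratio of mark totals in an unmixed cell
#'
#' `log2((sum(y1) + pseudocount) / (sum(y2) + pseudocount))`, the
#' cell-level balance between the two marks (e.g. H3K36me3 vs H3K9me3
#' cuts).
#'
#' @param unmixed an `unmixed_cell` (or list with `y1`, `y2`).
#' @param pseudocount non-negative; default 1.
#' @return Scalar log2 ratio.
#' @export
mark_ratio <- function(unmixed, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  t1 <- sum(unmixed$y1)
  t2 <- sum(unmixed$y2)
  if (pseudocount == 0 && min(t1, t2) == 0)
    stop("zero mark total with zero pseudocount")
  log2((t1 + pseudocount) / (t2 + pseudocount))
}

#' Deconvolve a full double-incubated dataset
#'
#' Runs the per-cell pipeline — cluster-pair selection, mixing-fraction
#' estimation, per-region assignment probabilities, count splitting — for
#' every double-incubated cell, then projects the unmixed counts back into
#' the latent spaces of the two training models by fold-in. Cells whose
#' pair confidence falls below `confidence_threshold` (cells bordering
#' between clusters) are flagged and excluded from the projections but
#' retained in the report.
#'
#' @param double_counts [mark_counts()] of double-incubated cells.
#' @param model1,model2 fitted `topic_model`s for the two marks.
#' @param clusters1,clusters2 per-cell cluster labels for the training
#'   cells of each model (passed to [cluster_profiles()]).
#' @param confidence_threshold minimum pair confidence (default 0.99).
#' @param mode split mode, `"sampled"` (default) or `"expected"`.
#' @param seed integer seed (split sampling and fold-in).
#' @param fold_in_iter Gibbs sweeps for fold-in (default 100).
#' @return list with `fits` (per-cell data.frame: cell, c, d, w_hat,
#'   loglik, confidence, flagged), `unmixed1`/`unmixed2` (`mark_counts`
#'   over all cells), `latent1`/`latent2` (fold-in coordinates of kept
#'   cells), `profiles1`/`profiles2`, and `assignment_probs` (per selected
#'   pair, region x pair matrix of P_g).
#' @export
unmix_dataset <- function(double_counts, model1, model2, clusters1,
                          clusters2, confidence_threshold = 0.99,
                          mode = c("sampled", "expected"), seed = 1L,
                          fold_in_iter = 100L) {
  mode <- match.arg(mode)
  obj <- as_mark_counts(double_counts)
  stopifnot_same_regions(obj, structure(list(regions = model1$regions),
                                        class = "mark_counts"))
  stopifnot_same_regions(obj, structure(list(regions = model2$regions),
                                        class = "mark_counts"))
  tot <- Matrix::colSums(obj$counts)
  if (any(tot == 0))
    stop("empty double-incubated cell(s): ",
         paste(colnames(obj$counts)[tot == 0], collapse = ", "))
  prof1 <- cluster_profiles(model1, clusters1)
  prof2 <- cluster_profiles(model2, clusters2)
  n <- ncol(obj$counts)
  G <- nrow(obj$counts)
  fits <- vector("list", n)
  y1 <- matrix(0, G, n)
  y2 <- matrix(0, G, n)
  pair_key <- character(n)
  for (i in seq_len(n)) {
    y <- as.numeric(obj$counts[, i])
    fit <- select_pair(y, prof1, prof2, cell_id = colnames(obj$counts)[i])
    P <- assignment_probabilities(prof1$P[, fit$pair[["c"]]],
                                  prof2$P[, fit$pair[["d"]]], fit$w_hat)
    sp <- split_counts(y, P, mode = mode, seed = derive_seed(seed, i),
                       cell_id = fit$cell_id)
    y1[, i] <- sp$y1
    y2[, i] <- sp$y2
    pair_key[i] <- paste(fit$pair[["c"]], fit$pair[["d"]], sep = "|")
    fits[[i]] <- data.frame(cell = fit$cell_id, c = fit$pair[["c"]],
                            d = fit$pair[["d"]], w_hat = fit$w_hat,
                            loglik = fit$loglik,
                            confidence = fit$confidence,
                            stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, fits)
  fits$flagged <- fits$confidence < confidence_threshold
  keep <- !fits$flagged
  cells_out <- obj$cells
  mk <- function(m) {
    mm <- Matrix::Matrix(m, sparse = TRUE)
    mark_counts(mm, regions = obj$regions, cells = cells_out,
                real_valued = (mode == "expected"))
  }
  unmixed1 <- mk(y1)
  unmixed2 <- mk(y2)
  lat1 <- lat2 <- NULL
  if (any(keep)) {
    lat1 <- t(fold_in(model1, subset_cells(unmixed1, which(keep)),
                      n_iter = fold_in_iter, seed = derive_seed(seed, 91)))
    lat2 <- t(fold_in(model2, subset_cells(unmixed2, which(keep)),
                      n_iter = fold_in_iter, seed = derive_seed(seed, 92)))
  }
  # per-pair assignment probability tracks for the pairs actually selected
  pairs <- unique(pair_key)
  ap <- vapply(pairs, function(k) {
    cd <- strsplit(k, "|", fixed = TRUE)[[1]]
    w_med <- stats::median(fits$w_hat[pair_key == k])
    assignment_probabilities(prof1$P[, cd[1]], prof2$P[, cd[2]], w_med)
  }, numeric(G))
  ap <- matrix(ap, nrow = G, dimnames = list(rownames(prof1$P), pairs))
  list(fits = fits, unmixed1 = unmixed1, unmixed2 = unmixed2,
       latent1 = lat1, latent2 = lat2, profiles1 = prof1,
       profiles2 = prof2, assignment_probs = ap)
}
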