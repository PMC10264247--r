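#' Fit a latent Dirichlet allocation model on a count matrix
#'
#' Collapsed Gibbs sampling over token-level topic indicators on the
#' region x cell count matrix of single-incubated cells. The model treats
#' each cell as a mixture over `K` topics (Dirichlet prior `alpha` on the
#' per-cell topic weights) and each topic as a multinomial over genomic
#' bins (Dirichlet prior `delta`). Point estimates are read off the count
#' tables of the final sweep (or averaged over post-burn-in sweeps):
#' `V[g, k] = (n_gk + delta) / (n_k + G * delta)` and
#' `U[k, i] = (n_kc + alpha) / (N_i + K * alpha)`.
#'
#' @param counts a [mark_counts()] object (integer counts) or sparse
#'   matrix; cells with zero total counts are rejected.
#' @param K number of topics (default 30).
#' @param alpha Dirichlet prior on cell-topic weights (default 1.67, the
#'   `50 / K` convention at `K = 30`).
#' @param delta Dirichlet prior on topic-region probabilities (default 0.1).
#' @param n_iter Gibbs sweeps (default 1000).
#' @param burn_in sweeps discarded before averaging when
#'   `estimate = "average"` (default 200).
#' @param seed integer seed; fits are bit-reproducible given the seed.
#' @param estimate `"final"` (count tables of the last sweep) or
#'   `"average"` (tables averaged over post-burn-in sweeps).
#' @return A `topic_model` with fields `V` (G x K, columns on the simplex),
#'   `U` (K x n_cells, columns on the simplex), hyperparameters, `regions`
#'   and cell barcodes.
#' @export
fit_lda <- function(counts, K = 30L, alpha = 1.67, delta = 0.1,
                    n_iter = 1000L, burn_in = 200L, seed = 1L,
                    estimate = c("final", "average")) {
  estimate <- match.arg(estimate)
  obj <- as_mark_counts(counts)
  m <- obj$counts
  if (ncol(m) < K)
    stop("need at least K = ", K, " cells, got ", ncol(m))
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  trip <- sparse_triplets(m)
  res <- lda_gibbs_cpp(trip$i, trip$j, trip$x, nrow(m), ncol(m), as.integer(K),
                       alpha, delta, as.integer(n_iter), as.integer(burn_in),
                       as.integer(seed), estimate == "average")
  V <- sweep(res$n_gk + delta, 2, res$n_k + nrow(m) * delta, "/")
  U <- sweep(res$n_kc + alpha, 2, Matrix::colSums(res$n_kc) + K * alpha, "/")
  dimnames(V) <- list(rownames(m), sprintf("topic%d", seq_len(K)))
  dimnames(U) <- list(sprintf("topic%d", seq_len(K)), colnames(m))
  structure(list(V = V, U = U, K = as.integer(K), alpha = alpha,
                 delta = delta, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 estimate = estimate, regions = obj$regions,
                 barcodes = colnames(m)),
            class = "topic_model")
}

as_mark_counts <- function(x) {
  if (inherits(x, "mark_counts")) return(x)
  mark_counts(x)
}

sparse_triplets <- function(m) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@x != 0
  list(i = tm@i[keep], j = tm@j[keep], x = as.integer(tm@x[keep]))
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf(
    "topic_model: %d regions, %d cells, K = %d (alpha = %g, delta = %g)\n",
    nrow(x$V), ncol(x$U), x$K, x$alpha, x$delta))
  invisible(x)
}

#' Estimate topic weights for new cells under a fitted model
#'
#' The region-topic matrix `V` is held fixed; only the per-cell topic
#' counts of the new cells are Gibbs-sampled. Used to project unmixed
#' count vectors back into the latent space learned from the
#' single-incubated training data.
#'
#' @param model a fitted `topic_model`.
#' @param counts_new counts over the same region set ([mark_counts()] or
#'   matrix). Real-valued (expected-mode) matrices are rounded to integer
#'   token counts.
#' @param n_iter Gibbs sweeps (default 100).
#' @param burn_in sweeps discarded before averaging the topic counts
#'   (default half of `n_iter`).
#' @param seed integer seed.
#' @return A K x n_new matrix of topic weights, columns summing to 1.
#' @export
fold_in <- function(model, counts_new, n_iter = 100L,
                    burn_in = n_iter %/% 2L, seed = 1L) {
  stopifnot(inherits(model, "topic_model"))
  obj <- if (inherits(counts_new, "mark_counts")) counts_new
         else mark_counts(counts_new, regions = model$regions,
                          real_valued = TRUE)
  ids <- region_ids(obj$regions)
  if (length(ids) != nrow(model$V) || !all(ids == region_ids(model$regions)))
    stop("region sets do not match the model")
  m <- round(obj$counts)
  if (ncol(m) == 0)
    return(matrix(numeric(0), nrow = model$K, ncol = 0,
                  dimnames = list(rownames(model$U), NULL)))
  trip <- sparse_triplets(m)
  n_kc <- lda_fold_in_cpp(trip$i, trip$j, trip$x, model$V, ncol(m),
                          model$alpha, as.integer(n_iter),
                          as.integer(burn_in), as.integer(seed))
  U <- sweep(n_kc + model$alpha, 2, colSums(n_kc) + model$K * model$alpha,
             "/")
  dimnames(U) <- list(rownames(model$U), colnames(m))
  U
}

#' Cluster-specific multinomial profiles from a fitted model
#'
#' For each cluster, the model-reconstructed per-cell region probabilities
#' `V %*% U[, i]` are averaged over the cells assigned to the cluster,
#' giving the genome-wide multinomial profile used as a training
#' distribution for deconvolution.
#'
#' @param model a fitted `topic_model`.
#' @param cluster_assignments per-cell cluster labels, either named by
#'   barcode or in the model's cell order.
#' @return A `cluster_profiles` object: matrix `P` (regions x clusters,
#'   columns on the simplex) plus labels.
#' @export
cluster_profiles <- function(model, cluster_assignments) {
  stopifnot(inherits(model, "topic_model"))
  n <- ncol(model$U)
  cl <- cluster_assignments
  if (!is.null(names(cl))) {
    miss <- setdiff(model$barcodes, names(cl))
    if (length(miss))
      stop("no cluster label for barcode(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    cl <- cl[model$barcodes]
  }
  if (length(cl) != n) stop("need one cluster label per cell")
  if (anyNA(cl)) stop("NA cluster labels")
  labs <- sort(unique(as.character(cl)))
  P <- vapply(labs, function(lab) {
    idx <- which(as.character(cl) == lab)
    rowMeans(model$V %*% model$U[, idx, drop = FALSE])
  }, numeric(nrow(model$V)))
  P <- as.matrix(P)
  dimnames(P) <- list(rownames(model$V), labs)
  structure(list(P = P, labels = labs, K = model$K,
                 regions = model$regions),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("cluster_profiles: %d regions x %d clusters (%s)\n",
              nrow(x$P), length(x$labels), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Top cluster-specific bins
#'
#' Ranks the per-cluster bin loadings and returns the `n_top` bins with the
#' largest loadings for each cluster (descending; ties broken by bin
#' index). Typical choices are 150 bins for well-separated tissue atlases
#' and 250 for more heterogeneous data.
#'
#' @param profiles a `cluster_profiles` object (or a `topic_model`, in
#'   which case topic columns of `V` are ranked instead).
#' @param n_top number of bins per cluster (default 150).
#' @return A named list of integer bin-index vectors, one per cluster.
#' @export
top_cluster_bins <- function(profiles, n_top = 150L) {
  P <- if (inherits(profiles, "cluster_profiles")) profiles$P
       else if (inherits(profiles, "topic_model")) profiles$V
       else stop("need cluster_profiles or topic_model")
  if (n_top > nrow(P)) stop("n_top exceeds the number of bins")
  out <- lapply(seq_len(ncol(P)), function(j)
    order(-P[, j], seq_len(nrow(P)))[seq_len(n_top)])
  names(out) <- colnames(P)
  out
}

#' Per-cell latent coordinates
#'
#' Cell-topic weights transposed to a cells x K matrix, the coordinates
#' used for embedding, clustering and nearest-neighbor pooling.
#'
#' @param model a fitted `topic_model` or a K x n cell-topic weight matrix.
#' @return A cells x K matrix; rows sum to 1.
#' @export
latent_coordinates <- function(model) {
  U <- if (inherits(model, "topic_model")) model$U else model
  t(U)
}
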