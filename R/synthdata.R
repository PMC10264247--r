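#' @useDynLib chromunmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Small deterministic seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles the parameters of the Poisson count simulator: the number of
#' genomic bins, cells per antibody-incubation condition, technical
#' replicates, the fraction of bins whose rates are swapped between the two
#' marks, the number of cell types, and the log-normal stand-in distribution
#' for the per-bin Poisson rates.
#'
#' @param n_loci number of genomic bins (default 10,000).
#' @param n_cells_per_condition cells per condition per cell type
#'   (default 250).
#' @param n_replicates technical replicates the cells are partitioned into
#'   (default 3).
#' @param swap_fraction fraction `x` in `[0, 1]` of bins swapped between the
#'   highest- and lowest-rate tails to control mark overlap.
#' @param n_celltypes number of cell types (each gets its own bin shuffle).
#' @param rate_distribution_params `c(meanlog, sdlog)` of the log-normal from
#'   which per-bin Poisson rates are drawn.
#' @param seed integer master seed; every random draw in the simulator is
#'   derived deterministically from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10000L, n_cells_per_condition = 250L,
                       n_replicates = 3L, swap_fraction = 0.5,
                       n_celltypes = 1L,
                       rate_distribution_params = c(meanlog = -1.5,
                                                    sdlog = 1.2),
                       seed = 1L) {
  stopifnot(n_loci >= 1, n_cells_per_condition >= 1, n_replicates >= 1,
            n_celltypes >= 1)
  if (swap_fraction < 0 || swap_fraction > 1)
    stop("swap_fraction must be in [0, 1]")
  structure(list(n_loci = as.integer(n_loci),
                 n_cells_per_condition = as.integer(n_cells_per_condition),
                 n_replicates = as.integer(n_replicates),
                 swap_fraction = swap_fraction,
                 n_celltypes = as.integer(n_celltypes),
                 rate_distribution_params = rate_distribution_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

new_locus_means <- function(lam, mark_id, celltype_id, seed) {
  if (length(lam) < 1) stop("need at least one locus")
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("rates must be finite and non-negative")
  structure(list(lam = as.numeric(lam), mark_id = mark_id,
                 celltype_id = celltype_id, seed = as.integer(seed)),
            class = "locus_means")
}

#' Draw per-bin Poisson rates for one cell type
#'
#' Rates are drawn once from the configured log-normal (shared multiset
#' across cell types) and then shuffled in a cell-type-specific order, so
#' each cell type has its own profile while the genome-wide rate
#' distribution is preserved.
#'
#' @param config a [sim_config()].
#' @param celltype integer cell-type index in `1:n_celltypes`.
#' @return A `locus_means` object with fields `lam`, `mark_id`,
#'   `celltype_id`, `seed`.
#' @export
simulate_locus_means <- function(config, celltype = 1L) {
  stopifnot(inherits(config, "sim_config"))
  celltype <- as.integer(celltype)
  if (celltype < 1 || celltype > config$n_celltypes)
    stop("celltype out of range")
  G <- config$n_loci
  if (G <= 0) stop("n_loci must be positive")
  p <- config$rate_distribution_params
  lam <- with_seed(config$seed,
                   stats::rlnorm(G, meanlog = p[[1]], sdlog = p[[2]]))
  # cell type 1 keeps the base order; others get their own shuffle
  if (celltype > 1L) {
    ord <- with_seed(derive_seed(config$seed, 100 + celltype), sample.int(G))
    lam <- lam[ord]
  }
  new_locus_means(lam, mark_id = "mark1",
                  celltype_id = sprintf("celltype%d", celltype),
                  seed = config$seed)
}

#' Derive mark-2 rates by swapping rate tails
#'
#' The top `floor(x * G)` bins by rate exchange rates with the bottom
#' `floor(x * G)` bins (the i-th highest with the i-th lowest, ties broken
#' by bin index); all other bins are unchanged. Small `x` gives two marks
#' with mostly shared bin usage, large `x` mostly mutually exclusive usage.
#'
#' @param means a `locus_means` object (mark 1 rates).
#' @param swap_fraction fraction `x` in `[0, 1]`.
#' @return A `locus_means` object for mark 2 over the same bins.
#' @export
derive_mark2_means <- function(means, swap_fraction) {
  stopifnot(inherits(means, "locus_means"))
  if (swap_fraction < 0 || swap_fraction > 1)
    stop("swap_fraction must be in [0, 1]")
  lam <- means$lam
  G <- length(lam)
  n_swap <- floor(swap_fraction * G)
  if (2 * n_swap > G)
    stop("swap sets would intersect: 2 * floor(x * G) > G")
  if (n_swap > 0) {
    hi <- order(-lam, seq_along(lam))[seq_len(n_swap)]
    lo <- order(lam, seq_along(lam))[seq_len(n_swap)]
    tmp <- lam[hi]
    lam[hi] <- lam[lo]
    lam[lo] <- tmp
  }
  new_locus_means(lam, mark_id = "mark2", celltype_id = means$celltype_id,
                  seed = means$seed)
}

#' Simulate a sparse count matrix from per-bin rates
#'
#' Independent Poisson draws per bin per cell; cells are assigned to
#' technical replicates round-robin.
#'
#' @param means a `locus_means` object.
#' @param n_cells number of cells to draw.
#' @param seed integer seed for the draws.
#' @param condition condition label stored in the cell metadata
#'   (`"mark1"`, `"mark2"` or `"double"`).
#' @param n_replicates number of technical replicates.
#' @param barcode_prefix prefix for fabricated barcodes.
#' @return A [mark_counts()] object; the rate vector is kept in field
#'   `lam` for ground-truth bookkeeping.
#' @export
simulate_counts <- function(means, n_cells, seed,
                            condition = means$mark_id, n_replicates = 1L,
                            barcode_prefix = paste(condition,
                                                   means$celltype_id,
                                                   sep = "_")) {
  stopifnot(inherits(means, "locus_means"))
  if (n_cells <= 0) stop("n_cells must be positive")
  G <- length(means$lam)
  m <- with_seed(seed, {
    x <- stats::rpois(G * n_cells, rep(means$lam, times = n_cells))
    Matrix::Matrix(x, nrow = G, ncol = n_cells, sparse = TRUE)
  })
  cells <- data.frame(
    barcode = sprintf("%s_c%03d", barcode_prefix, seq_len(n_cells)),
    condition = condition,
    celltype = means$celltype_id,
    replicate = ((seq_len(n_cells) - 1L) %% n_replicates) + 1L,
    stringsAsFactors = FALSE)
  out <- mark_counts(m, cells = cells)
  out$lam <- means$lam
  out
}

#' Combine two single-incubated matrices into double-incubated cells
#'
#' Cell i of mark 1 is paired with cell i of mark 2; counts are added
#' elementwise. The ground truth records, per bin, the expected fraction
#' `p_true = lam1 / (lam1 + lam2)` of double-incubated reads belonging to
#' mark 1 (`NA` where both rates are 0), and the implied global mixing
#' fraction `w_true = sum(lam1) / (sum(lam1) + sum(lam2))`.
#'
#' @param counts1,counts2 [mark_counts()] objects from [simulate_counts()]
#'   over the same bins with equal cell numbers.
#' @return A list with elements `double` (a `mark_counts`) and `truth`
#'   (list with `p_true`, `celltype_labels`, `w_true`).
#' @export
simulate_double <- function(counts1, counts2) {
  stopifnot(inherits(counts1, "mark_counts"), inherits(counts2, "mark_counts"))
  stopifnot_same_regions(counts1, counts2)
  if (ncol(counts1$counts) != ncol(counts2$counts))
    stop("cell counts differ between the two marks")
  if (is.null(counts1$lam) || is.null(counts2$lam))
    stop("input matrices must carry their rate vectors (simulate_counts)")
  m <- counts1$counts + counts2$counts
  n <- ncol(m)
  cells <- data.frame(
    barcode = sprintf("double_%s_c%03d", counts1$cells$celltype[1],
                      seq_len(n)),
    condition = "double",
    celltype = counts1$cells$celltype,
    replicate = counts1$cells$replicate,
    stringsAsFactors = FALSE)
  dbl <- mark_counts(m, regions = counts1$regions, cells = cells)
  lam1 <- counts1$lam
  lam2 <- counts2$lam
  tot <- lam1 + lam2
  p_true <- ifelse(tot > 0, lam1 / tot, NA_real_)
  truth <- list(p_true = p_true,
                celltype_labels = cells$celltype,
                w_true = sum(lam1) / sum(tot))
  list(double = dbl, truth = truth)
}

#' Column-bind mark_counts objects over the same bins
#' @param ... `mark_counts` objects sharing a region set.
#' @return A single combined `mark_counts`.
#' @export
bind_cells <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "mark_counts"))
    xs <- xs[[1]]
  for (x in xs[-1]) stopifnot_same_regions(xs[[1]], x)
  counts <- do.call(cbind, lapply(xs, function(x) x$counts))
  cols <- Reduce(union, lapply(xs, function(x) names(x$cells)))
  cells <- do.call(rbind, lapply(xs, function(x) {
    df <- x$cells
    for (nm in setdiff(cols, names(df))) df[[nm]] <- NA
    df[, cols, drop = FALSE]
  }))
  mark_counts(counts, regions = xs[[1]]$regions, cells = cells,
              real_valued = any(vapply(xs, function(x) x$real_valued,
                                       logical(1))))
}

#' Simulate a full two-mark benchmark dataset
#'
#' For each cell type: draw mark-1 rates, derive mark-2 rates by the
#' tail-swap rule, draw `n_cells_per_condition` single-incubated cells per
#' mark, and add paired draws to form double-incubated cells. Cell types are
#' concatenated into three condition-level matrices.
#'
#' @param config a [sim_config()].
#' @return A list with `mark1`, `mark2`, `double` (`mark_counts`),
#'   `truth` (per cell type: `p_true`, `w_true`), and `means` (per cell
#'   type, per mark `locus_means`).
#' @export
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m1 <- list(); m2 <- list(); dd <- list(); truth <- list(); means <- list()
  for (ct in seq_len(config$n_celltypes)) {
    mu1 <- simulate_locus_means(config, ct)
    mu2 <- derive_mark2_means(mu1, config$swap_fraction)
    c1 <- simulate_counts(mu1, config$n_cells_per_condition,
                          seed = derive_seed(config$seed, 1000 + ct),
                          condition = "mark1",
                          n_replicates = config$n_replicates)
    c2 <- simulate_counts(mu2, config$n_cells_per_condition,
                          seed = derive_seed(config$seed, 2000 + ct),
                          condition = "mark2",
                          n_replicates = config$n_replicates)
    c1d <- simulate_counts(mu1, config$n_cells_per_condition,
                           seed = derive_seed(config$seed, 3000 + ct),
                           condition = "mark1",
                           n_replicates = config$n_replicates)
    c2d <- simulate_counts(mu2, config$n_cells_per_condition,
                           seed = derive_seed(config$seed, 4000 + ct),
                           condition = "mark2",
                           n_replicates = config$n_replicates)
    d <- simulate_double(c1d, c2d)
    ctid <- mu1$celltype_id
    m1[[ctid]] <- c1
    m2[[ctid]] <- c2
    dd[[ctid]] <- d$double
    truth[[ctid]] <- d$truth
    means[[ctid]] <- list(mark1 = mu1, mark2 = mu2)
  }
  list(mark1 = bind_cells(m1), mark2 = bind_cells(m2),
       double = bind_cells(dd), truth = truth, means = means)
}

#' Per-bin rates placed at evenly spaced mark-1 fractions
#'
#' Alternative to the tail-swap rule: a total rate is drawn per bin from the
#' configured log-normal and split between the marks so that the expected
#' mark-1 read fraction `p` of each bin sits exactly at one of `n_points`
#' evenly spaced design values in `[0, 1]`. Used for calibration studies of
#' the inferred assignment probabilities.
#'
#' @param config a [sim_config()].
#' @param celltype cell-type index.
#' @param n_points number of design values (default 101).
#' @return A list with `means1`, `means2` (`locus_means`) and `p_design`
#'   (per-bin true mark-1 fraction).
#' @export
calibration_design_means <- function(config, celltype = 1L,
                                     n_points = 101L) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_loci
  if (n_points < 2 || n_points > G) stop("invalid n_points")
  pr <- config$rate_distribution_params
  lam_tot <- with_seed(derive_seed(config$seed, 5000 + celltype),
                       stats::rlnorm(G, meanlog = pr[[1]], sdlog = pr[[2]]))
  design <- seq(0, 1, length.out = n_points)
  p_design <- design[((seq_len(G) - 1L) %% n_points) + 1L]
  if (celltype > 1L) {
    ord <- with_seed(derive_seed(config$seed, 100 + celltype), sample.int(G))
    p_design <- p_design[ord]
  }
  ctid <- sprintf("celltype%d", celltype)
  means1 <- new_locus_means(lam_tot * p_design, "mark1", ctid, config$seed)
  means2 <- new_locus_means(lam_tot * (1 - p_design), "mark2", ctid,
                            config$seed)
  list(means1 = means1, means2 = means2, p_design = p_design)
}

#' Simulate a pseudotime course for two coupled marks
#'
#' Cells are placed uniformly on pseudotime `[0, 1]`. Mark-1 intensity at
#' each region follows a user-supplied driver profile of `t`; mark-2
#' intensity follows first-order exponential relaxation
#' `y0 + A * (1 - exp(-gamma * t))` with per-region kinetics. Counts are
#' Poisson draws from the intensities; double-incubated cells are sums of
#' fresh draws from both marks at the same `t` (optionally offset for
#' mark 2).
#'
#' @param n_cells cells per condition.
#' @param n_regions number of regions.
#' @param kinetics data.frame or list with per-region `y0`, `A`, `gamma`.
#' @param driver_profiles function of a pseudotime vector returning an
#'   `n_regions x length(t)` matrix of non-negative mark-1 intensities.
#' @param seed integer seed.
#' @param t2_offset pseudotime offset added (and clamped to `[0, 1]`) for
#'   the mark-2 component of double cells.
#' @return list with `mark1`, `mark2`, `double` (`mark_counts`), `t`
#'   (true pseudotime per cell) and `t2` (mark-2 pseudotime of doubles).
#' @export
simulate_pseudotime_course <- function(n_cells, n_regions, kinetics,
                                       driver_profiles, seed,
                                       t2_offset = 0) {
  stopifnot(n_cells > 0, n_regions > 0)
  kin <- as.data.frame(kinetics)
  stopifnot(nrow(kin) == n_regions, all(c("y0", "A", "gamma") %in% names(kin)))
  t <- with_seed(derive_seed(seed, 1), sort(stats::runif(n_cells)))
  relax <- function(tt) {
    out <- outer(seq_len(n_regions), tt, function(g, x)
      kin$y0[g] + kin$A[g] * (1 - exp(-kin$gamma[g] * x)))
    out
  }
  int1 <- driver_profiles(t)
  if (!is.matrix(int1) || nrow(int1) != n_regions || ncol(int1) != n_cells)
    stop("driver_profiles must return an n_regions x n_cells matrix")
  if (any(int1 < 0)) stop("negative mark-1 intensity")
  int2 <- relax(t)
  if (any(int2 < 0)) stop("negative mark-2 intensity")
  t2 <- pmin(pmax(t + t2_offset, 0), 1)
  int1d <- driver_profiles(t)
  int2d <- relax(t2)
  draw <- function(intensity, off, cond) {
    m <- with_seed(derive_seed(seed, off),
                   Matrix::Matrix(stats::rpois(length(intensity), intensity),
                                  nrow = n_regions, sparse = TRUE))
    cells <- data.frame(barcode = sprintf("%s_c%04d", cond, seq_len(n_cells)),
                        condition = cond, celltype = "course",
                        replicate = 1L, stringsAsFactors = FALSE)
    mark_counts(m, cells = cells)
  }
  mark1 <- draw(int1, 11, "mark1")
  mark2 <- draw(int2, 12, "mark2")
  dbl1 <- with_seed(derive_seed(seed, 13),
                    matrix(stats::rpois(length(int1d), int1d),
                           nrow = n_regions))
  dbl2 <- with_seed(derive_seed(seed, 14),
                    matrix(stats::rpois(length(int2d), int2d),
                           nrow = n_regions))
  cells <- data.frame(barcode = sprintf("double_c%04d", seq_len(n_cells)),
                      condition = "double", celltype = "course",
                      replicate = 1L, stringsAsFactors = FALSE)
  dbl <- mark_counts(Matrix::Matrix(dbl1 + dbl2, sparse = TRUE),
                     cells = cells)
  list(mark1 = mark1, mark2 = mark2, double = dbl, t = t, t2 = t2,
       intensity1 = int1, intensity2 = int2)
}
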