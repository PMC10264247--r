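#' Confusion matrix and one-vs-rest classification metrics
#'
#' Cross-tabulates true against predicted class labels (cluster pairs are
#' compared as a single pasted label) and computes, per class `c`,
#' one-vs-rest false discovery rate `FP / (FP + TP)`, sensitivity
#' `TP / (TP + FN)` and specificity `TN / (TN + FP)`. A class with no
#' true and no predicted instances has undefined metrics, reported as
#' `NA`.
#'
#' @param true_labels per-cell true labels.
#' @param predicted per-cell predicted labels, or a data.frame with
#'   columns `c` and `d` (a pair prediction, pasted as `"c|d"`).
#' @return An `eval_report` with `confusion` (rows = true, cols =
#'   predicted) and `metrics` (per class FDR, sensitivity, specificity).
#' @export
confusion_and_metrics <- function(true_labels, predicted) {
  if (is.data.frame(predicted)) {
    stopifnot(all(c("c", "d") %in% names(predicted)))
    predicted <- paste(predicted$c, predicted$d, sep = "|")
  }
  if (length(true_labels) != length(predicted))
    stop("label vectors differ in length")
  labs <- sort(unique(c(
    if (is.factor(true_labels)) levels(true_labels),
    if (is.factor(predicted)) levels(predicted),
    as.character(true_labels), as.character(predicted))))
  conf <- table(factor(true_labels, levels = labs),
                factor(predicted, levels = labs))
  conf <- unclass(conf)
  total <- sum(conf)
  metrics <- lapply(labs, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    tn <- total - tp - fp - fn
    if (tp + fp + fn == 0)
      return(data.frame(class = cl, fdr = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(class = cl,
               fdr = if (tp + fp > 0) fp / (fp + tp) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(confusion = conf, metrics = do.call(rbind, metrics)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\nconfusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Calibration of inferred assignment probabilities
#'
#' Loci are binned by their true mark-1 read fraction into `n_bins`
#' equal-width bins over `[0, 1]`; per bin the mean inferred probability
#' and its normal-approximation 95% confidence interval (across loci) are
#' reported. With the default 101 bins, design points placed at
#' `0, 0.01, ..., 1` each occupy their own bin.
#'
#' @param p_true per-locus true probabilities in `[0, 1]`.
#' @param p_hat per-locus inferred probabilities (`NA` entries dropped).
#' @param n_bins number of bins (default 101).
#' @return data.frame: `bin`, `center`, `n`, `mean_p_true`, `mean_p_hat`,
#'   `ci_lo`, `ci_hi`. Empty bins are kept with `n = 0`.
#' @export
calibration <- function(p_true, p_hat, n_bins = 101L) {
  stopifnot(length(p_true) == length(p_hat))
  keep <- !is.na(p_true) & !is.na(p_hat)
  p_true <- p_true[keep]; p_hat <- p_hat[keep]
  if (any(p_true < 0 | p_true > 1) || any(p_hat < 0 | p_hat > 1))
    stop("probabilities must lie in [0, 1]")
  bin <- pmin(floor(p_true * n_bins) + 1L, n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    center <- (b - 0.5) / n_bins
    if (!length(idx))
      return(data.frame(bin = b, center = center, n = 0L,
                        mean_p_true = NA_real_, mean_p_hat = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    m <- mean(p_hat[idx])
    se <- if (length(idx) > 1) stats::sd(p_hat[idx]) / sqrt(length(idx))
          else 0
    data.frame(bin = b, center = center, n = length(idx),
               mean_p_true = mean(p_true[idx]), mean_p_hat = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  })
  do.call(rbind, out)
}

#' Classify loci by inferred assignment probability
#'
#' Labels a locus as mark 1 when its inferred probability is at or above
#' the cutoff and mark 2 below it; masked (`NA`) probabilities stay
#' unlabeled. The cutoff is configurable (cluster-specific cutoffs can be
#' applied by calling per cluster).
#'
#' @param p_hat per-locus probabilities.
#' @param cutoff in `(0, 1)`, default 0.5.
#' @return Character vector `"mark1"` / `"mark2"` (with `NA` for masked
#'   entries).
#' @export
classify_loci <- function(p_hat, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  ifelse(is.na(p_hat), NA_character_,
         ifelse(p_hat >= cutoff, "mark1", "mark2"))
}
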