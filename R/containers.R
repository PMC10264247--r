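#' Sparse region-by-cell count container
#'
#' The basic data object of the package: a sparse matrix of cut-fragment
#' counts over genomic bins (rows) and cells (columns), together with a bin
#' table (BED-style, 0-based half-open) and per-cell metadata. Counts are
#' non-negative integers for observed data; unmixed matrices produced in
#' `"expected"` mode are a real-valued variant and are flagged as such.
#'
#' @param counts matrix or sparse Matrix, regions x cells, non-negative.
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). If `NULL`, bins named `chrSim:0-1000` etc. are
#'   fabricated to match `nrow(counts)`.
#' @param cells data.frame of per-cell metadata; must contain a `barcode`
#'   column (unique). If `NULL`, barcodes `cell_1`, ... are fabricated.
#' @param real_valued logical; `TRUE` marks the fractional (expected-mode)
#'   variant, in which non-integer entries are permitted.
#' @return An object of class `mark_counts`.
#' @export
mark_counts <- function(counts, regions = NULL, cells = NULL,
                        real_valued = FALSE) {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!real_valued && any(counts@x != round(counts@x)))
    stop("non-integer counts in an integer count matrix; ",
         "use real_valued = TRUE for expected-mode matrices")
  G <- nrow(counts)
  n <- ncol(counts)
  if (is.null(regions)) regions <- fabricate_regions(G)
  if (is.null(cells)) {
    cells <- data.frame(barcode = sprintf("cell_%d", seq_len(n)),
                        stringsAsFactors = FALSE)
  }
  validate_regions(regions)
  if (nrow(regions) != G)
    stop("regions table has ", nrow(regions), " rows but counts has ",
         G, " rows")
  if (!("barcode" %in% names(cells))) stop("cells must have a barcode column")
  if (nrow(cells) != n)
    stop("cells table has ", nrow(cells), " rows but counts has ",
         n, " columns")
  dup <- cells$barcode[duplicated(cells$barcode)]
  if (length(dup))
    stop("duplicated barcode(s): ", paste(unique(dup), collapse = ", "))
  rownames(counts) <- region_ids(regions)
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, regions = regions, cells = cells,
                 real_valued = real_valued),
            class = "mark_counts")
}

fabricate_regions <- function(G, chrom = "chrSim", width = 1000L) {
  data.frame(chrom = chrom,
             start = as.integer((seq_len(G) - 1L) * width),
             end = as.integer(seq_len(G) * width),
             stringsAsFactors = FALSE)
}

validate_regions <- function(regions) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  bad <- which(regions$start >= regions$end)
  if (length(bad))
    stop("regions with start >= end at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- region_ids(regions)
  if (anyDuplicated(key))
    stop("duplicated region(s): ", key[duplicated(key)][1])
  invisible(TRUE)
}

region_ids <- function(regions) {
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}

#' @export
print.mark_counts <- function(x, ...) {
  cat(sprintf("mark_counts: %d regions x %d cells (%s), %d nonzero\n",
              nrow(x$counts), ncol(x$counts),
              if (x$real_valued) "real-valued" else "integer",
              length(x$counts@x)))
  if ("condition" %in% names(x$cells)) {
    tab <- table(x$cells$condition)
    cat("  conditions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.mark_counts <- function(x) dim(x$counts)

#' Subset cells of a mark_counts object
#' @param x a `mark_counts` object
#' @param idx integer, logical or barcode index over cells
#' @return a `mark_counts` with the selected cells
#' @export
subset_cells <- function(x, idx) {
  stopifnot(inherits(x, "mark_counts"))
  if (is.character(idx)) idx <- match(idx, x$cells$barcode)
  mark_counts(x$counts[, idx, drop = FALSE], x$regions,
              x$cells[idx, , drop = FALSE], real_valued = x$real_valued)
}

stopifnot_same_regions <- function(a, b) {
  ra <- if (inherits(a, "mark_counts")) region_ids(a$regions) else rownames(a)
  rb <- if (inherits(b, "mark_counts")) region_ids(b$regions) else rownames(b)
  if (length(ra) != length(rb) || !all(ra == rb))
    stop("region sets do not match")
  invisible(TRUE)
}
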