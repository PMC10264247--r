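#' Read a count matrix from MTX + BED + barcodes files
#'
#' Reads a Matrix Market coordinate file of region x cell counts, a BED
#' file of genomic bins (0-based half-open) and a tab-separated barcode
#' table with per-cell metadata, cross-checking all dimensions.
#'
#' @param mtx_path Matrix Market file (integer or real field).
#' @param bed_path BED file: chrom, start, end (no header).
#' @param barcodes_path TSV with header; first column `barcode`, optional
#'   `condition`, `celltype`, `replicate`, `day`.
#' @return A [mark_counts()] object.
#' @export
read_counts <- function(mtx_path, bed_path, barcodes_path) {
  for (f in c(mtx_path, bed_path, barcodes_path))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- Matrix::readMM(mtx_path)
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("malformed BED file: ", bed_path)
  regions <- data.frame(chrom = as.character(bed[[1]]),
                        start = as.integer(bed[[2]]),
                        end = as.integer(bed[[3]]),
                        stringsAsFactors = FALSE)
  bad <- which(!is.finite(regions$start) | !is.finite(regions$end) |
                 regions$start >= regions$end)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", bed_path)
  cells <- utils::read.table(barcodes_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!("barcode" %in% names(cells)))
    stop("barcodes file must have a 'barcode' column: ", barcodes_path)
  dup <- cells$barcode[duplicated(cells$barcode)]
  if (length(dup))
    stop("duplicated barcode '", dup[1], "' in ", barcodes_path)
  if (nrow(regions) != nrow(m) || nrow(cells) != ncol(m))
    stop("dimension mismatch: ", mtx_path, " is ", nrow(m), " x ", ncol(m),
         " but ", bed_path, " has ", nrow(regions), " regions and ",
         barcodes_path, " has ", nrow(cells), " barcodes")
  real_valued <- any(m@x != round(m@x))
  mark_counts(m, regions = regions, cells = cells,
              real_valued = real_valued)
}

#' Write a count matrix as MTX + BED + barcodes files
#'
#' The Matrix Market file uses the `integer` field for count matrices and
#' `real` for expected-mode (fractional) matrices; entries are written in
#' column-major order for deterministic output.
#'
#' @param matrix a [mark_counts()] object.
#' @param outdir output directory (created if needed).
#' @param prefix file name prefix (default `"counts"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_counts <- function(matrix, outdir, prefix = "counts") {
  stopifnot(inherits(matrix, "mark_counts"))
  if (any(!is.finite(matrix$counts@x))) stop("non-finite values")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(outdir, paste0(prefix, ".mtx"))
  bed <- file.path(outdir, paste0(prefix, ".bed"))
  bc <- file.path(outdir, paste0(prefix, "_barcodes.tsv"))
  tm <- methods::as(methods::as(matrix$counts, "generalMatrix"),
                    "TsparseMatrix")
  ord <- order(tm@j, tm@i)
  i <- tm@i[ord] + 1L; j <- tm@j[ord] + 1L; x <- tm@x[ord]
  field <- if (matrix$real_valued) "real" else "integer"
  vals <- if (field == "integer") format(as.integer(round(x)),
                                         scientific = FALSE, trim = TRUE)
          else format(x, digits = 10, scientific = FALSE, trim = TRUE)
  header <- c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                      field),
              sprintf("%d %d %d", nrow(tm), ncol(tm), length(i)))
  writeLines(c(header, paste(i, j, vals)), mtx)
  utils::write.table(matrix$regions[, c("chrom", "start", "end")], bed,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(matrix$cells, bc, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(mtx = mtx, bed = bed, barcodes = bc))
}

#' Serialize a topic model to TSV matrices plus a JSON sidecar
#'
#' @param model a `topic_model`.
#' @param outdir output directory.
#' @param prefix file name prefix (default `"model"`).
#' @return Named vector of paths, invisibly.
#' @export
write_topic_model <- function(model, outdir, prefix = "model") {
  stopifnot(inherits(model, "topic_model"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vf <- file.path(outdir, paste0(prefix, "_V.tsv"))
  uf <- file.path(outdir, paste0(prefix, "_U.tsv"))
  jf <- file.path(outdir, paste0(prefix, "_meta.json"))
  bf <- file.path(outdir, paste0(prefix, "_regions.bed"))
  utils::write.table(format(model$V, digits = 15), vf, sep = "\t",
                     quote = FALSE)
  utils::write.table(format(model$U, digits = 15), uf, sep = "\t",
                     quote = FALSE)
  utils::write.table(model$regions[, c("chrom", "start", "end")], bf,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meta <- model[c("K", "alpha", "delta", "n_iter", "burn_in", "seed",
                  "estimate")]
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(V = vf, U = uf, meta = jf, regions = bf))
}

#' Read a topic model written by [write_topic_model()]
#' @param outdir directory containing the files.
#' @param prefix file name prefix.
#' @return A `topic_model`.
#' @export
read_topic_model <- function(outdir, prefix = "model") {
  vf <- file.path(outdir, paste0(prefix, "_V.tsv"))
  uf <- file.path(outdir, paste0(prefix, "_U.tsv"))
  jf <- file.path(outdir, paste0(prefix, "_meta.json"))
  bf <- file.path(outdir, paste0(prefix, "_regions.bed"))
  V <- as.matrix(utils::read.table(vf, sep = "\t", check.names = FALSE))
  U <- as.matrix(utils::read.table(uf, sep = "\t", check.names = FALSE))
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  bed <- utils::read.table(bf, sep = "\t", stringsAsFactors = FALSE)
  regions <- data.frame(chrom = as.character(bed[[1]]),
                        start = as.integer(bed[[2]]),
                        end = as.integer(bed[[3]]),
                        stringsAsFactors = FALSE)
  structure(c(list(V = V, U = U), meta,
              list(regions = regions, barcodes = colnames(U))),
            class = "topic_model")
}

#' Serialize smooth pseudotime profiles as TSV plus JSON metadata
#' @param profiles a `smooth_profiles`.
#' @param path output TSV path (a `.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
write_smooth_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "smooth_profiles"))
  m <- profiles$P
  colnames(m) <- format(profiles$grid, digits = 10, trim = TRUE)
  utils::write.table(format(m, digits = 15), path, sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(list(span = profiles$span,
                            grid = profiles$grid),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read smooth profiles written by [write_smooth_profiles()]
#' @param path TSV path.
#' @return A `smooth_profiles`.
#' @export
read_smooth_profiles <- function(path) {
  P <- as.matrix(utils::read.table(path, sep = "\t", check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  structure(list(grid = as.numeric(meta$grid), P = P,
                 span = meta$span, regions = NULL),
            class = "smooth_profiles")
}

#' Export a per-region probability track as bedGraph
#'
#' Fixed-point values with 4 decimals; `NA` (masked) regions are skipped.
#'
#' @param regions BED-style region table.
#' @param values per-region values.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(regions, values, path) {
  validate_regions(regions)
  stopifnot(nrow(regions) == length(values))
  keep <- !is.na(values)
  lines <- sprintf("%s\t%d\t%d\t%.4f", regions$chrom[keep],
                   regions$start[keep], regions$end[keep], values[keep])
  writeLines(lines, path)
  invisible(path)
}
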