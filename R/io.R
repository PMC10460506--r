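#' Write a count matrix directory (Matrix Market + TSVs)
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv` (one
#' gene id per line, plus any rowData columns) and `cells.tsv` (cell id
#' plus any colData columns such as sample, treatment, timepoint_h,
#' sort_gate, cluster, type).
#'
#' @param x SummarizedExperiment/SingleCellExperiment with a `counts`
#'   assay, or a plain matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .countsOf(x)
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  genes <- data.frame(gene = rownames(counts), stringsAsFactors = FALSE)
  cells <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  if (methods::is(x, "SummarizedExperiment")) {
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    if (ncol(rd)) genes <- cbind(genes, rd)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cd[, setdiff(names(cd), "cell"), drop = FALSE]
    if (ncol(cd)) cells <- cbind(cells, cd)
  }
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix directory
#'
#' Counterpart of [writeCountMatrix()].
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
readCountMatrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts))
    stop("annotation row counts do not match matrix dimensions")
  dimnames(counts) <- list(genes$gene, cells$cell)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes[, -1, drop = FALSE],
                                   row.names = genes$gene),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell))
}

#' Read / write tagged-read tables
#'
#' TSV with columns `read_id`, `barcode`, `umi`, `gene_id` (extra
#' columns preserved).
#'
#' @param path file path.
#' @return `readTaggedReads`: the data.frame.
#' @export
readTaggedReads <- function(path) {
  reads <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "barcode", "umi", "gene_id")
  if (!all(need %in% names(reads)))
    stop("tagged-read table must have columns ",
         paste(need, collapse = ", "))
  reads
}

#' @rdname readTaggedReads
#' @param reads data.frame of tagged reads.
#' @export
writeTaggedReads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Intensity scale used when packing arbitrary-unit images into 16-bit
## TIFF samples.
.TIFF_SCALE <- 65535

#' Write / read a multi-channel image stack as multi-page TIFF
#'
#' Each channel (third array dimension) becomes one 16-bit page;
#' intensities are stored as `round(value) / 65535` and restored on
#' read, so arbitrary-unit images up to 65535 survive a round trip to
#' integer precision. Channel names are not stored in the file; supply
#' them on read.
#'
#' @param stack rows x cols x channels numeric array (values in
#'   [0, 65535]).
#' @param path output path.
#' @return `path` invisibly (write); the array (read).
#' @export
writeImageStack <- function(stack, path) {
  if (length(dim(stack)) != 3L) stop("expected rows x cols x channels")
  if (min(stack) < 0 || max(stack) > .TIFF_SCALE)
    stop("intensities must lie in [0, 65535] for 16-bit storage")
  pages <- lapply(seq_len(dim(stack)[3]), function(ch)
    round(stack[, , ch]) / .TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageStack
#' @param channels optional channel names for the third dimension.
#' @export
readImageStack <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)),
                 dimnames = list(NULL, NULL, channels))
  for (ch in seq_along(pages))
    stack[, , ch] <- round(pages[[ch]] * .TIFF_SCALE)
  stack
}

#' Write / read an ROI label mask as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background, ids < 65536).
#' @param path file path.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
writeLabelMask <- function(labels, path) {
  if (max(labels) >= .TIFF_SCALE) stop("too many ROI labels for 16-bit")
  tiff::writeTIFF(labels / .TIFF_SCALE, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * .TIFF_SCALE)), nrow(m), ncol(m))
}
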