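## Accept a SummarizedExperiment (counts assay) or a bare matrix.
.countsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

#' log2(CPM + 1) normalization
#'
#' Scales each cell's (or replicate's) counts to counts per million and
#' applies `log2(cpm + 1)`.
#'
#' @param x a count matrix (genes x cells) or a SummarizedExperiment
#'   with a `counts` assay.
#' @return a dense numeric matrix of log2(CPM + 1) values with the
#'   dimnames of the input.
#' @examples
#' m <- matrix(c(100, 0, 999900, 0), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' # c2 has zero total and would error; use c1 only
#' cpmLog2(m[, 1, drop = FALSE])
#' @export
cpmLog2 <- function(x) {
  counts <- .countsOf(x)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("zero total count in cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  cpm <- sweep(as.matrix(counts), 2, totals, "/") * 1e6
  log2(cpm + 1)
}

#' Per-gene z-scoring
#'
#' Centres and scales each gene (row) to mean 0 and population standard
#' deviation 1 (divisor `n`, not `n - 1`). Constant genes become
#' all-zero rows with a warning.
#'
#' @param mat numeric matrix (genes x cells), typically log2(CPM + 1).
#' @return z-scored matrix of the same shape.
#' @export
zscoreGenes <- function(mat) {
  if (ncol(mat) < 2L) stop("z-scoring needs at least two columns")
  mu <- rowMeans(mat)
  centred <- mat - mu
  popSd <- sqrt(rowMeans(centred^2))
  flat <- popSd == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) set to zero")
    popSd[flat] <- 1
  }
  centred / popSd
}

#' Score a gene signature per cell
#'
#' Sums normalized expression over the signature genes in each cell.
#' Signature genes missing from the matrix are skipped with a warning;
#' if none are present the call errors.
#'
#' @param mat normalized matrix (genes x cells), e.g. from [cpmLog2()].
#' @param signature a [GeneSignature-class] (or character vector of
#'   gene ids, coerced to one).
#' @param average if `TRUE`, return the mean over present signature
#'   genes instead of the sum (useful when comparing signatures of
#'   unequal size).
#' @return named numeric vector of per-cell scores.
#' @export
signatureScore <- function(mat, signature, average = FALSE) {
  if (is.character(signature))
    signature <- GeneSignature("signature", signature)
  genes <- signatureGenes(signature)
  present <- intersect(genes, rownames(mat))
  if (!length(present))
    stop("no signature gene present in the matrix for '",
         signatureName(signature), "'")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " signature gene(s) absent; ",
            "scoring on ", length(present), " gene(s)")
  sub <- mat[present, , drop = FALSE]
  if (average) colMeans(sub) else colSums(sub)
}

#' Bundled MHC class I / class II gene signatures
#'
#' The MHC-I signature holds the classical class Ia heavy/light chain
#' and peptide-loading genes; the MHC-II signature holds the class II
#' alpha/beta chains plus the invariant chain.
#'
#' @return named list of two [GeneSignature-class] objects, `MHC-I` and
#'   `MHC-II`.
#' @export
mhcSignatures <- function() {
  list(
    `MHC-I` = GeneSignature("MHC-I", c("H2-K1", "H2-D1", "B2m", "Tap1")),
    `MHC-II` = GeneSignature("MHC-II", c("H2-Ab1", "H2-Eb1", "H2-Aa",
                                         "Cd74"))
  )
}

#' Read a gene-set file
#'
#' Plain-text format: one gene per line, `#` starts a comment, blank
#' lines ignored.
#'
#' @param path file path.
#' @param name signature name; defaults to the file name.
#' @return a [GeneSignature-class].
#' @export
readGeneSet <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  GeneSignature(name, lines[nzchar(lines)])
}

#' Write a gene-set file
#'
#' @param signature a [GeneSignature-class] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSet <- function(signature, path) {
  genes <- if (is.character(signature)) signature
           else signatureGenes(signature)
  writeLines(genes, path)
  invisible(path)
}
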