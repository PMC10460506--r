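## Hamming distance between two equal-length strings.
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## Build a correction index: `exact` holds the whitelist itself;
## `near` maps each string at Hamming distance 1 from the whitelist to
## its unique source barcode, or to NA when two or more whitelist
## members lie at distance 1 (ambiguous). Exact membership takes
## priority over neighbourhood at lookup time.
.barcodeIndex <- function(whitelist) {
  exact <- new.env(hash = TRUE, parent = emptyenv())
  for (bc in whitelist) assign(bc, bc, envir = exact)
  near <- new.env(hash = TRUE, parent = emptyenv())
  for (bc in whitelist) {
    for (nb in hammingBall1(bc)) {
      if (exists(nb, envir = near, inherits = FALSE)) {
        if (!identical(get(nb, envir = near), bc))
          assign(nb, NA_character_, envir = near)
      } else {
        assign(nb, bc, envir = near)
      }
    }
  }
  list(exact = exact, near = near)
}

#' Correct barcodes against a whitelist
#'
#' Exact whitelist matches are returned as-is. An observed barcode at
#' Hamming distance 1 from exactly one whitelist member is corrected to
#' it; if two or more whitelist members lie at distance 1 the barcode is
#' rejected (`NA`) rather than guessed. All other barcodes are rejected.
#'
#' @param observed character vector of observed barcodes.
#' @param whitelist nonempty character vector of true barcodes, all the
#'   same length as the observed barcodes.
#' @return character vector the length of `observed`; `NA` marks
#'   rejected barcodes.
#' @examples
#' correctBarcode(c("ACGT", "ACGA", "GGGG"), c("ACGT", "TTTT"))
#' @export
correctBarcode <- function(observed, whitelist) {
  if (!length(whitelist)) stop("empty whitelist")
  lens <- unique(nchar(whitelist))
  if (length(lens) != 1L) stop("whitelist barcode lengths differ")
  if (length(observed) && any(nchar(observed) != lens))
    stop("observed barcode length differs from whitelist length")
  idx <- .barcodeIndex(whitelist)
  vapply(observed, function(bc) {
    if (exists(bc, envir = idx$exact, inherits = FALSE))
      bc
    else if (exists(bc, envir = idx$near, inherits = FALSE))
      get(bc, envir = idx$near)
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

## Connected components of UMIs under Hamming distance <= 1, computed by
## hashing each UMI's distance-1 neighbourhood. Returns a component id
## per input UMI.
.umiComponents <- function(umis) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(umis[i], i, envir = pos)
  for (i in seq_len(n)) {
    for (nb in hammingBall1(umis[i])) {
      if (exists(nb, envir = pos, inherits = FALSE)) {
        j <- get(nb, envir = pos)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse tagged reads into molecules
#'
#' Corrects barcodes against the whitelist (rejecting ambiguous or
#' uncorrectable ones), then collapses reads within each (corrected
#' barcode, gene) bucket: distinct UMIs are nodes of a graph with edges
#' between UMIs at Hamming distance <= 1, and each connected component
#' becomes one molecule. The representative UMI of a component is its
#' highest-read-support UMI (ties broken lexicographically); the
#' molecule's `read_support` is the total reads in the component.
#'
#' @param reads data.frame with columns `barcode`, `umi`, `gene_id`
#'   (and optionally `read_id`); tags must be uppercase ACGT strings of
#'   uniform length.
#' @param whitelist character vector of true barcodes.
#' @return list with `molecules` (data.frame `barcode`, `umi`,
#'   `gene_id`, `read_support`), `n_reads`, `n_assigned`, `n_rejected`.
#' @export
collapseMolecules <- function(reads, whitelist) {
  need <- c("barcode", "umi", "gene_id")
  if (!all(need %in% names(reads)))
    stop("reads must have columns ", paste(need, collapse = ", "))
  if (nrow(reads)) {
    if (length(unique(nchar(reads$umi))) > 1L)
      stop("UMI lengths are not uniform")
    if (any(grepl("[^ACGT]", c(reads$barcode, reads$umi))))
      stop("tags contain characters outside A/C/G/T")
  }
  corrected <- correctBarcode(reads$barcode, whitelist)
  keep <- !is.na(corrected)
  nRejected <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  corrected <- corrected[keep]

  if (!nrow(reads)) {
    return(list(
      molecules = data.frame(barcode = character(), umi = character(),
                             gene_id = character(),
                             read_support = integer(),
                             stringsAsFactors = FALSE),
      n_reads = nRejected, n_assigned = 0L, n_rejected = nRejected))
  }

  ## read support per distinct (barcode, gene, umi) triple
  key <- paste(corrected, reads$gene_id, reads$umi, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  triples <- data.frame(
    barcode = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    umi = vapply(parts, `[`, character(1), 3L),
    support = as.integer(tab),
    stringsAsFactors = FALSE
  )

  bucket <- paste(triples$barcode, triples$gene_id, sep = "\r")
  bucketSize <- table(bucket)
  single <- bucket %in% names(bucketSize)[bucketSize == 1L]

  ## fast path: buckets with one distinct UMI are already one molecule
  molecules <- data.frame(
    barcode = triples$barcode[single],
    umi = triples$umi[single],
    gene_id = triples$gene_id[single],
    read_support = triples$support[single],
    stringsAsFactors = FALSE
  )
  multi <- which(!single)
  if (length(multi)) {
    res <- lapply(split(multi, bucket[multi]), function(ix) {
      sub <- triples[ix, , drop = FALSE]
      comp <- .umiComponents(sub$umi)
      reps <- vapply(split(seq_len(nrow(sub)), comp), function(ci) {
        ci[order(-sub$support[ci], sub$umi[ci])][1]
      }, integer(1))
      data.frame(
        barcode = sub$barcode[reps],
        umi = sub$umi[reps],
        gene_id = sub$gene_id[reps],
        read_support = vapply(split(sub$support, comp), sum, numeric(1)),
        stringsAsFactors = FALSE
      )
    })
    molecules <- rbind(molecules, do.call(rbind, res))
  }
  rownames(molecules) <- NULL
  molecules$read_support <- as.integer(molecules$read_support)
  o <- order(molecules$barcode, molecules$gene_id, molecules$umi)
  molecules <- molecules[o, , drop = FALSE]
  rownames(molecules) <- NULL
  list(molecules = molecules,
       n_reads = nrow(reads) + nRejected,
       n_assigned = nrow(reads),
       n_rejected = nRejected)
}

#' Build a molecular count matrix from collapsed molecules
#'
#' Each matrix entry is the number of distinct molecules observed for a
#' (cell barcode, gene) pair; the total matrix sum equals the number of
#' molecules.
#'
#' @param molecules data.frame as returned by [collapseMolecules()];
#'   (barcode, umi, gene_id) triples must be unique.
#' @param genes optional character vector fixing the gene universe and
#'   row order; defaults to the genes observed.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay (genes x cells).
#' @export
countMatrixFromMolecules <- function(molecules, genes = NULL) {
  if (anyDuplicated(molecules[, c("barcode", "umi", "gene_id")]))
    stop("duplicate (barcode, umi, gene) triples: molecules are not collapsed")
  if (is.null(genes)) genes <- sort(unique(molecules$gene_id))
  cells <- sort(unique(molecules$barcode))
  i <- match(molecules$gene_id, genes)
  if (anyNA(i)) stop("molecules contain genes outside the gene universe")
  j <- match(molecules$barcode, cells)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(1L, nrow(molecules)),
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell = cells, row.names = cells))
}

#' Demultiplex tagged reads end-to-end
#'
#' Convenience wrapper: [collapseMolecules()] followed by
#' [countMatrixFromMolecules()].
#'
#' @inheritParams collapseMolecules
#' @inheritParams countMatrixFromMolecules
#' @return list with `sce` (the molecular count matrix), `molecules`,
#'   and the read-accounting counters of [collapseMolecules()].
#' @export
demuxReads <- function(reads, whitelist, genes = NULL) {
  col <- collapseMolecules(reads, whitelist)
  sce <- countMatrixFromMolecules(col$molecules, genes = genes)
  c(list(sce = sce), col)
}
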