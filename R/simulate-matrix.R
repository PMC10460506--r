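#' Simulate a single-nucleus UMI count matrix with ground truth
#'
#' Draws per-cell gene counts from a per-type negative-binomial
#' (gamma-Poisson) expression program. Marker genes are elevated only in
#' their own type; under IFN-gamma treatment, interferon-stimulated
#' genes are multiplied by type-specific amplitudes (glial amplitudes
#' exceed neuronal by the configured 2--8-fold factor) and MHC-II genes
#' are induced only in microglia. A `doubletFraction` of cells are
#' replaced by unscaled sums of two independently drawn parent cells of
#' different types, flagged in the ground truth.
#'
#' @param config a [SimConfig-class].
#' @param treatment `"saline"` or `"IFN"`.
#' @param sample sample label stored in the cell metadata.
#' @param doubletHosts optional character vector restricting which cell
#'   types may host a doublet (the host contributes the cell's label);
#'   default: any type.
#' @param doubletPartners optional character vector restricting the
#'   second parent's type; default: any type different from the host.
#' @param seed optional integer overriding `config@seed`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with sparse
#'   integer `counts`; `colData` columns `cell`, `type` (first parent's
#'   type), `doublet`, `doublet_partner`, `sample`, `treatment`,
#'   `cluster` (equal to `type`; stands in for upstream unsupervised
#'   cluster labels); `rowData` columns `class`, `marker_type`; and
#'   `metadata(x)$inductionFolds`, the genes-by-types fold matrix that
#'   generated the data.
#' @export
genNucleusMatrix <- function(config, treatment = c("saline", "IFN"),
                             sample = "S1", doubletHosts = NULL,
                             doubletPartners = NULL,
                             seed = config@seed) {
  validObject(config)
  treatment <- match.arg(treatment)
  program <- geneProgram(config)
  mu0 <- baselineMeans(config, program)
  fold <- inductionFolds(config, program)
  mu <- if (treatment == "IFN") mu0 * fold else mu0

  types <- names(config@nCellsByType)
  unknown <- setdiff(types, .ALL_TYPES)
  if (length(unknown))
    stop("unknown cell types in config: ", paste(unknown, collapse = ", "))
  cellType <- rep(types, config@nCellsByType)
  n <- length(cellType)
  if (n < 1L) stop("config requests zero cells")
  if (config@doubletFraction > 0 && length(types[config@nCellsByType > 0]) < 2L)
    stop("doublets require at least two cell types with cells")

  nGenes <- nrow(program)
  withr::with_seed(seed, {
    counts <- matrix(0L, nrow = nGenes, ncol = n)
    for (ty in types) {
      cols <- which(cellType == ty)
      if (!length(cols)) next
      counts[, cols] <- rnbinom(nGenes * length(cols),
                                mu = mu[, ty], size = config@dispersion)
    }
    doublet <- rep(FALSE, n)
    partner <- rep(NA_character_, n)
    nDoub <- round(config@doubletFraction * n)
    if (nDoub > 0) {
      present <- types[config@nCellsByType > 0]
      hostPool <- which(cellType %in% (doubletHosts %||% present))
      if (length(hostPool) < nDoub)
        stop("not enough eligible host cells for the requested doublets")
      host <- sample(hostPool, nDoub)
      doublet[host] <- TRUE
      for (i in host) {
        pool <- setdiff(doubletPartners %||% present, cellType[i])
        if (!length(pool))
          stop("no eligible partner type for host type ", cellType[i])
        other <- if (length(pool) == 1L) pool else sample(pool, 1L)
        partner[i] <- other
        counts[, i] <- counts[, i] +
          rnbinom(nGenes, mu = mu[, other], size = config@dispersion)
      }
    }
  })

  dimnames(counts) <- list(program$gene,
                           sprintf("%s_cell%05d", sample, seq_len(n)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      cell = colnames(counts),
      type = cellType,
      doublet = doublet,
      doublet_partner = partner,
      sample = sample,
      treatment = treatment,
      cluster = cellType,
      row.names = colnames(counts)
    ),
    rowData = S4Vectors::DataFrame(
      class = program$class,
      marker_type = program$marker_type,
      row.names = program$gene
    )
  )
  S4Vectors::metadata(sce)$inductionFolds <- fold
  S4Vectors::metadata(sce)$treatment <- treatment
  sce
}

#' Planted marker genes of one cell type
#'
#' Convenience accessor for the simulator's ground-truth marker list.
#'
#' @param config a [SimConfig-class].
#' @param type one of the simulated major cell types.
#' @return character vector of marker gene ids.
#' @export
plantedMarkers <- function(config, type) {
  program <- geneProgram(config)
  if (!type %in% .ALL_TYPES) stop("unknown type: ", type)
  program$gene[program$class == "marker" &
                 !is.na(program$marker_type) &
                 program$marker_type == type]
}
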