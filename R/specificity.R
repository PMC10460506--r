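#' Binomial marker-gene specificity per cluster
#'
#' For each (gene, cluster) pair, tests whether the fraction of
#' in-cluster cells expressing the gene (count > 0) exceeds what is
#' expected from the out-of-cluster expressing fraction. The p-value is
#' the one-sided binomial tail probability of observing at least the
#' in-cluster number of expressing cells among the in-cluster cells
#' when the success probability is the out-of-cluster expressing
#' fraction, floored at 1 / (total cells) to avoid a zero null.
#' Benjamini-Hochberg correction is applied within each cluster.
#' Genes with zero counts in all cells are omitted.
#'
#' @param x count matrix (genes x cells) or SummarizedExperiment with a
#'   `counts` assay.
#' @param clusters vector of cluster labels, one per cell (>= 2
#'   clusters, no empty cluster).
#' @return data.frame with columns `gene`, `cluster`, `n_in`, `k_in`,
#'   `frac_in`, `frac_out`, `log2_specificity` (log2 of the ratio of
#'   floored expressing fractions), `p`, `fdr`.
#' @export
binomialSpecificity <- function(x, clusters) {
  counts <- .countsOf(x)
  n <- ncol(counts)
  if (length(clusters) != n)
    stop("clusters must label every cell")
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  if (length(sizes) < 2L) stop("need at least two clusters")
  if (any(sizes == 0L)) stop("empty cluster")

  expressed <- counts > 0
  keep <- Matrix::rowSums(expressed) > 0
  expressed <- expressed[keep, , drop = FALSE]
  genes <- rownames(counts)[keep]
  floorP <- 1 / n

  res <- lapply(names(sizes), function(cl) {
    inC <- clusters == cl
    nIn <- sum(inC)
    nOut <- n - nIn
    kIn <- Matrix::rowSums(expressed[, inC, drop = FALSE])
    kOut <- Matrix::rowSums(expressed[, !inC, drop = FALSE])
    fracIn <- kIn / nIn
    fracOut <- kOut / nOut
    p0 <- pmax(fracOut, floorP)
    p <- pbinom(kIn - 1, nIn, p0, lower.tail = FALSE)
    data.frame(
      gene = genes,
      cluster = cl,
      n_in = nIn,
      k_in = as.integer(kIn),
      frac_in = fracIn,
      frac_out = fracOut,
      log2_specificity = log2(pmax(fracIn, floorP) / p0),
      p = p,
      fdr = p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select top marker genes for a cluster or cell type
#'
#' Genes passing both the specificity and FDR thresholds, ranked by
#' ascending FDR then descending specificity, truncated to `k`. The
#' defaults reproduce a top-99 marker list at log2 specificity > 3 and
#' FDR below 1e-49.
#'
#' @param table output of [binomialSpecificity()].
#' @param cluster cluster (or collapsed type) label to select markers
#'   for.
#' @param k maximum number of markers returned.
#' @param minSpec minimum log2 specificity (exclusive).
#' @param maxFdr maximum FDR (exclusive).
#' @return character vector of at most `k` gene ids (possibly fewer or
#'   empty).
#' @export
selectMarkers <- function(table, cluster, k = 99L, minSpec = 3,
                          maxFdr = 1e-49) {
  sub <- table[table$cluster == cluster &
                 table$log2_specificity > minSpec &
                 table$fdr < maxFdr, , drop = FALSE]
  sub <- sub[order(sub$fdr, -sub$log2_specificity, sub$gene), ,
             drop = FALSE]
  utils::head(sub$gene, k)
}

#' Assign clusters to major cell types from marker enrichment
#'
#' Each cluster is assigned the type whose marker set has the greatest
#' mean log2 specificity in that cluster, provided that mean is positive
#' and exceeds the runner-up by `margin`; otherwise the cluster is
#' `"UNASSIGNED"` (mirroring the exclusion of ambiguous clusters that
#' co-enrich several types' markers).
#'
#' @param table output of [binomialSpecificity()] computed on the
#'   cluster labels.
#' @param typeMarkerSets named list: type -> character vector of marker
#'   genes. Overlapping sets trigger a warning; empty sets error.
#' @param margin required lead (log2 units) of the best type's mean
#'   specificity over the runner-up.
#' @return named character vector: cluster -> type or `"UNASSIGNED"`.
#' @export
assignMajorTypes <- function(table, typeMarkerSets, margin = 1) {
  if (!length(typeMarkerSets)) stop("no marker sets supplied")
  if (any(!vapply(typeMarkerSets, length, integer(1))))
    stop("empty marker set")
  allMarkers <- unlist(typeMarkerSets, use.names = FALSE)
  if (anyDuplicated(allMarkers))
    warning("marker sets overlap; assignment may be unstable")

  clusters <- unique(table$cluster)
  out <- vapply(clusters, function(cl) {
    sub <- table[table$cluster == cl, , drop = FALSE]
    spec <- stats::setNames(sub$log2_specificity, sub$gene)
    means <- vapply(typeMarkerSets, function(gs) {
      present <- intersect(gs, names(spec))
      if (!length(present)) return(-Inf)
      mean(spec[present])
    }, numeric(1))
    o <- order(means, decreasing = TRUE)
    best <- means[o[1]]
    second <- if (length(means) > 1L) means[o[2]] else -Inf
    if (is.finite(best) && best > 0 && best - second > margin)
      names(means)[o[1]]
    else "UNASSIGNED"
  }, character(1))
  stats::setNames(out, clusters)
}

#' Collapse cluster labels to major types
#'
#' Applies a cluster-to-type map to per-cell cluster labels; cells in
#' unassigned clusters get `"UNASSIGNED"`.
#'
#' @param clusters per-cell cluster labels.
#' @param typeMap named vector from [assignMajorTypes()].
#' @return character vector of per-cell major types.
#' @export
collapseToMajorTypes <- function(clusters, typeMap) {
  out <- unname(typeMap[as.character(clusters)])
  out[is.na(out)] <- "UNASSIGNED"
  out
}
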