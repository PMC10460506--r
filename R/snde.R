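## Cross-cell scaling factors for the rank-sum test. Median-of-ratios
## size factors where estimable; with sparse single-cell counts the
## geometric-mean reference often vanishes, in which case library-size
## factors (totals scaled to mean 1) are used.
.sizeFactorsFor <- function(counts) {
  m <- as.matrix(counts)
  sf <- tryCatch(
    suppressWarnings(DESeq2::estimateSizeFactorsForMatrix(m)),
    error = function(e) NULL)
  if (is.null(sf) || any(!is.finite(sf)) || any(sf <= 0)) {
    totals <- colSums(m)
    if (any(totals == 0)) stop("cell with zero total count")
    sf <- totals / mean(totals)
  }
  sf
}

#' Equalize cell numbers between two groups
#'
#' Randomly subsamples the larger group, without replacement, to the
#' size of the smaller; the smaller group is returned unchanged.
#'
#' @param a,b count matrices (genes x cells) or SummarizedExperiments
#'   with a `counts` assay.
#' @param seed integer seed for the subsample draw.
#' @return list with matrices `a` and `b` (both with
#'   `min(ncol(a), ncol(b))` cells) and the retained column indices
#'   `idx_a`, `idx_b`.
#' @export
equalizeCellNumbers <- function(a, b, seed = 1L) {
  a <- .countsOf(a); b <- .countsOf(b)
  if (ncol(a) == 0L || ncol(b) == 0L) stop("empty group")
  n <- min(ncol(a), ncol(b))
  withr::with_seed(seed, {
    ia <- if (ncol(a) > n) sort(sample.int(ncol(a), n)) else seq_len(ncol(a))
    ib <- if (ncol(b) > n) sort(sample.int(ncol(b), n)) else seq_len(ncol(b))
  })
  list(a = a[, ia, drop = FALSE], b = b[, ib, drop = FALSE],
       idx_a = ia, idx_b = ib)
}

## Binomial thinning of a count matrix: each entry c becomes
## Binomial(c, p). Sparse-aware.
.thinCounts <- function(counts, p) {
  if (methods::is(counts, "sparseMatrix")) {
    counts <- methods::as(counts, "CsparseMatrix")
    counts@x <- as.numeric(rbinom(length(counts@x), counts@x, p))
    Matrix::drop0(counts)
  } else {
    out <- counts
    out[] <- rbinom(length(counts), as.integer(counts), p)
    out
  }
}

#' Equalize mean transcript depth between two groups
#'
#' The group with the higher mean total count per cell is binomially
#' thinned entrywise with probability p = (shallower mean) / (deeper
#' mean), so both groups end with the same average number of transcripts
#' per cell up to binomial sampling error. Postconditions (thinned
#' counts never exceed the originals; realized mean within sampling
#' error of the target) are asserted on every run.
#'
#' @param a,b cell-number-equalized count matrices (or
#'   SummarizedExperiments).
#' @param seed integer seed for the thinning draws.
#' @return list with matrices `a`, `b`, the thinning probability `p`,
#'   and which group was thinned (`"a"`, `"b"` or `"none"`).
#' @export
equalizeTranscriptDepth <- function(a, b, seed = 1L) {
  a <- .countsOf(a); b <- .countsOf(b)
  meanA <- mean(Matrix::colSums(a))
  meanB <- mean(Matrix::colSums(b))
  if (meanA == 0 || meanB == 0) stop("zero-mean group")
  if (meanA == meanB)
    return(list(a = a, b = b, p = 1, thinned = "none"))
  deeper <- if (meanA > meanB) "a" else "b"
  deepMat <- if (deeper == "a") a else b
  target <- min(meanA, meanB)
  p <- target / max(meanA, meanB)
  withr::with_seed(seed, thinned <- .thinCounts(deepMat, p))

  ## built-in postcondition checks
  if (any(thinned > deepMat)) stop("thinning exceeded original counts")
  realized <- mean(Matrix::colSums(thinned))
  se <- sqrt(p * (1 - p) * sum(deepMat)) / ncol(deepMat)
  if (abs(realized - target) > max(6 * se, 1e-8))
    stop(sprintf(
      "depth equalization failed: realized mean %.2f vs target %.2f (SE %.3f)",
      realized, target, se))

  if (deeper == "a") list(a = thinned, b = b, p = p, thinned = "a")
  else list(a = a, b = thinned, p = p, thinned = "b")
}

## Vectorized two-sided Mann-Whitney U with tie correction and normal
## approximation (continuity-corrected), matching wilcox.test's
## large-sample path; rows with an exact request (both n <= 8) are
## delegated to wilcox.test's exact enumeration when tie-free.
.rankSumMatrix <- function(matA, matB) {
  nA <- ncol(matA); nB <- ncol(matB)
  N <- nA + nB
  X <- cbind(matB, matA)  # statistic reported for group b (treated)
  stats <- t(apply(X, 1, function(v) {
    r <- rank(v)
    Rb <- sum(r[seq_len(nB)])
    tt <- table(v)
    c(Rb, sum(tt^3 - tt))
  }))
  U <- stats[, 1] - nB * (nB + 1) / 2
  tieSum <- stats[, 2]
  mu <- nA * nB / 2
  sigma2 <- (nA * nB / 12) * ((N + 1) - tieSum / (N * (N - 1)))
  z <- U - mu
  correction <- sign(z) * 0.5
  sigma <- sqrt(sigma2)
  z <- ifelse(sigma > 0, (z - correction) / sigma, 0)
  p <- pmin(2 * pnorm(-abs(z)), 1)
  p[sigma == 0] <- 1
  list(statistic = U, p = p)
}

#' Depth-equalized rank-sum differential expression
#'
#' Per-gene two-sided Mann-Whitney U test between two groups of cells
#' on size-factor-normalized counts, with Benjamini-Hochberg correction
#' across all tested genes. Genes with zero counts in both groups are
#' excluded. Log2 fold changes are computed on group means of
#' normalized counts with a pseudocount (default: the CPM-equivalent of
#' one count per million of the mean library size). Groups are expected
#' to be cell-number- and depth-equalized upstream (see
#' [equalizeCellNumbers()], [equalizeTranscriptDepth()]).
#'
#' @param a,b count matrices (genes x cells): control and treated.
#' @param pseudocount pseudocount on the normalized-count scale; `NULL`
#'   uses 1e-6 times the mean library size (1 CPM-equivalent).
#' @param exactMaxN use wilcox.test's exact enumeration when both
#'   groups have at most this many cells (default 8).
#' @return data.frame (`gene`, `log2fc` treated/control, `statistic`
#'   = U for the treated group, `p`, `fdr`, `mean_a`, `mean_b`).
#' @export
rankSumDE <- function(a, b, pseudocount = NULL, exactMaxN = 8L) {
  a <- .countsOf(a); b <- .countsOf(b)
  if (ncol(a) < 3L || ncol(b) < 3L) stop("each group needs >= 3 cells")
  if (!identical(rownames(a), rownames(b)))
    stop("gene universes differ between groups")
  sf <- .sizeFactorsFor(cbind(as.matrix(a), as.matrix(b)))
  normAll <- sweep(cbind(as.matrix(a), as.matrix(b)), 2, sf, "/")
  normA <- normAll[, seq_len(ncol(a)), drop = FALSE]
  normB <- normAll[, ncol(a) + seq_len(ncol(b)), drop = FALSE]

  keep <- rowSums(normAll) > 0
  normA <- normA[keep, , drop = FALSE]
  normB <- normB[keep, , drop = FALSE]
  genes <- rownames(a)[keep]

  if (is.null(pseudocount))
    pseudocount <- 1e-6 * mean(colSums(cbind(as.matrix(a), as.matrix(b))))

  meanA <- rowMeans(normA)
  meanB <- rowMeans(normB)
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))

  if (ncol(a) <= exactMaxN && ncol(b) <= exactMaxN) {
    res <- lapply(seq_along(genes), function(i) {
      wt <- suppressWarnings(
        wilcox.test(normB[i, ], normA[i, ], exact = TRUE))
      c(unname(wt$statistic), wt$p.value)
    })
    statistic <- vapply(res, `[`, numeric(1), 1L)
    p <- vapply(res, `[`, numeric(1), 2L)
  } else {
    rs <- .rankSumMatrix(normA, normB)
    statistic <- rs$statistic
    p <- rs$p
  }

  data.frame(
    gene = genes,
    log2fc = log2fc,
    statistic = statistic,
    p = p,
    fdr = p.adjust(p, method = "BH"),
    mean_a = meanA,
    mean_b = meanB,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

## One complete equalize-cells -> equalize-depth -> rank-sum run.
.sndeOnce <- function(control, treated, seed, pseudocount) {
  eq <- equalizeCellNumbers(control, treated, seed = seed)
  dq <- equalizeTranscriptDepth(eq$a, eq$b, seed = seed + 1L)
  rankSumDE(dq$a, dq$b, pseudocount = pseudocount)
}

#' Replicated single-nucleus differential expression
#'
#' Runs the full procedure (equalize cell numbers, equalize transcript
#' depth, rank-sum test, BH correction) for each treated sample against
#' the shared control, with a fresh seeded equalization per sample. A
#' gene is called up (down) only if it passes `|log2fc| > lfc` with a
#' consistent sign and `fdr < fdrThreshold` in every treated-vs-control
#' comparison.
#'
#' @param control count matrix (genes x cells) of the control sample's
#'   cells (one cell type).
#' @param treated named list of count matrices, one per treated sample.
#' @param lfc absolute log2-fold-change call threshold (default 3,
#'   i.e. > 8-fold).
#' @param fdrThreshold FDR call threshold (default 0.01).
#' @param pseudocount see [rankSumDE()].
#' @param seed base seed; comparison `i` uses `seed + 100 * i`.
#' @param nDraws subsample draws per comparison; with more than one
#'   draw, per-gene p-values, fold changes and means are averaged over
#'   draws and the FDR recomputed (default 1, a single draw).
#' @return list with `tables` (per-sample DE data.frames), `up` and
#'   `down` (intersected gene calls).
#' @export
replicatedDE <- function(control, treated, lfc = 3, fdrThreshold = 0.01,
                         pseudocount = NULL, seed = 1L, nDraws = 1L) {
  if (!is.list(treated)) treated <- list(sample1 = treated)
  if (!length(treated)) stop("need at least one treated sample")
  if (is.null(names(treated)))
    names(treated) <- paste0("sample", seq_along(treated))

  universes <- lapply(treated, function(x) rownames(.countsOf(x)))
  shared <- Reduce(intersect, c(list(rownames(.countsOf(control))),
                                universes))
  if (any(vapply(universes, length, integer(1)) != length(shared)) ||
      length(shared) != nrow(.countsOf(control))) {
    warning("gene universes differ; intersecting")
  }
  control <- .countsOf(control)[shared, , drop = FALSE]

  tables <- lapply(seq_along(treated), function(i) {
    tr <- .countsOf(treated[[i]])[shared, , drop = FALSE]
    draws <- lapply(seq_len(nDraws), function(d)
      .sndeOnce(control, tr, seed = seed + 100L * i + 7L * (d - 1L),
                pseudocount = pseudocount))
    if (nDraws == 1L) return(draws[[1]])
    ## average p-values and effect sizes over draws on the union of
    ## tested genes (a gene missing from a draw was all-zero there)
    genes <- sort(unique(unlist(lapply(draws, `[[`, "gene"))))
    acc <- function(col) rowMeans(vapply(draws, function(d)
      d[[col]][match(genes, d$gene)], numeric(length(genes))),
      na.rm = TRUE)
    p <- acc("p")
    data.frame(gene = genes, log2fc = acc("log2fc"),
               statistic = acc("statistic"), p = p,
               fdr = p.adjust(p, method = "BH"),
               mean_a = acc("mean_a"), mean_b = acc("mean_b"),
               stringsAsFactors = FALSE)
  })
  names(tables) <- names(treated)

  callDir <- function(tab, dir) {
    ok <- tab$fdr < fdrThreshold &
      (if (dir > 0) tab$log2fc > lfc else tab$log2fc < -lfc)
    tab$gene[ok]
  }
  up <- Reduce(intersect, lapply(tables, callDir, dir = 1))
  down <- Reduce(intersect, lapply(tables, callDir, dir = -1))
  list(tables = tables, up = up, down = down)
}
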