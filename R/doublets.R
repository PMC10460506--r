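#' Per-cell marker-set expression sum
#'
#' Sums expression of a marker gene set in each cell, on normalized
#' log2(CPM + 1) values by default or on raw counts. Marker genes
#' absent from the matrix are skipped with a warning; if none remain
#' the call errors.
#'
#' @param x count matrix (genes x cells) or SummarizedExperiment with a
#'   `counts` assay.
#' @param geneSet character vector of marker gene ids.
#' @param normalized use log2(CPM + 1) values (default) instead of raw
#'   counts.
#' @return named numeric vector of per-cell scores.
#' @export
markerSumScores <- function(x, geneSet, normalized = TRUE) {
  if (!length(geneSet)) stop("empty gene set")
  mat <- if (normalized) cpmLog2(x) else as.matrix(.countsOf(x))
  signatureScore(mat, GeneSignature("markers", unique(geneSet)))
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Components are initialized at the 25th/75th percentiles of the data
#' with equal weights, iterated to convergence (absolute log-likelihood
#' change below `tol`) or `maxIter` iterations, and reported in
#' ascending order of mean.
#'
#' @param scores numeric vector (>= 20 finite points).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return a [MixtureFit-class].
#' @export
fitTwoComponentGMM <- function(scores, tol = 1e-6, maxIter = 500L) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 20L) stop("need at least 20 points to fit a mixture")
  if (diff(range(scores)) == 0)
    stop("all points are equal; mixture undefined - skip filtering")

  sdFloor <- max(diff(range(scores)) * 1e-6, .Machine$double.eps)
  mu <- unname(quantile(scores, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(scores) / 2
  sg <- rep(max(sd(scores) / 2, sdFloor), 2)
  w <- c(0.5, 0.5)

  logLik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    ## E step in log space for numerical safety
    l1 <- log(w[1]) + dnorm(scores, mu[1], sg[1], log = TRUE)
    l2 <- log(w[2]) + dnorm(scores, mu[2], sg[2], log = TRUE)
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    newLogLik <- sum(den)
    r1 <- exp(l1 - den)
    ## M step
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * scores) / n1, sum((1 - r1) * scores) / n2)
    sg <- c(sqrt(sum(r1 * (scores - mu[1])^2) / n1),
            sqrt(sum((1 - r1) * (scores - mu[2])^2) / n2))
    sg <- pmax(sg, sdFloor)
    if (abs(newLogLik - logLik) < tol) {
      logLik <- newLogLik
      converged <- TRUE
      break
    }
    logLik <- newLogLik
  }

  o <- order(mu)
  new("MixtureFit",
      weights = w[o], means = mu[o], sds = sg[o],
      converged = converged, nPoints = as.integer(n),
      logLik = logLik, iterations = as.integer(iter))
}

#' Iterative Gaussian-mixture doublet filtering
#'
#' For each marker set in order (default interpretation: off-type
#' glial marker programs such as oligodendrocyte, astrocyte and
#' microglial markers), computes per-cell marker-sum scores and fits a
#' two-component Gaussian mixture *within each* major cell class other
#' than the marker set's own type, removing cells whose score exceeds
#' the first (lower) component's mean by more than `kSd` of that
#' component's standard deviations. Fitting per class keeps each
#' singlet score distribution unimodal; pooling classes with different
#' baseline marker leakage would let the first component lock onto the
#' lowest class and flag the others. Removed cells are dropped before
#' the next round; mixtures are re-estimated each round on surviving
#' cells. A class whose mixture fit fails (e.g. too few cells or
#' constant scores) is skipped with a warning and loses no cells.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay.
#' @param markerSets named ordered list: own-type label -> marker gene
#'   vector. Names must match values of the `types` labels.
#' @param kSd removal threshold in first-component standard deviations
#'   (default 8).
#' @param types per-cell major-type labels; defaults to `colData(x)$type`.
#' @param normalized score on log2(CPM + 1) (default) or raw counts.
#' @param minSeparation minimum Ashman's D,
#'   `(m2 - m1) / sqrt((s1^2 + s2^2) / 2)`, for the two fitted
#'   components to count as distinct modes (default 2, the standard
#'   distinguishability cutoff). Below it the class is treated as a
#'   single (singlet) population and the threshold uses that
#'   population's own mean and SD. Together with identifying the
#'   singlet component as the dominant-weight component (doublets are
#'   a small minority), this guards against the EM parking a
#'   near-degenerate component on a narrow slice of the singlet mode
#'   and flagging ordinary cells.
#' @return list with `filtered` (column-subset of `x`), and `report`
#'   (data.frame `cell`, `round`, `marker_set`, `cell_class`, `score`,
#'   `threshold`, one row per removed cell).
#' @export
filterDoublets <- function(x, markerSets, kSd = 8,
                           types = SummarizedExperiment::colData(x)$type,
                           normalized = TRUE, minSeparation = 2) {
  if (is.null(names(markerSets)) || any(!nzchar(names(markerSets))))
    stop("markerSets must be a named list (own type -> genes)")
  if (length(types) != ncol(x))
    stop("types must label every cell")
  types <- as.character(types)

  alive <- rep(TRUE, ncol(x))
  names(alive) <- colnames(x)
  report <- list()
  for (round in seq_along(markerSets)) {
    selfType <- names(markerSets)[round]
    for (cls in setdiff(unique(types), selfType)) {
      target <- alive & types == cls
      if (!any(target)) next
      scores <- tryCatch(
        markerSumScores(x[, target, drop = FALSE], markerSets[[round]],
                        normalized = normalized),
        error = function(e) e)
      fit <- if (inherits(scores, "error")) scores else
        tryCatch(fitTwoComponentGMM(scores), error = function(e) e)
      if (inherits(fit, "error")) {
        warning("round ", round, " (", selfType, " markers), class ",
                cls, " skipped: ", conditionMessage(fit))
        next
      }
      m <- mixtureMeans(fit); s <- mixtureSds(fit)
      w <- mixtureWeights(fit)
      ashmanD <- (m[2] - m[1]) / sqrt((s[1]^2 + s[2]^2) / 2)
      ## the singlet component is the dominant one: doublets are a
      ## small minority, so a low-weight low-mean component is an EM
      ## artefact (a narrow slice of the singlet mode), not the
      ## singlet population
      sing <- if (w[1] >= w[2]) 1L else 2L
      threshold <- if (ashmanD >= minSeparation)
        m[sing] + kSd * s[sing]
      else  # unimodal class: the singlet component is the whole class
        mean(scores) + kSd * sqrt(mean((scores - mean(scores))^2))
      flagged <- names(scores)[scores > threshold]
      if (length(flagged)) {
        alive[flagged] <- FALSE
        report[[length(report) + 1L]] <- data.frame(
          cell = flagged,
          round = round,
          marker_set = selfType,
          cell_class = cls,
          score = unname(scores[flagged]),
          threshold = threshold,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(cell = character(), round = integer(),
               marker_set = character(), cell_class = character(),
               score = numeric(), threshold = numeric(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(filtered = x[, alive, drop = FALSE], report = report)
}
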