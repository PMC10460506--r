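#' Per-gene two-group test on bulk replicates
#'
#' Two-sided per-gene test on log2(CPM + 1) replicate values. The
#' default is an empirical-Bayes moderated t-test (limma), the standard
#' choice at 4--6 replicates per group where per-gene variance
#' estimates are unstable; plain Welch t-tests and the exact rank-sum
#' test are also available (the granularity of exact rank-sum p-values
#' at few replicates limits the achievable FDR). Log2 fold changes are
#' computed from group mean CPM with a pseudocount, and
#' Benjamini-Hochberg correction is applied across genes.
#'
#' @param a,b count matrices (genes x replicates): reference and
#'   comparison group, >= 2 replicates each.
#' @param method `"moderated"` (default), `"welch"` or `"ranksum"`.
#' @param pseudocount pseudocount on the CPM scale for the fold change.
#' @return data.frame `gene`, `log2fc` (b over a), `statistic`, `p`,
#'   `fdr`, `mean_a`, `mean_b` (mean CPM).
#' @export
perGeneBulkTest <- function(a, b,
                            method = c("moderated", "welch", "ranksum"),
                            pseudocount = 1) {
  method <- match.arg(method)
  a <- .countsOf(a); b <- .countsOf(b)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs >= 2 replicates")
  if (!identical(rownames(a), rownames(b)))
    stop("gene universes differ between groups")
  la <- cpmLog2(a); lb <- cpmLog2(b)
  cpmA <- 2^la - 1; cpmB <- 2^lb - 1
  meanA <- rowMeans(cpmA); meanB <- rowMeans(cpmB)
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))

  if (method == "moderated") {
    design <- cbind(Intercept = 1,
                    group = c(rep(0, ncol(la)), rep(1, ncol(lb))))
    ## genes that are constant in both groups (usually all-zero) have
    ## zero sample variance; limma offsets those internally and warns,
    ## and their moderated t is 0 anyway
    fit <- suppressWarnings(
      limma::eBayes(limma::lmFit(cbind(la, lb), design)))
    statistic <- fit$t[, "group"]
    p <- fit$p.value[, "group"]
  } else if (method == "welch") {
    nA <- ncol(la); nB <- ncol(lb)
    mA <- rowMeans(la); mB <- rowMeans(lb)
    vA <- rowSums((la - mA)^2) / (nA - 1)
    vB <- rowSums((lb - mB)^2) / (nB - 1)
    se2 <- vA / nA + vB / nB
    tstat <- (mB - mA) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    flat <- se2 == 0
    tstat[flat] <- 0
    p[flat] <- 1
    statistic <- tstat
  } else {
    res <- lapply(seq_len(nrow(la)), function(i) {
      wt <- suppressWarnings(wilcox.test(lb[i, ], la[i, ]))
      c(unname(wt$statistic), wt$p.value)
    })
    statistic <- vapply(res, `[`, numeric(1), 1L)
    p <- vapply(res, `[`, numeric(1), 2L)
  }

  data.frame(
    gene = rownames(a), log2fc = log2fc, statistic = statistic,
    p = p, fdr = p.adjust(p, method = "BH"),
    mean_a = meanA, mean_b = meanB,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## Split a bulk SummarizedExperiment into the count submatrix of one
## design cell.
.bulkSubset <- function(se, gate, treatment, timepoint = NULL) {
  cd <- SummarizedExperiment::colData(se)
  sel <- cd$sort_gate == gate & cd$treatment == treatment
  if (!is.null(timepoint)) sel <- sel & cd$timepoint_h == timepoint
  SummarizedExperiment::assay(se, "counts")[, sel, drop = FALSE]
}

#' Differentially expressed gene counts per gate and timepoint
#'
#' For each sort gate and timepoint, tests IFN-gamma vs saline
#' replicates ([perGeneBulkTest()]) and counts genes passing
#' `|log2fc| > lfc` and `fdr < padj`, split by direction, together with
#' the cross-gate overlap (genes called in both gates with the same
#' direction).
#'
#' @param se bulk SummarizedExperiment from [genBulkSeries()] or with
#'   the same `colData` columns.
#' @param lfc,padj call thresholds (defaults 1 and 0.01).
#' @param method test passed to [perGeneBulkTest()].
#' @return list with `counts` (data.frame `sort_gate`, `timepoint_h`,
#'   `up`, `down`, `overlap_up`, `overlap_down`), `calls` (nested list
#'   gate -> timepoint -> list(up, down)), and `tables` (the per-test
#'   DE data.frames).
#' @export
degCountsByTimepoint <- function(se, lfc = 1, padj = 0.01,
                                 method = "moderated") {
  cd <- SummarizedExperiment::colData(se)
  gates <- unique(cd$sort_gate)
  tps <- sort(unique(cd$timepoint_h[cd$treatment == "IFN"]))
  calls <- list(); tables <- list()
  for (g in gates) {
    calls[[g]] <- list()
    for (tp in tps) {
      sal <- .bulkSubset(se, g, "saline", tp)
      ifn <- .bulkSubset(se, g, "IFN", tp)
      if (!ncol(sal) || !ncol(ifn))
        stop("missing design cell: ", g, " at ", tp, " h")
      tab <- perGeneBulkTest(sal, ifn, method = method)
      key <- paste0(g, "@", tp)
      tables[[key]] <- tab
      pass <- tab$fdr < padj & abs(tab$log2fc) > lfc
      calls[[g]][[as.character(tp)]] <- list(
        up = tab$gene[pass & tab$log2fc > 0],
        down = tab$gene[pass & tab$log2fc < 0])
    }
  }
  counts <- do.call(rbind, lapply(gates, function(g)
    do.call(rbind, lapply(tps, function(tp) {
      cl <- calls[[g]][[as.character(tp)]]
      other <- setdiff(gates, g)[1]
      ov <- if (!is.na(other)) calls[[other]][[as.character(tp)]] else
        list(up = character(), down = character())
      data.frame(sort_gate = g, timepoint_h = tp,
                 up = length(cl$up), down = length(cl$down),
                 overlap_up = length(intersect(cl$up, ov$up)),
                 overlap_down = length(intersect(cl$down, ov$down)),
                 stringsAsFactors = FALSE)
    }))))
  list(counts = counts, calls = calls, tables = tables)
}

#' Persistently upregulated core genes
#'
#' Genes called up in both sort gates at at least `minTimepoints`
#' timepoints: the sustained cross-cell-type core of the response.
#'
#' @param calls the `calls` element of [degCountsByTimepoint()].
#' @param minTimepoints minimum number of timepoints (default 3).
#' @param strictlyGreater require strictly more than `minTimepoints`
#'   timepoints instead of at least (default FALSE).
#' @return character vector of gene ids.
#' @export
persistentCoreGenes <- function(calls, minTimepoints = 3L,
                                strictlyGreater = FALSE) {
  gates <- names(calls)
  if (length(gates) < 2L) stop("need calls for two gates")
  perGate <- lapply(gates, function(g) {
    tab <- table(unlist(lapply(calls[[g]], `[[`, "up")))
    names(tab)[if (strictlyGreater) tab > minTimepoints else
      tab >= minTimepoints]
  })
  Reduce(intersect, perGate)
}

#' Mean +/- SEM kinetics of selected genes
#'
#' Per-gene, per-gate, per-timepoint mean and standard error of
#' log2(CPM + 1), with all saline replicates pooled at t = 0.
#'
#' @param se bulk SummarizedExperiment.
#' @param genes gene ids to profile.
#' @return data.frame `gene`, `sort_gate`, `timepoint_h`, `n`, `mean`,
#'   `sem` (`NA` with a flag impossible: groups of one replicate get
#'   `sem = NA`).
#' @export
kineticsProfile <- function(se, genes) {
  missing <- setdiff(genes, rownames(se))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cd <- SummarizedExperiment::colData(se)
  lcpm <- cpmLog2(SummarizedExperiment::assay(se, "counts"))[genes, ,
                                                             drop = FALSE]
  ## saline pools at t = 0; IFN keeps its timepoint
  tp <- ifelse(cd$treatment == "saline", 0, cd$timepoint_h)
  groups <- split(seq_len(ncol(se)),
                  list(gate = cd$sort_gate, tp = tp), drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(key) {
    ix <- groups[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- lcpm[, ix, drop = FALSE]
    n <- length(ix)
    data.frame(
      gene = genes,
      sort_gate = parts[1],
      timepoint_h = as.numeric(parts[2]),
      n = n,
      mean = rowMeans(sub),
      sem = if (n > 1) apply(sub, 1, sd) / sqrt(n) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  out[order(out$gene, out$sort_gate, out$timepoint_h), ]
}

#' Permutation test for gate-differential IFN effects
#'
#' Tests, per gene, whether the IFN-minus-saline effect on
#' log2(CPM + 1) differs between the NeuN- and NeuN+ gates. The
#' observed statistic is the difference of the two gates'
#' treatment-effect estimates (a linear contrast of replicate group
#' means). Its null distribution is obtained by a Freedman-Lane scheme:
#' the additive gate + treatment fit is held fixed and its residuals
#' are permuted within each gate before recomputing the contrast, so
#' main effects of gate and treatment (which are present for most
#' induced genes) do not inflate the interaction null. BH correction
#' across genes.
#'
#' @param se bulk SummarizedExperiment.
#' @param timepoint timepoint (hours) at which to compare effects.
#' @param nPerm number of permutations (>= 1000 recommended).
#' @param seed integer seed for the permutation draws.
#' @param fdrThreshold FDR below which a gene is called
#'   gate-differential.
#' @return list with `table` (data.frame `gene`, `effect_neuron`,
#'   `effect_glia`, `delta` = glia - neuron, `p`, `fdr`) and `genes`
#'   (the called set).
#' @export
interactionCalls <- function(se, timepoint, nPerm = 1000L, seed = 1L,
                             fdrThreshold = 0.05) {
  cd <- SummarizedExperiment::colData(se)
  sel <- cd$timepoint_h == timepoint &
    cd$treatment %in% c("saline", "IFN")
  if (!any(sel)) stop("no replicates at timepoint ", timepoint)
  sub <- se[, sel]
  cd <- SummarizedExperiment::colData(sub)
  gates <- sort(unique(cd$sort_gate))
  if (length(gates) != 2L) stop("need exactly two sort gates")
  perGateN <- table(cd$sort_gate, cd$treatment)
  if (any(perGateN < 3L))
    stop("need >= 3 replicates per gate x treatment for permutation")

  lcpm <- cpmLog2(SummarizedExperiment::assay(sub, "counts"))
  ## gate-difference of treatment effects as a linear contrast of
  ## replicate columns
  w <- numeric(ncol(sub))
  for (g in gates) {
    for (tr in c("IFN", "saline")) {
      ix <- cd$sort_gate == g & cd$treatment == tr
      sgnGate <- if (g == gates[1]) 1 else -1
      sgnTr <- if (tr == "IFN") 1 else -1
      w[ix] <- sgnGate * sgnTr / sum(ix)
    }
  }
  obs <- as.numeric(lcpm %*% w)

  effect <- function(gate) {
    ifn <- cd$sort_gate == gate & cd$treatment == "IFN"
    sal <- cd$sort_gate == gate & cd$treatment == "saline"
    rowMeans(lcpm[, ifn, drop = FALSE]) -
      rowMeans(lcpm[, sal, drop = FALSE])
  }
  effNeuron <- effect("NeuN+")
  effGlia <- effect("NeuN-")

  ## Freedman-Lane: residuals from the additive gate + treatment fit,
  ## permuted within gate; the additive fitted part is annihilated by
  ## the interaction contrast in a balanced design and retained exactly
  ## otherwise.
  X <- stats::model.matrix(~ sort_gate + treatment, data = as.data.frame(cd))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  fittedPart <- lcpm %*% H
  resid <- lcpm - fittedPart
  baseT <- as.numeric(fittedPart %*% w)
  gateIdx <- lapply(gates, function(g) which(cd$sort_gate == g))
  withr::with_seed(seed, {
    P <- vapply(seq_len(nPerm), function(b) {
      perm <- seq_len(ncol(sub))
      for (ix in gateIdx) perm[ix] <- ix[sample.int(length(ix))]
      perm
    }, integer(ncol(sub)))
  })
  permStats <- vapply(seq_len(nPerm), function(b)
    abs(baseT + as.numeric(resid[, P[, b], drop = FALSE] %*% w)),
    numeric(nrow(lcpm)))
  exceed <- rowSums(permStats >= abs(obs))
  p <- (1 + exceed) / (1 + nPerm)
  tab <- data.frame(
    gene = rownames(lcpm),
    effect_neuron = effNeuron,
    effect_glia = effGlia,
    delta = effGlia - effNeuron,
    p = p,
    fdr = p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(table = tab, genes = tab$gene[tab$fdr < fdrThreshold])
}

#' Classify interaction-significant genes into response modules
#'
#' Among genes with a gate-differential IFN effect, assigns the four
#' response-module archetypes: `purple` (up-called in both gates, glial
#' effect greater), `green` (neuron-high baseline, glia-only
#' upregulation), `orange` (neuron-high baseline, glia-only
#' downregulation), `yellow` (glia-high baseline, glial
#' downregulation); anything else is `UNCLASSIFIED`.
#'
#' @param neuronDE,gliaDE per-gate DE data.frames
#'   ([perGeneBulkTest()], saline vs IFN) for NeuN+ and NeuN-.
#' @param interactionGenes character vector of interaction-significant
#'   genes (see [interactionCalls()]).
#' @param baselineNeuron,baselineGlia named numeric vectors of saline
#'   log2(CPM + 1) means per gene and gate.
#' @param lfc,padj per-gate call thresholds (defaults 1, 0.01).
#' @param delta baseline log2 difference required for "highly expressed
#'   in one compartment but not the other" (default 1).
#' @return named character vector: gene -> module, over
#'   `interactionGenes`.
#' @export
classifyResponseModules <- function(neuronDE, gliaDE, interactionGenes,
                                    baselineNeuron, baselineGlia,
                                    lfc = 1, padj = 0.01, delta = 1) {
  shared <- Reduce(intersect, list(neuronDE$gene, gliaDE$gene,
                                   names(baselineNeuron),
                                   names(baselineGlia)))
  genes <- intersect(interactionGenes, shared)
  if (length(genes) < length(interactionGenes))
    warning("gene universes mismatch; classifying the intersection")

  nd <- neuronDE[match(genes, neuronDE$gene), ]
  gd <- gliaDE[match(genes, gliaDE$gene), ]
  nUp <- nd$fdr < padj & nd$log2fc > lfc
  nDown <- nd$fdr < padj & nd$log2fc < -lfc
  nCalled <- nUp | nDown
  gUp <- gd$fdr < padj & gd$log2fc > lfc
  gDown <- gd$fdr < padj & gd$log2fc < -lfc
  bN <- baselineNeuron[genes]
  bG <- baselineGlia[genes]

  out <- rep("UNCLASSIFIED", length(genes))
  out[nUp & gUp & gd$log2fc > nd$log2fc] <- "purple"
  green <- out == "UNCLASSIFIED" & (bN - bG > delta) & gUp & !nCalled
  out[green] <- "green"
  orange <- out == "UNCLASSIFIED" & (bN - bG > delta) & gDown & !nCalled
  out[orange] <- "orange"
  yellow <- out == "UNCLASSIFIED" & (bG - bN > delta) & gDown
  out[yellow] <- "yellow"
  stats::setNames(out, genes)
}

#' Saline baseline means per gate
#'
#' Convenience helper: per-gene mean log2(CPM + 1) over all saline
#' replicates of one gate.
#'
#' @param se bulk SummarizedExperiment.
#' @param gate sort gate label.
#' @return named numeric vector.
#' @export
baselineMeansByGate <- function(se, gate) {
  m <- .bulkSubset(se, gate, "saline")
  if (!ncol(m)) stop("no saline replicates for gate ", gate)
  rowMeans(cpmLog2(m))
}
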