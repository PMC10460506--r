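## Kinetic shape of IFN-driven fold changes over the time course:
## fraction of the asymptotic (log-scale) effect realised at each hour.
## Early responses peak at 6 h and decay; late responses peak at 24 h
## and decay slowly, remaining strongly elevated at 72 h.
.kineticShape <- function(timepoints, class) {
  early <- c("0" = 0, "6" = 1, "24" = 0.4, "48" = 0.15, "72" = 0.05)
  ## late decay leaves ~fold^0.7 (about 8-fold for a typical glial
  ## amplitude) at 72 h while keeping the 24 h peak resolvable at
  ## replicate-level noise
  late <- c("0" = 0, "6" = 0.4, "24" = 1, "48" = 0.8, "72" = 0.7)
  tab <- switch(class,
    isg_early = , mod_purple = , mod_green = , mod_orange = ,
    mod_yellow = early,
    isg_late = , mhc2 = late,
    stats::setNames(rep(0, 5), names(early))
  )
  key <- as.character(timepoints)
  if (!all(key %in% names(tab)))
    stop("bulk kinetics defined only for timepoints 0/6/24/48/72 h")
  unname(tab[key])
}

## Gate-level baseline relative expression and asymptotic IFN fold for
## every gene. Gates aggregate the neuronal (NeuN+) or glial (NeuN-)
## types, so marker genes and module archetypes get gate-specific
## baselines and the ISG amplitude asymmetry appears as a per-gene
## NeuN-/NeuN+ fold ratio in the configured 2--8 range.
.bulkGateProgram <- function(config, program, inducedShare = 0.05) {
  base <- cbind(`NeuN+` = program$base_mean, `NeuN-` = program$base_mean)
  fold <- cbind(`NeuN+` = rep(1, nrow(program)),
                `NeuN-` = rep(1, nrow(program)))
  rownames(base) <- rownames(fold) <- program$gene

  isMark <- program$class == "marker"
  neuronalMark <- isMark & program$marker_type %in% .NEURONAL_TYPES
  glialMark <- isMark & program$marker_type %in% .GLIAL_TYPES
  base[neuronalMark, "NeuN+"] <- base[neuronalMark, "NeuN+"] * config@markerFold
  base[neuronalMark, "NeuN-"] <- base[neuronalMark, "NeuN-"] * 0.02
  base[glialMark, "NeuN-"] <- base[glialMark, "NeuN-"] * config@markerFold
  base[glialMark, "NeuN+"] <- base[glialMark, "NeuN+"] * 0.02

  isg <- program$class %in% c("isg_early", "isg_late")
  fold[isg, "NeuN+"] <- config@isgFoldNeuron
  fold[isg, "NeuN-"] <- config@isgFoldNeuron * program$glia_factor[isg]

  mhc2 <- program$class == "mhc2"
  base[mhc2, ] <- base[mhc2, ] * .MHC2_BASELINE
  fold[mhc2, "NeuN-"] <- config@mhc2Fold

  modP <- program$class == "mod_purple"
  fold[modP, "NeuN+"] <- 4
  fold[modP, "NeuN-"] <- 16

  modG <- program$class == "mod_green"
  base[modG, "NeuN+"] <- base[modG, "NeuN+"] * 10
  base[modG, "NeuN-"] <- base[modG, "NeuN-"] * 0.5
  fold[modG, "NeuN-"] <- 6

  modO <- program$class == "mod_orange"
  base[modO, "NeuN+"] <- base[modO, "NeuN+"] * 10
  base[modO, "NeuN-"] <- base[modO, "NeuN-"] * 0.5
  fold[modO, "NeuN-"] <- 1 / 6

  modY <- program$class == "mod_yellow"
  base[modY, "NeuN-"] <- base[modY, "NeuN-"] * 10
  base[modY, "NeuN+"] <- base[modY, "NeuN+"] * 0.5
  fold[modY, "NeuN-"] <- 1 / 6

  ## cell-type marker genes are identity labels, not the bulk of the
  ## transcriptome: cap their mass share per gate so they cannot crowd
  ## out the rest of the library (at many markers per type and a large
  ## own-type fold their naive share would dominate the gate)
  isMarkGene <- isMark
  for (g in colnames(base)) {
    markMass <- sum(base[isMarkGene, g])
    lim <- 0.3 * sum(base[, g])
    if (markMass > lim)
      base[isMarkGene, g] <- base[isMarkGene, g] * lim / markMass
  }

  ## keep the aggregate induced mass a small share of the library, as
  ## in real transcriptomes: otherwise per-replicate CPM normalization
  ## couples every gene to the induction program (a strongly induced
  ## 20% mass share would depress all other genes' CPM at the response
  ## peak and distort the planted kinetics)
  induced <- rowSums(fold > 1) > 0
  for (g in colnames(base)) {
    extra <- sum(base[induced, g] * pmax(fold[induced, g] - 1, 0))
    lim <- inducedShare * sum(base[, g])
    if (extra > lim)
      base[induced, g] <- base[induced, g] * lim / extra
  }

  list(base = base, fold = fold)
}

#' Simulate a bulk sorted-nuclei RNA-seq time course
#'
#' Generates replicate-level UMI counts for NeuN+ (neuronal) and NeuN-
#' (glial) sorted nuclei over the configured time course. Early ISGs
#' peak at 6 h; late ISGs peak at 24 h and decay slowly (still strongly
#' elevated at 72 h); the glial induced amplitude exceeds the neuronal
#' one by the configured per-gene 2--8-fold factor; four response-module
#' archetype gene sets are planted (conserved-up-glia-amplified,
#' neuron-baseline/glia-up, neuron-baseline/glia-down,
#' glia-baseline/glia-down). Saline replicates sit at the baseline of
#' their gate at every timepoint.
#'
#' @param config a [SimConfig-class]; `replicateDesign` defines the
#'   replicates.
#' @param bulkDispersion negative-binomial size parameter for replicate
#'   counts (large = replicate-level noise only).
#' @param inducedShare cap on the extra library mass contributed by
#'   induced genes at full induction, as a fraction of the library
#'   (default 0.05); keeps global composition realistic so CPM values
#'   of unrelated genes are not depressed at the response peak.
#' @param seed optional integer overriding `config@seed`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with integer
#'   `counts` (genes x replicates), `colData` columns `replicate`,
#'   `sort_gate`, `treatment`, `timepoint_h`, and `rowData` column
#'   `class` carrying the planted gene classes.
#' @export
genBulkSeries <- function(config, bulkDispersion = 50,
                          inducedShare = 0.05, seed = config@seed) {
  validObject(config)
  design <- config@replicateDesign
  if (nrow(design) == 0L) stop("replicateDesign is empty")
  need <- c("sort_gate", "treatment", "timepoint_h", "n_replicates")
  if (!all(need %in% names(design)))
    stop("replicateDesign must have columns ",
         paste(need, collapse = ", "))
  program <- geneProgram(config)
  gp <- .bulkGateProgram(config, program, inducedShare = inducedShare)

  reps <- design[rep(seq_len(nrow(design)), design$n_replicates), ,
                 drop = FALSE]
  reps$n_replicates <- NULL
  rownames(reps) <- NULL
  reps$replicate <- sprintf("rep%03d", seq_len(nrow(reps)))

  withr::with_seed(seed, {
    counts <- matrix(0L, nrow = nrow(program), ncol = nrow(reps),
                     dimnames = list(program$gene, reps$replicate))
    for (i in seq_len(nrow(reps))) {
      gate <- reps$sort_gate[i]
      if (!gate %in% colnames(gp$base))
        stop("unknown sort gate: ", gate)
      mu <- gp$base[, gate]
      if (reps$treatment[i] == "IFN") {
        shape <- vapply(program$class, function(cl)
          .kineticShape(reps$timepoint_h[i], cl), numeric(1))
        ## interpolate the fold on the log scale so partial effects are
        ## geometric between baseline and the asymptotic fold
        mu <- mu * exp(log(gp$fold[, gate]) * shape)
      }
      mu <- mu / sum(mu) * config@bulkDepth
      counts[, i] <- rnbinom(length(mu), mu = mu, size = bulkDispersion)
    }
  })

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(reps, row.names = reps$replicate),
    rowData = S4Vectors::DataFrame(class = program$class,
                                   row.names = program$gene)
  )
}

#' Planted bulk response-module genes
#'
#' Ground-truth gene lists for the four bulk response-module archetypes.
#'
#' @param module one of `"purple"`, `"green"`, `"orange"`, `"yellow"`.
#' @return character vector of gene ids.
#' @export
plantedModuleGenes <- function(module = c("purple", "green", "orange",
                                          "yellow")) {
  module <- match.arg(module)
  .MODULE_GENE_NAMES[[paste0("mod_", module)]]
}
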