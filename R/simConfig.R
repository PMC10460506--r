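`%||%` <- function(a, b) if (is.null(a)) b else a

## Major-cell-type vocabulary used throughout the simulator. The glial /
## neuronal split drives the amplitude asymmetry of the IFN response.
.GLIAL_TYPES <- c("Oligodendrocyte", "Astrocyte", "Microglia")
.NEURONAL_TYPES <- c("Dopamine", "GABAergic", "VGLUT2")
.ALL_TYPES <- c(.GLIAL_TYPES, .NEURONAL_TYPES)

## Published nuclei counts per major type after doublet filtering; used as
## the default composition of the simulated single-nucleus experiment.
.DEFAULT_COMPOSITION <- c(
  Oligodendrocyte = 1241L, Astrocyte = 194L, Microglia = 134L,
  Dopamine = 437L, GABAergic = 1257L, VGLUT2 = 1436L
)

## Canonical marker genes per type; the generator pads each list with
## synthetic names up to markerGenesPerType.
.CANONICAL_MARKERS <- list(
  Oligodendrocyte = c("Mal", "Mag", "Mog", "Mbp", "Plp1"),
  Astrocyte = c("Gja1", "Fgfr3", "Atp1a2"),
  Microglia = c("C1qb", "Siglech", "Csf1r"),
  Dopamine = c("Th", "Slc6a3", "En1", "Slc10a4"),
  GABAergic = c("Slc32a1", "Gad1", "Gad2"),
  VGLUT2 = c("Slc17a6", "Cacna2d1", "Ntng1")
)

## Interferon-stimulated genes by kinetic class. Early genes peak at 6 h
## (GAS-driven first wave); late genes peak at 24 h and decay slowly
## (IRF1/ISRE-driven second wave).
.ISG_EARLY <- c("Tap1", "Tapbp", "Irf1", "Cxcl9", "Cxcl10", "Cxcl11",
                "Ccl2", "Ccl12", "Socs1", "Gbp3")
.ISG_LATE <- c("H2-K1", "H2-D1", "B2m", "Psmb9", "Stat1", "Nlrc5",
               "Gbp2", "Tap2", "Psmb8", "Irgm1")

## MHC class II genes plus the invariant chain: induced only in microglia.
.MHC2_GENES <- c("H2-Ab1", "H2-Eb1", "H2-Aa", "Cd74")

## Bulk response-module archetypes (gate-level behaviour in the bulk
## series): purple = induced in both gates, stronger in glia; green =
## neuron-high baseline, glia-only induction; orange = neuron-high
## baseline, glia-only repression; yellow = glia-high baseline, glial
## repression.
.MODULE_CLASSES <- c("mod_purple", "mod_green", "mod_orange", "mod_yellow")
.MODULE_GENES_PER_CLASS <- 15L
.MODULE_GENE_NAMES <- setNames(lapply(.MODULE_CLASSES, function(cl)
  sprintf("%s%03d", c(mod_purple = "ModP", mod_green = "ModG",
                      mod_orange = "ModO", mod_yellow = "ModY")[[cl]],
          seq_len(.MODULE_GENES_PER_CLASS))), .MODULE_CLASSES)

#' Construct a simulation configuration
#'
#' Builds a [SimConfig-class] with defaults matching the structure of a
#' sorted-nuclei interferon-gamma study of the mouse ventral midbrain:
#' six major cell types at the published composition (1,241
#' oligodendrocytes, 194 astrocytes, 134 microglia, 437 dopamine, 1,257
#' GABAergic and 1,436 VGLUT2 nuclei), interferon-stimulated genes whose
#' induction is 2--8-fold stronger in glia than in neurons, early (6 h)
#' and late (24 h) kinetic classes over a 0/6/24/48/72 h time course,
#' microglia-restricted MHC-II genes, doublets formed as sums of two
#' parent profiles, and substitution errors plus PCR duplicates in
#' barcode/UMI-tagged reads.
#'
#' @param seed integer seed fixing all generator randomness.
#' @param nCellsByType named integer vector of cells per type; defaults
#'   to the published composition.
#' @param nGenes number of genes in the simulated universe.
#' @param markerGenesPerType planted marker genes per cell type.
#' @param isgFoldNeuron neuronal ISG fold induction under IFN-gamma.
#' @param gliaAmplitudeRange range of the per-gene glia/neuron amplitude
#'   ratio (default `c(2, 8)`).
#' @param mhc2Fold microglial fold induction of MHC-II genes.
#' @param timepoints bulk time course in hours (0 = saline).
#' @param doubletFraction fraction of cells replaced by doublets.
#' @param barcodeLength,umiLength tag lengths in nucleotides.
#' @param barcodeErrorRate,umiErrorRate per-read substitution
#'   probabilities (at most one substitution per tag per read).
#' @param readsPerMoleculeMean mean reads per molecule (PCR duplication).
#' @param moleculesPerCellMean mean true molecules per cell in read
#'   simulation.
#' @param dispersion shared negative-binomial size parameter.
#' @param baseMeanLog,baseMeanSdLog log-normal parameters for baseline
#'   gene means.
#' @param markerFold fold elevation of a marker in its own type.
#' @param replicateDesign bulk design data.frame (`sort_gate`,
#'   `treatment`, `timepoint_h`, `n_replicates`); default 5 replicates
#'   per condition with saline controls at every timepoint.
#' @param bulkDepth mean total counts per bulk replicate.
#'
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 500)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nCellsByType = .DEFAULT_COMPOSITION,
                      nGenes = 2000L,
                      markerGenesPerType = 120L,
                      isgFoldNeuron = 4,
                      gliaAmplitudeRange = c(2, 8),
                      mhc2Fold = 30,
                      timepoints = c(0, 6, 24, 48, 72),
                      doubletFraction = 0,
                      barcodeLength = 12L,
                      umiLength = 8L,
                      barcodeErrorRate = 0.01,
                      umiErrorRate = 0.01,
                      readsPerMoleculeMean = 3,
                      moleculesPerCellMean = 200,
                      dispersion = 2,
                      baseMeanLog = log(0.5),
                      baseMeanSdLog = 1,
                      markerFold = 30,
                      replicateDesign = defaultBulkDesign(),
                      bulkDepth = 5e5) {
  cells <- as.integer(round(nCellsByType))
  names(cells) <- names(nCellsByType)
  new("SimConfig",
      seed = as.integer(seed),
      nCellsByType = cells,
      nGenes = as.integer(nGenes),
      markerGenesPerType = as.integer(markerGenesPerType),
      isgFoldNeuron = isgFoldNeuron,
      gliaAmplitudeRange = as.numeric(gliaAmplitudeRange),
      mhc2Fold = mhc2Fold,
      timepoints = as.numeric(timepoints),
      doubletFraction = doubletFraction,
      barcodeLength = as.integer(barcodeLength),
      umiLength = as.integer(umiLength),
      barcodeErrorRate = barcodeErrorRate,
      umiErrorRate = umiErrorRate,
      readsPerMoleculeMean = readsPerMoleculeMean,
      moleculesPerCellMean = moleculesPerCellMean,
      dispersion = dispersion,
      baseMeanLog = baseMeanLog,
      baseMeanSdLog = baseMeanSdLog,
      markerFold = markerFold,
      replicateDesign = replicateDesign,
      bulkDepth = bulkDepth)
}

#' Default bulk replicate design
#'
#' Five replicates per (sort gate, treatment, timepoint) cell: NeuN+ and
#' NeuN- nuclei, IFN-gamma at 6/24/48/72 h, and saline controls at every
#' timepoint (pooled at t = 0 downstream).
#'
#' @return data.frame with columns `sort_gate`, `treatment`,
#'   `timepoint_h`, `n_replicates`.
#' @export
defaultBulkDesign <- function() {
  d <- expand.grid(
    sort_gate = c("NeuN+", "NeuN-"),
    treatment = c("saline", "IFN"),
    timepoint_h = c(6, 24, 48, 72),
    stringsAsFactors = FALSE
  )
  d$n_replicates <- 5L
  d
}

#' Read a simulation configuration from YAML
#'
#' Any field of [simConfig()] may appear as a top-level YAML key;
#' omitted fields take their defaults. `replicateDesign` may be given as
#' a list of records with the design columns.
#'
#' @param path path to a YAML file.
#' @return a [SimConfig-class].
#' @export
simConfigFromYAML <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(vals$nCellsByType))
    vals$nCellsByType <- unlist(vals$nCellsByType)
  if (!is.null(vals$replicateDesign))
    vals$replicateDesign <- do.call(
      rbind, lapply(vals$replicateDesign, as.data.frame))
  do.call(simConfig, vals)
}

## Deterministic layout of the simulated gene universe: which genes are
## markers (and for which type), early/late ISGs, MHC-II, and filler.
## Randomness (baseline means, per-gene glia amplitude factors) is drawn
## under the config seed so the program is a pure function of the config.
geneProgram <- function(config) {
  nMark <- config@markerGenesPerType
  markers <- lapply(.ALL_TYPES, function(ty) {
    canon <- .CANONICAL_MARKERS[[ty]]
    if (is.null(canon)) canon <- character()
    extra <- nMark - length(canon)
    c(canon, if (extra > 0)
      sprintf("Mk%s%03d", abbreviate(ty, 4), seq_len(extra)))[seq_len(nMark)]
  })
  names(markers) <- .ALL_TYPES

  special <- c(unlist(markers, use.names = FALSE), .ISG_EARLY, .ISG_LATE,
               .MHC2_GENES, unlist(.MODULE_GENE_NAMES, use.names = FALSE))
  if (anyDuplicated(special))
    stop("internal error: overlapping gene-program classes")
  nFiller <- config@nGenes - length(special)
  if (nFiller < 0)
    stop("nGenes too small for the configured gene program (need >= ",
         length(special), ")")
  genes <- c(special, sprintf("Gene%04d", seq_len(nFiller)))

  cls <- rep("filler", length(genes))
  names(cls) <- genes
  for (ty in .ALL_TYPES) cls[markers[[ty]]] <- "marker"
  cls[.ISG_EARLY] <- "isg_early"
  cls[.ISG_LATE] <- "isg_late"
  cls[.MHC2_GENES] <- "mhc2"
  for (mcl in .MODULE_CLASSES) cls[.MODULE_GENE_NAMES[[mcl]]] <- mcl

  markerType <- rep(NA_character_, length(genes))
  names(markerType) <- genes
  for (ty in .ALL_TYPES) markerType[markers[[ty]]] <- ty

  withr::with_seed(config@seed, {
    baseMean <- rlnorm(length(genes), config@baseMeanLog,
                       config@baseMeanSdLog)
    ## markers and programmed genes get a moderate, reproducible baseline
    baseMean[cls != "filler"] <- rlnorm(
      sum(cls != "filler"), log(0.8), 0.5)
    gliaFactor <- runif(length(genes), config@gliaAmplitudeRange[1],
                        config@gliaAmplitudeRange[2])
  })

  data.frame(
    gene = genes,
    class = unname(cls),
    marker_type = unname(markerType),
    base_mean = baseMean,
    glia_factor = gliaFactor,
    row.names = genes,
    stringsAsFactors = FALSE
  )
}

## Per-type mean matrix (genes x types) at baseline: markers elevated
## in their own type, leaky elsewhere. The off-type leak (8% of base)
## mirrors the few-percent off-type detection rates of lineage markers
## in real nuclei data (ambient background): low enough for strong
## binomial specificity, high enough that marker-sum scores of
## singlets form a continuous distribution a Gaussian mixture can
## describe rather than a sparse count lattice.
.MARKER_OFFTYPE_LEAK <- 0.08

## MHC-II is near-silent at baseline in every type (antigen-presenting
## induction is what makes it microglia-restricted under IFN).
.MHC2_BASELINE <- 0.05

baselineMeans <- function(config, program) {
  mu <- matrix(program$base_mean, nrow = nrow(program),
               ncol = length(.ALL_TYPES),
               dimnames = list(program$gene, .ALL_TYPES))
  isMark <- program$class == "marker"
  for (ty in .ALL_TYPES) {
    own <- isMark & program$marker_type == ty
    mu[own, ty] <- mu[own, ty] * config@markerFold
    mu[isMark & program$marker_type != ty, ty] <-
      mu[isMark & program$marker_type != ty, ty] * .MARKER_OFFTYPE_LEAK
  }
  mu[program$class == "mhc2", ] <- mu[program$class == "mhc2", ] *
    .MHC2_BASELINE
  mu
}

## IFN induction fold per (gene, type). Neuronal ISG fold is
## isgFoldNeuron; glial fold is that times the per-gene glia factor.
## MHC-II genes are induced in microglia only.
inductionFolds <- function(config, program) {
  fold <- matrix(1, nrow = nrow(program), ncol = length(.ALL_TYPES),
                 dimnames = list(program$gene, .ALL_TYPES))
  isg <- program$class %in% c("isg_early", "isg_late")
  for (ty in .NEURONAL_TYPES) fold[isg, ty] <- config@isgFoldNeuron
  for (ty in .GLIAL_TYPES)
    fold[isg, ty] <- config@isgFoldNeuron * program$glia_factor[isg]
  fold[program$class == "mhc2", "Microglia"] <- config@mhc2Fold
  fold
}
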