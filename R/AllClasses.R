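#' @import methods
#' @importFrom stats median sd quantile rnbinom rpois rbinom rnorm runif
#'   rlnorm p.adjust pbinom pnorm wilcox.test t.test dnorm setNames
#'   complete.cases rgamma ks.test
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration for sorted-nuclei experiments
#'
#' A `SimConfig` holds every knob of the synthetic-data generator:
#' cell-type composition, gene program layout (markers, early/late
#' interferon-stimulated genes, microglia-restricted MHC-II genes),
#' induction amplitudes, time course, doublet rate, barcode/UMI geometry
#' and error rates, and the bulk replicate design. All generators are
#' pure functions of a `SimConfig` plus its seed.
#'
#' @slot seed integer; fixes all downstream randomness.
#' @slot nCellsByType named integer vector, cells per major type.
#' @slot nGenes total number of genes in the simulated universe.
#' @slot markerGenesPerType number of marker genes planted per type.
#' @slot isgFoldNeuron fold induction of ISGs in neuronal types under
#'   IFN-gamma (unitless, > 1).
#' @slot gliaAmplitudeRange length-2 numeric; glial ISG induction is the
#'   neuronal fold multiplied by a per-gene factor drawn uniformly from
#'   this range (default 2--8).
#' @slot mhc2Fold fold induction of MHC-II genes in microglia only.
#' @slot timepoints hours of the bulk time course; 0 denotes saline.
#' @slot doubletFraction fraction of cells replaced by doublets in [0, 1).
#' @slot barcodeLength,umiLength nucleotides.
#' @slot barcodeErrorRate,umiErrorRate per-read probability of a single
#'   substitution in the barcode / UMI.
#' @slot readsPerMoleculeMean mean reads per molecule (>= 1; the excess
#'   over one read is Poisson).
#' @slot moleculesPerCellMean mean true molecules per cell for read
#'   simulation.
#' @slot dispersion negative-binomial size parameter shared across genes
#'   (smaller = more overdispersed).
#' @slot baseMeanLog,baseMeanSdLog log-normal parameters of baseline
#'   per-gene mean counts.
#' @slot markerFold fold elevation of a marker gene in its own type.
#' @slot replicateDesign data.frame with columns `sort_gate`,
#'   `treatment`, `timepoint_h`, `n_replicates` describing the bulk
#'   experiment.
#' @slot bulkDepth mean total counts per bulk replicate.
#'
#' @seealso [simConfig()] for the user-facing constructor with the
#'   study-composition defaults.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nCellsByType = "integer",
  nGenes = "integer",
  markerGenesPerType = "integer",
  isgFoldNeuron = "numeric",
  gliaAmplitudeRange = "numeric",
  mhc2Fold = "numeric",
  timepoints = "numeric",
  doubletFraction = "numeric",
  barcodeLength = "integer",
  umiLength = "integer",
  barcodeErrorRate = "numeric",
  umiErrorRate = "numeric",
  readsPerMoleculeMean = "numeric",
  moleculesPerCellMean = "numeric",
  dispersion = "numeric",
  baseMeanLog = "numeric",
  baseMeanSdLog = "numeric",
  markerFold = "numeric",
  replicateDesign = "data.frame",
  bulkDepth = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@nCellsByType < 0L)) msg <- c(msg, "cell counts must be >= 0")
  if (is.null(names(object@nCellsByType)) || anyDuplicated(names(object@nCellsByType)))
    msg <- c(msg, "nCellsByType must have unique names")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@doubletFraction < 0 || object@doubletFraction >= 1)
    msg <- c(msg, "doubletFraction must be in [0, 1)")
  if (object@isgFoldNeuron <= 0 || object@mhc2Fold <= 0 || object@markerFold <= 0)
    msg <- c(msg, "fold changes must be > 0")
  if (length(object@gliaAmplitudeRange) != 2L ||
      any(object@gliaAmplitudeRange <= 0) ||
      diff(object@gliaAmplitudeRange) < 0)
    msg <- c(msg, "gliaAmplitudeRange must be an increasing positive pair")
  if (object@barcodeErrorRate < 0 || object@barcodeErrorRate > 1 ||
      object@umiErrorRate < 0 || object@umiErrorRate > 1)
    msg <- c(msg, "error rates must be probabilities")
  if (object@readsPerMoleculeMean < 1)
    msg <- c(msg, "readsPerMoleculeMean must be >= 1")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' Two-component Gaussian mixture fit
#'
#' Result of [fitTwoComponentGMM()]. Components are stored in ascending
#' order of mean; the first component is interpreted downstream as the
#' singlet population when filtering doublets.
#'
#' @slot weights numeric(2), mixing proportions summing to one.
#' @slot means numeric(2), ascending component means.
#' @slot sds numeric(2), positive component standard deviations.
#' @slot converged logical flag from the EM loop.
#' @slot nPoints number of observations fitted.
#' @slot logLik final observed-data log-likelihood.
#' @slot iterations EM iterations used.
#' @export
setClass("MixtureFit", representation(
  weights = "numeric",
  means = "numeric",
  sds = "numeric",
  converged = "logical",
  nPoints = "integer",
  logLik = "numeric",
  iterations = "integer"
))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (length(object@means) != 2L || length(object@sds) != 2L ||
      length(object@weights) != 2L)
    msg <- c(msg, "exactly two components required")
  if (is.unsorted(object@means)) msg <- c(msg, "means must be ascending")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be > 0")
  if (any(object@weights <= 0) || any(object@weights >= 1) ||
      abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must be in (0,1) and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Gene signature
#'
#' A named, duplicate-free set of gene identifiers whose normalized
#' expression is summed per cell by [signatureScore()].
#'
#' @slot name signature label.
#' @slot genes character vector of gene identifiers.
#' @export
setClass("GeneSignature", representation(
  name = "character",
  genes = "character"
))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "signature must be nonempty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in signature")
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSignature-class construct a signature.
#' @param name signature label.
#' @param genes character vector of gene identifiers (no duplicates).
#' @export
GeneSignature <- function(name, genes) {
  new("GeneSignature", name = as.character(name), genes = as.character(genes))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", sum(object@nCellsByType), " cells / ",
      length(object@nCellsByType), " types, ", object@nGenes, " genes\n",
      sep = "")
  comp <- paste0(names(object@nCellsByType), "=", object@nCellsByType)
  cat("  composition: ", paste(comp, collapse = ", "), "\n", sep = "")
  cat("  doublet fraction: ", object@doubletFraction,
      "; seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit (n=%d, %s in %d iterations)\n", object@nPoints,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
  cat(sprintf("  comp1: w=%.3f mean=%.4g sd=%.4g\n",
              object@weights[1], object@means[1], object@sds[1]))
  cat(sprintf("  comp2: w=%.3f mean=%.4g sd=%.4g\n",
              object@weights[2], object@means[2], object@sds[2]))
})

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ", length(object@genes),
      " genes\n", sep = "")
})

#' @describeIn MixtureFit-class component means (ascending).
#' @param object a `MixtureFit`.
#' @export
mixtureMeans <- function(object) object@means

#' @describeIn MixtureFit-class component standard deviations.
#' @export
mixtureSds <- function(object) object@sds

#' @describeIn MixtureFit-class mixing weights.
#' @export
mixtureWeights <- function(object) object@weights

#' @describeIn GeneSignature-class genes in the signature.
#' @param x a `GeneSignature`.
#' @export
signatureGenes <- function(x) x@genes

#' @describeIn GeneSignature-class signature name.
#' @export
signatureName <- function(x) x@name
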