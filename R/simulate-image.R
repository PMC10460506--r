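.NUCLEUS_CLASSES <- c("TH+/NeuN+", "TH-/NeuN+", "TH-/NeuN-")

#' Simulate a multi-channel nuclei image with ROI labels and truth
#'
#' Paints disk-shaped nuclei of the three classes used in midbrain
#' pSTAT1 quantification (TH+/NeuN+ dopamine neurons, TH-/NeuN+
#' non-dopamine neurons, TH-/NeuN- glia) onto a noisy background. The
#' four channels are DAPI (all nuclei), TH and NeuN (class markers) and
#' a signal channel painted at a per-class intensity. Nuclei are placed
#' without overlap by rejection sampling.
#'
#' @param config a [SimConfig-class] (supplies the seed).
#' @param width,height image size in pixels.
#' @param nPerClass named integer vector: nuclei per class (names from
#'   `"TH+/NeuN+"`, `"TH-/NeuN+"`, `"TH-/NeuN-"`).
#' @param radius disk radius in pixels.
#' @param background background intensity (arbitrary units).
#' @param noiseSd Gaussian noise SD added to every pixel (0 = noise-free).
#' @param markerLevel intensity painted into DAPI/TH/NeuN channels for
#'   positive nuclei, above background.
#' @param signalLevels named numeric: signal-channel intensity painted
#'   for each class, above background.
#' @param seed optional integer overriding `config@seed`.
#' @return list with `stack` (height x width x 4 array, channels
#'   `dapi`, `th`, `neun`, `signal`), `labels` (integer ROI label
#'   matrix, 0 = background) and `truth` (data.frame `roi_id`, `class`,
#'   `signal`, centre coordinates and radius; `signal` is the painted
#'   signal level above background).
#' @export
genNucleiImage <- function(config,
                           width = 256L, height = 256L,
                           nPerClass = c(`TH+/NeuN+` = 8L,
                                         `TH-/NeuN+` = 8L,
                                         `TH-/NeuN-` = 8L),
                           radius = 6,
                           background = 100,
                           noiseSd = 5,
                           markerLevel = 150,
                           signalLevels = c(`TH+/NeuN+` = 60,
                                            `TH-/NeuN+` = 70,
                                            `TH-/NeuN-` = 180),
                           seed = config@seed) {
  validObject(config)
  if (width < 1L || height < 1L) stop("image dimensions must be positive")
  classes <- rep(names(nPerClass), nPerClass)
  nRoi <- length(classes)
  capacity <- floor(width * height / (pi * (2 * radius + 2)^2))
  if (nRoi > capacity)
    stop("cannot place ", nRoi, " non-overlapping nuclei of radius ",
         radius, " in a ", width, "x", height, " image")

  withr::with_seed(seed, {
    centres <- matrix(NA_real_, nrow = nRoi, ncol = 2)
    placed <- 0L
    attempts <- 0L
    while (placed < nRoi) {
      attempts <- attempts + 1L
      if (attempts > 200L * nRoi)
        stop("failed to place non-overlapping nuclei; reduce count or radius")
      cand <- c(runif(1, radius + 1, height - radius),
                runif(1, radius + 1, width - radius))
      if (placed > 0L) {
        d2 <- (centres[seq_len(placed), 1] - cand[1])^2 +
          (centres[seq_len(placed), 2] - cand[2])^2
        if (any(d2 < (2 * radius + 2)^2)) next
      }
      placed <- placed + 1L
      centres[placed, ] <- cand
    }

    labels <- matrix(0L, nrow = height, ncol = width)
    chans <- c("dapi", "th", "neun", "signal")
    stack <- array(background, dim = c(height, width, 4L),
                   dimnames = list(NULL, NULL, chans))
    rowIdx <- matrix(seq_len(height), nrow = height, ncol = width)
    colIdx <- matrix(seq_len(width), nrow = height, ncol = width,
                     byrow = TRUE)
    for (i in seq_len(nRoi)) {
      disk <- (rowIdx - centres[i, 1])^2 + (colIdx - centres[i, 2])^2 <=
        radius^2
      labels[disk] <- i
      cls <- classes[i]
      stack[, , "dapi"][disk] <- background + markerLevel
      if (startsWith(cls, "TH+"))
        stack[, , "th"][disk] <- background + markerLevel
      if (grepl("NeuN\\+", cls))
        stack[, , "neun"][disk] <- background + markerLevel
      stack[, , "signal"][disk] <- background + signalLevels[[cls]]
    }
    if (noiseSd > 0)
      stack <- stack + array(rnorm(length(stack), 0, noiseSd),
                             dim = dim(stack), dimnames = dimnames(stack))
  })

  truth <- data.frame(
    roi_id = seq_len(nRoi),
    class = classes,
    signal = if (nRoi) unname(signalLevels[classes]) else numeric(0),
    centre_row = centres[, 1],
    centre_col = centres[, 2],
    radius = rep(radius, nRoi),
    stringsAsFactors = FALSE
  )
  list(stack = stack, labels = labels, truth = truth)
}
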