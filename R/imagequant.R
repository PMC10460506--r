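#' Maximum-intensity projection
#'
#' Collapses a z-stack (rows x cols x z) to a single 2D image by
#' per-pixel maximum.
#'
#' @param stack 3D numeric array.
#' @return numeric matrix.
#' @export
maxProject <- function(stack) {
  if (length(dim(stack)) != 3L) stop("expected a rows x cols x z array")
  apply(stack, c(1, 2), max)
}

#' Threshold a channel at k standard deviations above background
#'
#' Estimates the image background and its spread, then masks pixels
#' brighter than `background + k * SD`. The default robust estimator
#' takes the background level as the image median and its SD as the
#' root mean square deviation of sub-median pixels from the median
#' (consistent for symmetric noise and insensitive to bright objects);
#' `method = "mean"` uses the plain mean/SD of all pixels.
#'
#' @param img single-channel 2D numeric matrix (max-projected
#'   upstream).
#' @param k threshold in background SDs (default 2).
#' @param method background estimator, `"median"` (robust, default) or
#'   `"mean"`.
#' @return logical matrix; constant images give an all-FALSE mask with
#'   a warning.
#' @export
channelMask2sd <- function(img, k = 2, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is.matrix(img)) stop("expected a 2D image matrix")
  if (diff(range(img)) == 0) {
    warning("constant image; empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  if (method == "median") {
    bg <- median(img)
    below <- img[img < bg]
    bgSd <- if (length(below)) sqrt(mean((below - bg)^2)) else 0
  } else {
    bg <- mean(img)
    bgSd <- sd(img)
  }
  img > bg + k * bgSd
}

## ROI ids present in a label mask (excluding background 0).
.roiIds <- function(labels) sort(unique(labels[labels > 0]))

#' Classify ROIs by marker-mask overlap
#'
#' An ROI is marker-positive when more than `overlapFrac` of its pixels
#' fall inside the marker's binary mask; the (TH, NeuN) positivity pair
#' then yields the nucleus class: `TH+/NeuN+` (dopamine neurons),
#' `TH-/NeuN+` (other neurons) or `TH-/NeuN-` (glia). TH+/NeuN- ROIs
#' (not part of the scheme) are labelled `"TH+/NeuN-"`.
#'
#' @param labels integer ROI label matrix (0 = background).
#' @param thMask,neunMask logical marker masks, same shape as `labels`
#'   (see [channelMask2sd()]).
#' @param overlapFrac positivity threshold on the pixel overlap
#'   fraction (default 0.5).
#' @param rois ROI ids to classify; defaults to all ids in `labels`.
#'   An id with no pixels errors.
#' @return data.frame `roi_id`, `n_pixels`, `frac_th`, `frac_neun`,
#'   `nucleus_class`.
#' @export
classifyRois <- function(labels, thMask, neunMask, overlapFrac = 0.5,
                         rois = .roiIds(labels)) {
  if (!all(dim(labels) == dim(thMask)) ||
      !all(dim(labels) == dim(neunMask)))
    stop("mask dimensions differ from label mask")
  out <- do.call(rbind, lapply(rois, function(id) {
    px <- labels == id
    n <- sum(px)
    if (n == 0L) stop("ROI ", id, " has no pixels")
    fracTh <- sum(thMask[px]) / n
    fracNeun <- sum(neunMask[px]) / n
    data.frame(roi_id = id, n_pixels = n,
               frac_th = fracTh, frac_neun = fracNeun,
               stringsAsFactors = FALSE)
  }))
  out$nucleus_class <- paste0(
    ifelse(out$frac_th > overlapFrac, "TH+", "TH-"), "/",
    ifelse(out$frac_neun > overlapFrac, "NeuN+", "NeuN-"))
  out
}

#' Background-subtracted mean ROI intensity
#'
#' Mean signal intensity over each ROI's pixels minus the median of the
#' entire image (the background estimate); results may be negative.
#' Adding a constant to the whole image leaves the result unchanged.
#'
#' @param signal single-channel 2D numeric matrix.
#' @param labels integer ROI label matrix, same shape.
#' @param rois ROI ids to quantify; defaults to all ids present. A
#'   requested id absent from the mask errors.
#' @return data.frame `roi_id`, `n_pixels`, `mean_intensity_bgsub`.
#' @export
roiMeanBgsub <- function(signal, labels, rois = .roiIds(labels)) {
  if (!all(dim(signal) == dim(labels)))
    stop("signal and label mask dimensions differ")
  bg <- median(signal)
  out <- do.call(rbind, lapply(rois, function(id) {
    px <- labels == id
    n <- sum(px)
    if (n == 0L) stop("ROI ", id, " absent from label mask")
    data.frame(roi_id = id, n_pixels = n,
               mean_intensity_bgsub = mean(signal[px]) - bg,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Quantify a multi-channel nuclei image
#'
#' End-to-end ROI quantification: thresholds the TH and NeuN channels
#' at `k` SDs above background, classifies each ROI into a nucleus
#' class from the marker masks (never from the signal channel), and
#' reports the median-background-subtracted mean signal intensity per
#' ROI.
#'
#' @param stack rows x cols x channels array with dimnames on the
#'   channel axis including `th`, `neun` and `signal` (as produced by
#'   [genNucleiImage()]).
#' @param labels integer ROI label matrix.
#' @param k marker threshold in background SDs (default 2).
#' @param overlapFrac marker positivity threshold (default 0.5).
#' @return data.frame `roi_id`, `nucleus_class`, `channel`,
#'   `mean_intensity_bgsub`, `n_pixels`.
#' @export
quantifyRois <- function(stack, labels, k = 2, overlapFrac = 0.5) {
  chans <- dimnames(stack)[[3]]
  need <- c("th", "neun", "signal")
  if (is.null(chans) || !all(need %in% chans))
    stop("stack must carry channels th, neun, signal")
  thMask <- channelMask2sd(stack[, , "th"], k = k)
  neunMask <- channelMask2sd(stack[, , "neun"], k = k)
  classes <- classifyRois(labels, thMask, neunMask,
                          overlapFrac = overlapFrac)
  quant <- roiMeanBgsub(stack[, , "signal"], labels)
  data.frame(
    roi_id = quant$roi_id,
    nucleus_class = classes$nucleus_class[match(quant$roi_id,
                                                classes$roi_id)],
    channel = "signal",
    mean_intensity_bgsub = quant$mean_intensity_bgsub,
    n_pixels = quant$n_pixels,
    stringsAsFactors = FALSE
  )
}
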