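# Hue-channel Otsu segmentation of CK-IHC TMA cores.
#
# Pipeline: Gaussian smoothing -> edge-based tissue contour -> RGB-to-HSV hue
# -> Otsu threshold on the tissue-masked hue histogram -> class orientation by
# distance to a DAB-brown reference -> morphological repair -> TSR.

# Hue is measured in degrees [0, 360) and quantized to an integer scale
# 0..255 by round(deg * 255 / 360). All thresholds are reported on both
# scales.
HUE_LEVELS <- 256L

#' Segmentation parameters
#'
#' @param kernel_size Side of the square Gaussian smoothing kernel (odd).
#' @param sigma Gaussian sigma in pixels; by default derived from the kernel
#'   size as `0.3 * ((kernel_size - 1) / 2 - 1) + 0.8` (1.1 for the 5x5
#'   default).
#' @param edge_min Absolute floor on the gradient-magnitude edge threshold.
#' @param contour_brush Diameter of the box brush used to bridge the edge
#'   band before hole filling.
#' @param contour_trim Diameter of the disc brush of a final erosion that
#'   removes the blur skirt of the boundary (the edge band detected by the
#'   gradient extends a couple of pixels beyond the true contour because of
#'   the Gaussian pre-smoothing).
#' @param morph_kernel Side of the square structuring element for the
#'   closing/opening label repair.
#' @param morph_iterations Iterations of closing then opening.
#' @param brown_reference RGB triple of the DAB-brown reference used to
#'   orient the two Otsu classes.
#' @param stroma_reference RGB triple of the off-white stroma reference,
#'   used only when the hue histogram is degenerate.
#' @return A list of class `tsr_seg_config`.
#' @export
segmentation_config <- function(kernel_size = 5, sigma = NULL,
                                edge_min = 10, contour_brush = 5,
                                contour_trim = 7,
                                morph_kernel = 3, morph_iterations = 1,
                                brown_reference = c(150, 90, 40),
                                stroma_reference = c(225, 228, 238)) {
  if (kernel_size < 3 || kernel_size %% 2 == 0)
    stop_validation("kernel_size must be an odd integer >= 3")
  sigma <- sigma %||% (0.3 * ((kernel_size - 1) / 2 - 1) + 0.8)
  if (sigma <= 0) stop_validation("sigma must be positive")
  structure(list(kernel_size = kernel_size, sigma = sigma,
                 edge_min = edge_min, contour_brush = contour_brush,
                 contour_trim = contour_trim,
                 morph_kernel = morph_kernel,
                 morph_iterations = morph_iterations,
                 brown_reference = brown_reference,
                 stroma_reference = stroma_reference),
            class = "tsr_seg_config")
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(w, w)
  k / sum(k)
}

#' Gaussian pre-smoothing of an RGB image
#'
#' Convolves each channel with a discrete Gaussian kernel (replicated
#' boundary).
#'
#' @param image H x W x 3 numeric array, values 0..255.
#' @param config A [segmentation_config()].
#' @return Smoothed array of the same shape.
#' @export
smooth_image <- function(image, config = segmentation_config()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  k <- gaussian_kernel(config$kernel_size, config$sigma)
  out <- image
  for (ch in 1:3)
    out[, , ch] <- EBImage::filter2(image[, , ch], k, boundary = "replicate")
  # FFT convolution can overshoot the 8-bit range by numerical error
  pmin(pmax(out, 0), 255)
}

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Tissue mask from the core contour
#'
#' Finds the outline of the tissue core by edge detection on the smoothed
#' luminance (Sobel gradient magnitude thresholded at
#' `max(edge_min, 1.33 * median magnitude)`), bridges the edge band with a
#' box dilation, fills the enclosed region, erodes back, and keeps the
#' largest connected component. Everything outside the resulting contour is
#' background and excluded from analysis.
#'
#' @param image Smoothed H x W x 3 array.
#' @param config A [segmentation_config()].
#' @return Logical H x W matrix, `TRUE` on tissue. If no contour is found
#'   the mask is empty and carries `attr(, "warning") = "no_contour"`.
#' @export
tissue_mask <- function(image, config = segmentation_config()) {
  lum <- luminance(image)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(lum, sx, boundary = "replicate")
  gy <- EBImage::filter2(lum, t(sx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(config$edge_min, 1.33 * stats::median(mag))
  edges <- mag > thr
  if (!any(edges)) {
    mask <- matrix(FALSE, nrow(lum), ncol(lum))
    attr(mask, "warning") <- "no_contour"
    warning("no tissue contour found; returning empty mask",
            call. = FALSE)
    return(mask)
  }
  brush <- EBImage::makeBrush(config$contour_brush, shape = "box")
  closed <- EBImage::dilate(edges + 0, brush)
  filled <- EBImage::fillHull(closed)
  filled <- EBImage::erode(filled, brush)
  if (config$contour_trim > 1)
    filled <- EBImage::erode(
      filled, EBImage::makeBrush(config$contour_trim, shape = "disc"))
  labs <- EBImage::bwlabel(filled)
  if (max(labs) == 0) {
    mask <- matrix(FALSE, nrow(lum), ncol(lum))
    attr(mask, "warning") <- "no_contour"
    warning("no tissue contour found; returning empty mask",
            call. = FALSE)
    return(mask)
  }
  counts <- tabulate(labs[labs > 0])
  mask <- matrix(labs == which.max(counts), nrow(lum), ncol(lum))
  attr(mask, "edge_threshold") <- thr
  mask
}

#' Hue channel of an RGB image
#'
#' Converts RGB to HSV and returns the hue, quantized from degrees
#' `[0, 360)` to the integer scale 0..255 (`round(deg * 255 / 360)`).
#' Achromatic pixels (R = G = B) get hue 0 by convention.
#'
#' @param image H x W x 3 numeric array, values 0..255.
#' @return Integer H x W matrix of quantized hues, with the hue in degrees
#'   available as `attr(, "degrees")`.
#' @export
hue_channel <- function(image) {
  d <- dim(image)
  px <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  deg <- matrix(hsv[1, ] * 360, d[1], d[2])
  q <- matrix(as.integer(round(deg * 255 / 360)), d[1], d[2])
  attr(q, "degrees") <- deg
  q
}

#' Otsu threshold of a quantized histogram
#'
#' Exhaustively maximizes the between-class variance of the histogram of
#' `values` over all levels; ties are broken toward the lowest maximizing
#' level. The split is `values <= threshold` vs `values > threshold`.
#'
#' @param values Integer vector of quantized intensities in
#'   `0..(levels - 1)`, typically the tissue-masked hue pixels.
#' @param levels Number of histogram levels (256 for the hue scale).
#' @return Integer threshold with attributes `degenerate` (single distinct
#'   value) and `between_class_variance` (profile over levels).
#' @export
otsu_threshold <- function(values, levels = HUE_LEVELS) {
  if (length(values) < 1) stop_validation("otsu_threshold needs >= 1 pixel")
  values <- as.integer(values)
  if (any(values < 0 | values >= levels))
    stop_validation("values out of histogram range")
  counts <- tabulate(values + 1L, nbins = levels)
  if (sum(counts > 0) == 1) {
    thr <- which(counts > 0) - 1L
    attr(thr, "degenerate") <- TRUE
    return(thr)
  }
  p <- counts / sum(counts)
  lev <- seq_len(levels) - 1
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  thr <- as.integer(which.max(sb) - 1L)
  attr(thr, "degenerate") <- FALSE
  attr(thr, "between_class_variance") <- sb
  thr
}

#' Binary tumour/stroma classification of tissue pixels
#'
#' Splits tissue pixels at the Otsu hue threshold and orients the two
#' classes by colour: each class is assigned to the reference (DAB-brown
#' tumour or off-white stroma) its mean RGB is closer to (Euclidean).
#' In the regular case one class maps to each reference and the
#' brown-like class is labelled tumour (255). When both classes map to the
#' same reference — a core that is entirely stroma or entirely tumour, so
#' the Otsu split only divides noise — the whole tissue receives that
#' single label. Orientation is decided by colour, not by which side of
#' the threshold a class falls on, because hue wraps and the position of
#' DAB brown on the hue scale is a convention.
#'
#' @param image Smoothed RGB array (used for class mean colours).
#' @param hue Quantized hue matrix from [hue_channel()].
#' @param threshold Output of [otsu_threshold()].
#' @param mask Tissue mask.
#' @param config A [segmentation_config()].
#' @return Numeric H x W matrix with 255 on tumour, 0 elsewhere;
#'   `attr(, "orientation_flipped")` is `TRUE` when the above-threshold
#'   class was labelled tumour.
#' @export
classify_tissue <- function(image, hue, threshold, mask,
                            config = segmentation_config()) {
  labels <- matrix(0, nrow(hue), ncol(hue))
  mean_rgb <- function(sel) {
    vapply(1:3, function(ch) mean(image[, , ch][sel]), numeric(1))
  }
  cdist <- function(a, b) sqrt(sum((a - b)^2))
  if (isTRUE(attr(threshold, "degenerate"))) {
    m <- mean_rgb(mask)
    is_tumor <- cdist(m, config$brown_reference) <
      cdist(m, config$stroma_reference)
    if (is_tumor) labels[mask] <- 255
    attr(labels, "orientation_flipped") <- NA
    return(labels)
  }
  below <- mask & hue <= as.integer(threshold)
  above <- mask & hue > as.integer(threshold)
  if (!any(below) || !any(above)) {
    sel <- if (any(below)) below else above
    m <- mean_rgb(sel)
    if (cdist(m, config$brown_reference) <
        cdist(m, config$stroma_reference)) labels[sel] <- 255
    attr(labels, "orientation_flipped") <- NA
    return(labels)
  }
  is_brown <- function(sel) {
    m <- mean_rgb(sel)
    cdist(m, config$brown_reference) < cdist(m, config$stroma_reference)
  }
  brown_below <- is_brown(below); brown_above <- is_brown(above)
  if (brown_below == brown_above) {
    # both classes share one colour identity: single-class tissue
    if (brown_below) labels[mask] <- 255
    attr(labels, "orientation_flipped") <- NA
    return(labels)
  }
  labels[if (brown_below) below else above] <- 255
  attr(labels, "orientation_flipped") <- brown_above
  labels
}

#' Morphological repair of the tumour label image
#'
#' Closing (dilate then erode) fills localized holes up to the structuring
#' element size; opening (erode then dilate) removes isolated speckles below
#' it. Square k x k element, default 3 x 3, one iteration each.
#'
#' @param labels Binary label matrix (255/0 or logical).
#' @param config A [segmentation_config()].
#' @return Numeric matrix with values 255/0.
#' @export
morph_repair <- function(labels, config = segmentation_config()) {
  bin <- (labels > 0) + 0
  kern <- EBImage::makeBrush(config$morph_kernel, shape = "box")
  for (i in seq_len(config$morph_iterations)) {
    bin <- EBImage::closing(bin, kern)
    bin <- EBImage::opening(bin, kern)
  }
  out <- matrix(as.numeric(bin > 0) * 255, nrow(labels), ncol(labels))
  out
}

#' Tumour-stroma ratio of one core
#'
#' TSR = 100 * area_tumor / (area_tumor + area_stroma), with the areas in
#' pixels counted inside the tissue mask.
#'
#' @param labels Tumour label matrix (255 on tumour).
#' @param mask Tissue mask.
#' @param otsu_threshold,orientation_flipped Optional provenance carried
#'   into the result.
#' @return A list of class `tsr_segmentation` with `area_tissue`,
#'   `area_tumor`, `area_stroma`, `tsr` (percent), `otsu_threshold`,
#'   `otsu_threshold_degrees`, `orientation_flipped`.
#' @export
compute_tsr <- function(labels, mask, otsu_threshold = NA,
                        orientation_flipped = NA) {
  area_tissue <- sum(mask)
  if (area_tissue == 0)
    stop(errorCondition("empty tissue mask: TSR undefined",
                        class = c("tsr_empty_tissue", "error")))
  area_tumor <- sum(labels > 0 & mask)
  thr <- suppressWarnings(as.integer(otsu_threshold))
  structure(list(area_tissue = area_tissue, area_tumor = area_tumor,
                 area_stroma = area_tissue - area_tumor,
                 tsr = 100 * area_tumor / area_tissue,
                 otsu_threshold = thr,
                 otsu_threshold_degrees =
                   if (is.na(thr)) NA_real_ else thr * 360 / 255,
                 orientation_flipped = orientation_flipped),
            class = "tsr_segmentation")
}

#' @export
print.tsr_segmentation <- function(x, ...) {
  cat(sprintf(
    "TSR %.2f%% (tumor %d / tissue %d px; hue threshold %s)\n",
    x$tsr, x$area_tumor, x$area_tissue,
    ifelse(is.na(x$otsu_threshold), "NA", x$otsu_threshold)))
  invisible(x)
}

#' Segment one core image end to end
#'
#' Runs smoothing, tissue-contour masking, hue conversion, masked-histogram
#' Otsu thresholding, colour-oriented classification, morphological repair
#' and TSR computation.
#'
#' @param image H x W x 3 numeric array, values 0..255.
#' @param config A [segmentation_config()].
#' @return A `tsr_segmentation` (see [compute_tsr()]).
#' @export
segment_core <- function(image, config = segmentation_config()) {
  sm <- smooth_image(image, config)
  mask <- tissue_mask(sm, config)
  if (!any(mask))
    stop(errorCondition("empty tissue mask: TSR undefined",
                        class = c("tsr_empty_tissue", "error")))
  hue <- hue_channel(sm)
  thr <- otsu_threshold(hue[mask])
  labels <- classify_tissue(sm, hue, thr, mask, config)
  flipped <- attr(labels, "orientation_flipped")
  labels <- morph_repair(labels, config)
  compute_tsr(labels, mask, otsu_threshold = thr,
              orientation_flipped = flipped)
}

#' Aggregate per-core TSR values to one patient value
#'
#' With two cores per patient the one with the highest stroma proportion —
#' i.e. the minimum TSR — is recorded as the patient's value; a single core
#' is returned as-is.
#'
#' @param results List of `tsr_segmentation` objects (or numeric TSR
#'   values) for one patient; invalid entries (`NULL`/`NA`) are dropped.
#' @return Patient TSR percent, or `NA_real_` (with a warning) when no
#'   valid core remains.
#' @export
aggregate_patient <- function(results) {
  tsr <- vapply(results, function(r) {
    if (is.null(r)) return(NA_real_)
    if (inherits(r, "tsr_segmentation")) r$tsr else as.numeric(r)
  }, numeric(1))
  tsr <- tsr[!is.na(tsr)]
  if (length(tsr) == 0) {
    warning("no valid core for patient; excluded", call. = FALSE)
    return(NA_real_)
  }
  min(tsr)
}
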