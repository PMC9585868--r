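#' Specification for a synthetic TMA core image
#'
#' Describes a circular tissue core on a white background, with DAB-brown
#' tumour regions and counterstained off-white stroma. The defaults mimic a
#' cytokeratin-IHC TMA core: tumour epithelium stains brown
#' (RGB 150,90,40), stroma carries a faint hematoxylin tint
#' (RGB 225,228,238) so that tumour and stroma occupy well separated
#' positions on the hue circle (about 27 and 226 degrees), and the slide
#' background is white.
#'
#' @param width,height Image size in pixels.
#' @param core_radius Core radius in pixels; the core must fit in the frame.
#' @param tumor_fraction_target Desired tumour area fraction of the core,
#'   in `[0, 1]`.
#' @param n_blobs Number of Gaussian bumps forming the tumour region.
#' @param blob_scale Characteristic bump radius in pixels.
#' @param tumor_color,stroma_color,background_color RGB triples in 0..255.
#' @param noise_sd Standard deviation of per-channel Gaussian colour noise,
#'   in 8-bit intensity units.
#' @param seed Integer seed; fixed seed gives a bit-identical image.
#' @return An object of class `tsr_image_spec`.
#' @seealso [render_core()]
#' @export
image_spec <- function(width = 256, height = 256, core_radius = 100,
                       tumor_fraction_target = 0.5, n_blobs = 6,
                       blob_scale = 25,
                       tumor_color = c(150, 90, 40),
                       stroma_color = c(225, 228, 238),
                       background_color = c(255, 255, 255),
                       noise_sd = 8, seed = NULL) {
  if (tumor_fraction_target < 0 || tumor_fraction_target > 1)
    stop_validation("tumor_fraction_target must be in [0, 1]")
  if (width < 1 || height < 1)
    stop_validation("image dimensions must be positive")
  if (core_radius <= 0 || 2 * core_radius > min(width, height))
    stop_validation("core must fit inside the image")
  for (col in list(tumor_color, stroma_color, background_color))
    if (length(col) != 3 || any(col < 0) || any(col > 255))
      stop_validation("colors must be RGB triples in 0..255")
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  if (n_blobs < 1 && tumor_fraction_target > 0 && tumor_fraction_target < 1)
    stop_validation("tumor_fraction_target in (0,1) requires n_blobs >= 1")
  structure(list(width = width, height = height, core_radius = core_radius,
                 tumor_fraction_target = tumor_fraction_target,
                 n_blobs = n_blobs, blob_scale = blob_scale,
                 tumor_color = tumor_color, stroma_color = stroma_color,
                 background_color = background_color,
                 noise_sd = noise_sd, seed = seed),
            class = "tsr_image_spec")
}

#' Render a synthetic TMA core with known tumour fraction
#'
#' Draws a filled disc of tissue on the background and places tumour regions
#' inside it as the upper level set of a random field (a sum of Gaussian
#' bumps, i.e. metaballs). The level is chosen as the empirical quantile of
#' the field over disc pixels, so the realized tumour fraction matches the
#' target up to pixel quantization. Per-channel Gaussian noise is added and
#' the result clipped to 8-bit range.
#'
#' @param spec An [image_spec()].
#' @return A list of class `tsr_core_render` with elements
#'   `image` (H x W x 3 array, 0..255), `truth` (realized tumour fraction,
#'   equal to `sum(mask) / sum(disc)`), `mask` (logical ground-truth tumour
#'   mask) and `disc` (logical core mask).
#' @export
render_core <- function(spec) {
  stopifnot(inherits(spec, "tsr_image_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; r <- spec$core_radius
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    xg <- matrix(rep(seq_len(w), each = h), h, w)
    yg <- matrix(rep(seq_len(h), times = w), h, w)
    disc <- (xg - cx)^2 + (yg - cy)^2 <= r^2

    tgt <- spec$tumor_fraction_target
    if (tgt <= 0) {
      mask <- matrix(FALSE, h, w)
    } else if (tgt >= 1) {
      mask <- disc
    } else {
      field <- matrix(0, h, w)
      for (b in seq_len(spec$n_blobs)) {
        rad <- r * sqrt(stats::runif(1)) * 0.95
        ang <- stats::runif(1, 0, 2 * pi)
        bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
        s <- spec$blob_scale * stats::runif(1, 0.6, 1.4)
        field <- field + exp(-((xg - bx)^2 + (yg - by)^2) / (2 * s^2))
      }
      q <- stats::quantile(field[disc], probs = 1 - tgt, type = 1,
                           names = FALSE)
      mask <- disc & field > q
    }
    truth <- sum(mask) / sum(disc)
    if (abs(truth - tgt) > 0.05)
      stop("unreachable tumor_fraction_target ", tgt,
           " (realized ", signif(truth, 3),
           "); increase n_blobs or blob_scale")

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_color[ch], h, w)
      plane[disc] <- spec$stroma_color[ch]
      plane[mask] <- spec$tumor_color[ch]
      if (spec$noise_sd > 0)
        plane <- plane + stats::rnorm(h * w, sd = spec$noise_sd)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    structure(list(image = img, truth = truth, mask = mask, disc = disc,
                   spec = spec),
              class = "tsr_core_render")
  })
}

#' Write a rendered core as a PNG named `<patient_id>_core<k>.png`
#'
#' @param render A `tsr_core_render`.
#' @param patient_id Patient identifier used in the file name.
#' @param core_index Core index, 1 or 2.
#' @param dir Output directory (created if missing).
#' @return The file path, invisibly.
#' @export
write_core_png <- function(render, patient_id, core_index, dir) {
  stopifnot(inherits(render, "tsr_core_render"), core_index %in% c(1, 2))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_core%d.png", patient_id, core_index))
  png::writePNG(render$image / 255, target = path)
  invisible(path)
}

#' Read an RGB core image from PNG or TIFF
#'
#' @param path Image path; `.png`, `.tif` or `.tiff`.
#' @return Numeric H x W x 3 array with values in 0..255.
#' @export
read_core_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}
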