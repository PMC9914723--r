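#' Filter parameters for the pre-processing stage
#'
#' All operator parameters are configurable and echoed into run reports;
#' the defaults are: 3x3 median window, CLAHE clip 0.01 (fraction of tile
#' pixels per histogram bin) on an 8x8 tile grid, unsharp-mask Gaussian
#' sigma 2 with amount 1, Otsu label threshold, and a disc of radius 5 for
#' the morphological opening.
#'
#' @param median_kernel odd median window side (pixels).
#' @param clahe_clip relative clip limit (> 0).
#' @param clahe_tiles tile grid `c(nx, ny)`.
#' @param usm_radius Gaussian sigma of the unsharp mask (pixels).
#' @param usm_amount unsharp-mask weight (>= 0).
#' @param label_threshold binarization intensity for label removal, or
#'   `NULL` for Otsu's method.
#' @param morph_radius structuring-element radius for the opening (pixels).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(median_kernel = 3L, clahe_clip = 0.01,
                          clahe_tiles = c(8L, 8L), usm_radius = 2.0,
                          usm_amount = 1.0, label_threshold = NULL,
                          morph_radius = 5L) {
  if (median_kernel %% 2 != 1 || median_kernel < 1)
    stop("median_kernel must be odd and >= 1", call. = FALSE)
  stopifnot(clahe_clip > 0, usm_radius > 0, usm_amount >= 0,
            morph_radius >= 1, length(clahe_tiles) == 2)
  structure(list(median_kernel = as.integer(median_kernel),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 usm_radius = usm_radius, usm_amount = usm_amount,
                 label_threshold = label_threshold,
                 morph_radius = as.integer(morph_radius)),
            class = "filter_params")
}

# pad a matrix by symmetric reflection (edge row/col repeated)
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(r:1, nr), seq_len(nr), nr + 1 - pmin(1:r, nr))
  ci <- c(pmin(r:1, nc), seq_len(nc), nc + 1 - pmin(1:r, nc))
  m[ri, ci, drop = FALSE]
}

crop_pad <- function(m, r, nr, nc) m[r + seq_len(nr), r + seq_len(nc),
                                     drop = FALSE]

#' Median filter
#'
#' Each pixel is replaced by the median of its `kernel` x `kernel`
#' neighbourhood; edges are handled by reflection padding.
#'
#' @param img a [gray_image()].
#' @param kernel odd window side.
#' @return A [gray_image()] of the same shape; its range is contained in
#'   the input's range.
#' @export
median_filter <- function(img, kernel = 3L) {
  if (kernel %% 2 != 1 || kernel < 1)
    stop("median kernel must be odd", call. = FALSE)
  img <- gray_image(img)
  if (kernel == 1) return(img)
  r <- (kernel - 1L) / 2L
  padded <- reflect_pad(as_pixel_matrix(img), r) / 255
  out <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(padded), r))
  gray_image(round(crop_pad(out, r, nrow(img), ncol(img)) * 255))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipped histograms, redistributed
#' excess and bilinear interpolation between tile mappings. `clip` is the
#' relative clip limit: the fraction of a tile's pixels a single histogram
#' bin may hold. A constant image is returned unchanged (no contrast to
#' create).
#'
#' @param img a [gray_image()].
#' @param clip relative clip limit (> 0).
#' @param tiles tile grid `c(nx, ny)`.
#' @return A [gray_image()] with intensities in \[0, 255\].
#' @export
clahe_enhance <- function(img, clip = 0.01, tiles = c(8L, 8L)) {
  img <- gray_image(img)
  stopifnot(clip > 0)
  if (tiles[1] > ncol(img) || tiles[2] > nrow(img))
    stop("tile grid larger than image", call. = FALSE)
  m <- as_pixel_matrix(img)
  if (diff(range(m)) == 0) return(img)
  bins <- 256L
  out <- EBImage::imageData(EBImage::clahe(
    EBImage::Image(m / 255), nx = tiles[1], ny = tiles[2], bins = bins,
    limit = clip * bins, keep.range = FALSE))
  gray_image(pmin(pmax(round(out * 255), 0), 255))
}

# Gaussian blur with reflection padding (separable kernel via filter2)
gaussian_blur <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  k <- min(k, 2L * min(dim(m)) - 1L)
  if (k %% 2 == 0) k <- k - 1L
  r <- (k - 1L) / 2L
  padded <- reflect_pad(m, r)
  brush <- EBImage::makeBrush(k, "Gaussian", sigma = sigma)
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(padded), brush,
                                             boundary = "replicate"))
  crop_pad(out, r, nrow(m), ncol(m))
}

#' Unsharp masking
#'
#' Sharpens by adding back the detail removed by a Gaussian blur:
#' `out = clip(img + amount * (img - blur(img, radius)), 0, 255)`.
#' `amount = 0` is the identity.
#'
#' @param img a [gray_image()].
#' @param radius Gaussian sigma of the blur (pixels).
#' @param amount weight of the detail layer (>= 0).
#' @return A [gray_image()].
#' @export
unsharp_mask <- function(img, radius = 2.0, amount = 1.0) {
  stopifnot(radius > 0, amount >= 0)
  img <- gray_image(img)
  if (amount == 0) return(img)
  m <- as_pixel_matrix(img)
  out <- m + amount * (m - gaussian_blur(m, radius))
  gray_image(pmin(pmax(round(out), 0), 255))
}

#' Remove the label artifact and keep the breast region
#'
#' Binarizes the image (Otsu's threshold unless `label_threshold` is set),
#' applies a morphological opening (erosion then dilation with a disc of
#' `morph_radius`), keeps the largest connected foreground component as the
#' breast mask, and zeroes everything outside it — eliminating the bright
#' label rectangle and stray marks, which are disconnected from the breast.
#'
#' @param img a [gray_image()].
#' @param p a [filter_params()].
#' @return `list(image, breast_mask)`: the masked image and the 0/1 breast
#'   mask.
#' @export
remove_label <- function(img, p = filter_params()) {
  img <- gray_image(img)
  m <- as_pixel_matrix(img)
  thr <- p$label_threshold
  if (is.null(thr)) {
    if (diff(range(m)) == 0)
      stop("no breast region found (constant image)", call. = FALSE)
    thr <- EBImage::otsu(EBImage::Image(m / 255)) * 255
  }
  bin <- (m > thr) * 1
  brush <- EBImage::makeBrush(2L * p$morph_radius + 1L, "disc")
  opened <- EBImage::imageData(EBImage::opening(EBImage::Image(bin), brush))
  if (sum(opened) == 0)
    stop("no breast region found", call. = FALSE)
  labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(opened)))
  counts <- tabulate(labs[labs > 0])
  keep <- which.max(counts)
  mask <- (labs == keep) * 1L
  list(image = gray_image(m * mask), breast_mask = mask)
}

#' The five pre-processing combinations
#'
#' @return Character vector of the legal combination names, in canonical
#'   order: `CLAHE`, `MF_CLAHE`, `MF_USM`, `CLAHE_USM`, `MF_CLAHE_USM`.
#' @export
preproc_combos <- function()
  c("CLAHE", "MF_CLAHE", "MF_USM", "CLAHE_USM", "MF_CLAHE_USM")

#' Apply a pre-processing combination
#'
#' Operators run in the order the combination name lists them (median
#' filter first, CLAHE second, unsharp mask last when present). The image
#' is assumed to have had its label removed already.
#'
#' @param img a [gray_image()].
#' @param combo one of [preproc_combos()] (case-insensitive).
#' @param p a [filter_params()].
#' @return A [gray_image()].
#' @export
apply_combo <- function(img, combo, p = filter_params()) {
  combo <- toupper(combo)
  if (!combo %in% preproc_combos())
    stop("unknown pre-processing combination: ", combo, call. = FALSE)
  steps <- strsplit(combo, "_")[[1]]
  out <- gray_image(img)
  for (s in steps) {
    out <- switch(s,
      MF = median_filter(out, p$median_kernel),
      CLAHE = clahe_enhance(out, p$clahe_clip, p$clahe_tiles),
      USM = unsharp_mask(out, p$usm_radius, p$usm_amount))
  }
  out
}
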