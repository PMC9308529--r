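# Conversion of solved temperature fields into the grayscale thermal images
# used for segmentation: additive Gaussian noise in temperature space,
# min-max normalization to [0, 1], and a center crop to the network input
# size (default 96 x 96).

#' Add Gaussian noise to a temperature field
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `level * reference scale` to every non-background pixel. The reference
#' scale is, by default, the dynamic range (max - min) of the non-background
#' temperatures; `reference = "mean"` uses their mean instead. Background
#' pixels are left untouched. Deterministic for a fixed seed; the global RNG
#' state is preserved.
#'
#' @param temps numeric temperature matrix, degC.
#' @param level noise level as a fraction of the reference scale (>= 0);
#'   0.05 reproduces "5% Gaussian noise".
#' @param seed integer RNG seed.
#' @param background optional logical matrix of background pixels (excluded
#'   from both the reference scale and the noise); `NULL` treats every pixel
#'   as tissue.
#' @param reference `"range"` (default) or `"mean"`.
#' @return Noised temperature matrix.
#' @export
addGaussianNoise <- function(temps, level = 0.05, seed = 1,
                             background = NULL,
                             reference = c("range", "mean")) {
  reference <- match.arg(reference)
  if (!is.finite(level) || level < 0) stop("noise level must be >= 0")
  if (level == 0) return(temps)
  if (is.null(background))
    background <- matrix(FALSE, nrow(temps), ncol(temps))
  stopifnot(identical(dim(background), dim(temps)))
  vals <- temps[!background]
  scale <- switch(reference,
                  range = diff(range(vals)),
                  mean = mean(vals))
  noise <- withSeed(seed, rnorm(sum(!background), mean = 0,
                                sd = level * scale))
  out <- temps
  out[!background] <- out[!background] + noise
  out
}

#' Convert a temperature grid to a normalized grayscale thermal image
#'
#' Min-max normalizes all pixels to [0, 1] and records the source (min, max)
#' so the temperatures can be recovered with [fromGrayscale()]. A constant
#' field cannot be normalized; it yields an all-zero image with a warning.
#'
#' @param temps numeric temperature matrix (degC) or a
#'   [TemperatureField-class].
#' @param mask optional binary lesion ground-truth matrix carried alongside.
#' @param seed optional noise seed recorded for provenance.
#' @return A [ThermalImage-class].
#' @export
toGrayscale <- function(temps, mask = NULL, seed = NA) {
  if (is(temps, "TemperatureField")) temps <- tempMatrix(temps)
  lo <- min(temps); hi <- max(temps)
  if (hi == lo) {
    warning("constant temperature field: degenerate normalization, image is all zero")
    px <- matrix(0, nrow(temps), ncol(temps))
  } else {
    px <- (temps - lo) / (hi - lo)
  }
  ThermalImage(px, sourceRange = c(lo, hi), mask = mask, seed = seed)
}

#' Recover temperatures from a normalized thermal image
#'
#' @param image a [ThermalImage-class].
#' @return Temperature matrix reconstructed from the stored source range.
#' @export
fromGrayscale <- function(image) {
  stopifnot(is(image, "ThermalImage"))
  rg <- sourceRange(image)
  pixelMatrix(image) * (rg[2] - rg[1]) + rg[1]
}

# crop index window: drop floor(excess/2) on the low side, remainder high
cropWindow <- function(src, target) {
  if (target > src) stop("crop target exceeds source size")
  lo <- (src - target) %/% 2
  seq.int(lo + 1L, lo + target)
}

#' Center-crop an image (and its mask) to a target size
#'
#' Removes `floor((src - target)/2)` pixels from the low side and the
#' remainder from the high side of each axis, so a 96 x 110 slice cropped to
#' 96 x 96 loses 7 columns on each side.
#'
#' @param image a [ThermalImage-class] or a plain matrix.
#' @param target_rows,target_cols target size; must not exceed the source.
#' @return Cropped object of the same type; a [ThermalImage-class]'s mask is
#'   cropped identically.
#' @export
centerCrop <- function(image, target_rows = 96, target_cols = 96) {
  if (is(image, "ThermalImage")) {
    px <- pixelMatrix(image)
    ri <- cropWindow(nrow(px), target_rows)
    cj <- cropWindow(ncol(px), target_cols)
    m <- imageMask(image)
    return(ThermalImage(px[ri, cj, drop = FALSE], sourceRange(image),
                        mask = if (is.null(m)) NULL else
                          m[ri, cj, drop = FALSE],
                        seed = image@seed))
  }
  ri <- cropWindow(nrow(image), target_rows)
  cj <- cropWindow(ncol(image), target_cols)
  image[ri, cj, drop = FALSE]
}

#' Full field-to-image rendering pipeline
#'
#' Noise (in temperature space, over non-background pixels), min-max
#' normalization, then center crop — the conversion applied to every solved
#' slice before segmentation. `order = "normalize_first"` instead adds the
#' noise after grayscale conversion (scaled by the [0,1] range, i.e. by 1).
#'
#' @param field a [TemperatureField-class] or temperature matrix.
#' @param map the [TissueLabelMap-class] the field was solved on (provides
#'   the background mask and lesion ground truth).
#' @param noise noise level fraction, default 0.05.
#' @param seed noise RNG seed.
#' @param crop target (rows, cols) after cropping, default c(96, 96).
#' @param order `"noise_first"` (default: noise in temperature space) or
#'   `"normalize_first"`.
#' @param maskClass which ground-truth mask to attach: `"penumbra"`
#'   (default, the segmentation target), `"core"`, or `"lesion"` (union).
#' @return A [ThermalImage-class] with the cropped lesion mask attached.
#' @export
renderThermalImage <- function(field, map, noise = 0.05, seed = 1,
                               crop = c(96, 96),
                               order = c("noise_first", "normalize_first"),
                               maskClass = c("penumbra", "core", "lesion")) {
  order <- match.arg(order)
  maskClass <- match.arg(maskClass)
  temps <- if (is(field, "TemperatureField")) tempMatrix(field) else field
  bg <- labelMatrix(map) == labelLegend(map)[["background"]]
  mask <- lesionMasks(map)[[maskClass]]
  if (order == "noise_first") {
    temps <- addGaussianNoise(temps, noise, seed, background = bg)
    img <- toGrayscale(temps, mask = mask, seed = seed)
  } else {
    img <- toGrayscale(temps, mask = mask, seed = seed)
    px <- addGaussianNoise(pixelMatrix(img), noise, seed, background = bg)
    img <- ThermalImage(pmin(pmax(px, 0), 1), sourceRange(img),
                        mask = mask, seed = seed)
  }
  centerCrop(img, crop[1], crop[2])
}
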