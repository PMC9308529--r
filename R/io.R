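# Readers and writers for the small set of on-disk formats: 8-bit grayscale
# PNG (label maps, thermal images, binary masks), NIfTI (temperature fields
# and label volumes), YAML property configs and CSV manifests.

#' Write / read a tissue label map as 8-bit grayscale PNG
#'
#' Label integers are stored directly as 8-bit pixel values.
#'
#' @param map a [TissueLabelMap-class].
#' @param path output / input PNG path.
#' @param spacing,legend metadata to attach on read (PNG carries neither).
#' @return `writeLabelMapPNG` returns `path` invisibly; `readLabelMapPNG`
#'   returns a [TissueLabelMap-class].
#' @export
writeLabelMapPNG <- function(map, path) {
  stopifnot(is(map, "TissueLabelMap"))
  png::writePNG(labelMatrix(map) / 255, path)
  invisible(path)
}

#' @rdname writeLabelMapPNG
#' @export
readLabelMapPNG <- function(path, spacing = 2, legend = tissueLegend()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  TissueLabelMap(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)),
                 spacing = spacing, legend = legend)
}

#' Write / read a thermal image (and optional mask) as 8-bit grayscale PNG
#'
#' The [0, 1] float representation is canonical; the 8-bit export rounds
#' half up from `pixels * 255`.
#'
#' @param image a [ThermalImage-class].
#' @param path output PNG path.
#' @param maskPath optional path for the binary mask PNG.
#' @return `path`, invisibly.
#' @export
writeThermalImagePNG <- function(image, path, maskPath = NULL) {
  stopifnot(is(image, "ThermalImage"))
  px <- floor(pixelMatrix(image) * 255 + 0.5) / 255
  png::writePNG(px, path)
  m <- imageMask(image)
  if (!is.null(maskPath)) {
    if (is.null(m)) stop("image carries no mask to write")
    png::writePNG(m, maskPath)
  }
  invisible(path)
}

#' @rdname writeThermalImagePNG
#' @export
readMaskPNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  (px >= 0.5) + 0
}

#' Write / read a temperature field as NIfTI
#'
#' Stored as a single-slice 32-bit float volume with the pixel spacing in
#' the header.
#'
#' @param field a [TemperatureField-class].
#' @param path output / input `.nii` (or `.nii.gz`) path.
#' @return `writeTemperatureNIfTI` returns `path` invisibly;
#'   `readTemperatureNIfTI` returns the temperature matrix with the spacing
#'   as attribute `spacing`.
#' @export
writeTemperatureNIfTI <- function(field, path) {
  stopifnot(is(field, "TemperatureField"))
  img <- RNifti::asNifti(tempMatrix(field))
  RNifti::pixdim(img) <- c(spacing(field), spacing(field))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname writeTemperatureNIfTI
#' @export
readTemperatureNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  m <- as.matrix(img[, , drop = TRUE])
  attr(m, "spacing") <- RNifti::pixdim(img)[1]
  m
}

#' Write a label volume (one slice per map) as NIfTI
#'
#' @param maps list of [TissueLabelMap-class] objects of one shape.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelVolumeNIfTI <- function(maps, path) {
  if (is(maps, "TissueLabelMap")) maps <- list(maps)
  arr <- array(0L, c(dim(labelMatrix(maps[[1]])), length(maps)))
  for (i in seq_along(maps)) arr[, , i] <- labelMatrix(maps[[i]])
  sp <- spacing(maps[[1]])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, sp, sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a dataset manifest as CSV
#'
#' @param manifest a [buildManifest()] data.frame.
#' @param path CSV path.
#' @return `writeManifestCSV` returns `path` invisibly; `readManifestCSV`
#'   the manifest data.frame.
#' @export
writeManifestCSV <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifestCSV
#' @export
readManifestCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a metric report as JSON
#'
#' @param report a list or data.frame of metric values.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeMetricReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
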