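# Synthetic brain phantoms: an elliptical brain (WM interior, GM rim, CSF
# band) inside a fixed-temperature background border, with an optional
# concentric stroke lesion (infarct core disk + penumbra shell) in deep
# white matter. The anatomy is schematic; it exists to exercise the bioheat
# solver and the imaging pipeline with all tissue classes present at the
# 96 x 110 pixel / 2 mm slice geometry.

#' Stroke lesion geometry and severity specification
#'
#' A concentric acute ischemic lesion: a circular infarct core of diameter
#' `core_diameter` (mm) surrounded by a penumbra shell of thickness
#' `penumbra_thickness` (mm). The dimensionless factors scale white-matter
#' blood perfusion and metabolic heat generation in each compartment;
#' defaults are the acute-stroke model values: penumbra keeps 40% perfusion
#' and 70% metabolism, the core keeps 20% perfusion and no metabolism.
#'
#' @param center lesion center as (row, col) pixel coordinates (1-based), or
#'   `NULL` to use the phantom's brain-ellipse center.
#' @param core_diameter infarct core diameter, mm (> 0).
#' @param penumbra_thickness penumbra shell thickness, mm (>= 0).
#' @param perfusion_factor_penumbra,metabolism_factor_penumbra fractions in
#'   [0, 1] applied to WM wb and qm inside the penumbra.
#' @param perfusion_factor_core,metabolism_factor_core fractions in [0, 1]
#'   applied inside the infarct core.
#' @return A `LesionSpec` list.
#' @export
lesionSpec <- function(center = NULL, core_diameter = 10,
                       penumbra_thickness = 5,
                       perfusion_factor_penumbra = 0.4,
                       metabolism_factor_penumbra = 0.7,
                       perfusion_factor_core = 0.2,
                       metabolism_factor_core = 0) {
  if (!is.finite(core_diameter) || core_diameter <= 0)
    stop("core_diameter must be positive (mm)")
  if (!is.finite(penumbra_thickness) || penumbra_thickness < 0)
    stop("penumbra_thickness must be non-negative (mm)")
  fac <- c(perfusion_factor_penumbra, metabolism_factor_penumbra,
           perfusion_factor_core, metabolism_factor_core)
  if (any(!is.finite(fac)) || any(fac < 0) || any(fac > 1))
    stop("all reduction factors must lie in [0, 1]")
  structure(list(center = center, core_diameter = core_diameter,
                 penumbra_thickness = penumbra_thickness,
                 perfusion_factor_penumbra = perfusion_factor_penumbra,
                 metabolism_factor_penumbra = metabolism_factor_penumbra,
                 perfusion_factor_core = perfusion_factor_core,
                 metabolism_factor_core = metabolism_factor_core),
            class = "LesionSpec")
}

# evaluate a function with a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# normalized elliptical radius of every pixel for a given geometry
phantomRadius <- function(rows, cols, geom) {
  i <- matrix(seq_len(rows), rows, cols)
  j <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  sqrt(((i - geom$ci) / geom$a)^2 + ((j - geom$cj) / geom$b)^2)
}

#' Generate a synthetic brain phantom label map
#'
#' Rasterizes an elliptical brain centered in a `rows` x `cols` grid:
#' white matter for normalized elliptical radius r <= `wmFrac`, a gray-matter
#' rim for r in (`wmFrac`, `gmFrac`], a CSF band for r in (`gmFrac`, 1], and
#' background outside. The ellipse semi-axes leave at least a 1-pixel
#' background border on every side. The seed jitters the ellipse size and
#' center slightly (within a pixel) so different subjects differ; the result
#' is deterministic for a fixed seed. The construction parameters are stored
#' in the `geometry` slot.
#'
#' @param rows,cols grid size in pixels; both must be >= 16.
#' @param spacing pixel size in mm (isotropic), default 2.
#' @param seed integer RNG seed for the geometric jitter.
#' @param wmFrac,gmFrac outer normalized radii of the WM core and GM rim.
#' @return A [TissueLabelMap-class] with geometry metadata.
#' @export
#' @examples
#' ph <- generateBrainPhantom(96, 110, spacing = 2, seed = 1)
#' table(labelMatrix(ph))
generateBrainPhantom <- function(rows, cols, spacing = 2, seed = 1,
                                 wmFrac = 0.80, gmFrac = 0.92) {
  if (rows < 16 || cols < 16)
    stop("grid too small to contain the brain ellipse (need >= 16 pixels per side)")
  stopifnot(wmFrac > 0, wmFrac < gmFrac, gmFrac < 1)
  jit <- withSeed(seed, runif(3, min = c(0.96, -0.5, -0.5),
                              max = c(1.00, 0.5, 0.5)))
  geom <- list(
    ci = (rows + 1) / 2 + jit[2],
    cj = (cols + 1) / 2 + jit[3],
    a = (rows / 2 - 2) * jit[1],
    b = (cols / 2 - 2) * jit[1],
    wmFrac = wmFrac, gmFrac = gmFrac)
  r <- phantomRadius(rows, cols, geom)
  legend <- tissueLegend()
  lab <- matrix(legend[["background"]], rows, cols)
  lab[r <= 1] <- legend[["CSF"]]
  lab[r <= gmFrac] <- legend[["GM"]]
  lab[r <= wmFrac] <- legend[["WM"]]
  TissueLabelMap(lab, spacing = spacing, geometry = geom)
}

#' Embed a concentric stroke lesion into a phantom
#'
#' Relabels pixels whose center-to-center Euclidean distance (in mm) from the
#' lesion center is at most `core_diameter/2` as infarct core, and pixels in
#' the half-open shell (core radius, core radius + penumbra thickness] as
#' penumbra. All other labels are unchanged; background and CSF are never
#' relabelled. The operation is idempotent: previously embedded lesion pixels
#' of the same spec are relabelled identically.
#'
#' @param map a [TissueLabelMap-class].
#' @param lesion a [lesionSpec()]; a `NULL` center defaults to the phantom's
#'   ellipse center (rounded to a pixel).
#' @return The relabelled [TissueLabelMap-class]. Binary ground-truth masks
#'   are available from [lesionMasks()].
#' @export
embedLesion <- function(map, lesion = lesionSpec()) {
  stopifnot(is(map, "TissueLabelMap"), inherits(lesion, "LesionSpec"))
  lab <- labelMatrix(map)
  legend <- labelLegend(map)
  center <- lesion$center
  if (is.null(center)) {
    if (is.null(map@geometry$ci))
      stop("lesion center not given and map has no phantom geometry")
    center <- c(round(map@geometry$ci), round(map@geometry$cj))
  }
  ci <- center[1]; cj <- center[2]
  if (ci < 1 || ci > nrow(lab) || cj < 1 || cj > ncol(lab))
    stop("lesion center outside the grid")
  wmLike <- legend[c("WM", "penumbra", "infarct_core")]
  if (!lab[ci, cj] %in% wmLike)
    stop("lesion center must lie on a white-matter pixel")
  i <- matrix(seq_len(nrow(lab)), nrow(lab), ncol(lab))
  j <- matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE)
  d <- spacing(map) * sqrt((i - ci)^2 + (j - cj)^2)
  rCore <- lesion$core_diameter / 2
  core <- d <= rCore
  pen <- d > rCore & d <= rCore + lesion$penumbra_thickness
  allowed <- legend[c("GM", "WM", "penumbra", "infarct_core")]
  if (any(!lab[core | pen] %in% allowed))
    stop("lesion exceeds the brain extent (disk covers CSF or background)")
  lab[pen] <- legend[["penumbra"]]
  lab[core] <- legend[["infarct_core"]]
  TissueLabelMap(lab, spacing = spacing(map), legend = legend,
                 geometry = map@geometry)
}

#' Binary lesion ground-truth masks of a label map
#'
#' @param map a [TissueLabelMap-class].
#' @return List of 0/1 matrices `core`, `penumbra` and `lesion`
#'   (their union).
#' @export
lesionMasks <- function(map) {
  stopifnot(is(map, "TissueLabelMap"))
  lab <- labelMatrix(map)
  legend <- labelLegend(map)
  core <- (lab == legend[["infarct_core"]]) + 0
  pen <- (lab == legend[["penumbra"]]) + 0
  list(core = core, penumbra = pen, lesion = pmax(core, pen))
}
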