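#' Thermophysical properties of a tissue
#'
#' Bundles the five scalars that enter the Pennes bioheat equation for one
#' tissue class: thermal conductivity k (W/(m.degC)), density rho (kg/m^3),
#' specific heat cp (J/(kg.degC)), metabolic heat generation qm (W/m^3) and
#' blood perfusion rate wb (ml of blood per second per ml of tissue).
#'
#' @param name tissue label (character).
#' @param k thermal conductivity, W/(m.degC); must be > 0.
#' @param rho density, kg/m^3; must be > 0.
#' @param cp specific heat, J/(kg.degC); must be > 0.
#' @param qm metabolic heat generation, W/m^3; must be >= 0.
#' @param wb blood perfusion rate, ml/(s.ml); must be >= 0.
#' @return A `TissueProperties` list.
#' @export
#' @examples
#' tissueProperties("WM", k = 0.503, rho = 1027.4, cp = 3600,
#'                  qm = 4517.9, wb = 0.0036956)
tissueProperties <- function(name, k, rho, cp, qm, wb) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  if (!is.finite(cp) || cp <= 0) stop("cp must be positive")
  if (!is.finite(qm) || qm < 0) stop("qm must be non-negative")
  if (!is.finite(wb) || wb < 0) stop("wb must be non-negative")
  structure(list(name = name, k = k, rho = rho, cp = cp, qm = qm, wb = wb),
            class = "TissueProperties")
}

#' @export
print.TissueProperties <- function(x, ...) {
  cat(sprintf(
    "TissueProperties[%s]: k=%g W/(m.degC), rho=%g kg/m3, cp=%g J/(kg.degC), qm=%g W/m3, wb=%g ml/(s.ml)\n",
    x$name, x$k, x$rho, x$cp, x$qm, x$wb))
  invisible(x)
}

#' Blood constants for the perfusion term
#'
#' Arterial blood enters the bioheat equation through its density rho_b,
#' specific heat cp_b and temperature t_a; perfused tissue is pulled toward
#' t_a at rate wb * rho_b * cp_b. The blood density and specific heat default
#' to standard literature values (1050 kg/m^3, 3800 J/(kg.degC)) and can be
#' overridden; the arterial temperature defaults to 36.7 degC.
#'
#' @param rho_b blood density, kg/m^3.
#' @param cp_b blood specific heat, J/(kg.degC).
#' @param t_a arterial blood temperature, degC; must lie in (30, 42).
#' @return A `BloodProperties` list.
#' @export
bloodProperties <- function(rho_b = 1050, cp_b = 3800, t_a = 36.7) {
  if (!is.finite(rho_b) || rho_b <= 0) stop("rho_b must be positive")
  if (!is.finite(cp_b) || cp_b <= 0) stop("cp_b must be positive")
  if (!is.finite(t_a) || t_a <= 30 || t_a >= 42)
    stop("t_a must lie within (30, 42) degC")
  structure(list(rho_b = rho_b, cp_b = cp_b, t_a = t_a),
            class = "BloodProperties")
}

#' Baseline tissue property table
#'
#' The built-in thermophysical constants for the normal brain tissue classes
#' (CSF, GM, WM) plus a water-like `background` entry used only to define the
#' conductive interface toward the fixed-temperature surround (background
#' pixels themselves are never updated by the solver). Any value can be
#' overridden through `config`, a nested list such as
#' `list(WM = list(qm = 4000))`, or loaded from YAML with
#' [readPropertyConfig()].
#'
#' @param config optional nested list of overrides, tissue -> field -> value.
#' @return Named list of [tissueProperties()] entries
#'   (background, CSF, GM, WM).
#' @export
#' @examples
#' baselineProperties()$WM$wb
#' baselineProperties(list(WM = list(qm = 4000)))$WM$qm
baselineProperties <- function(config = NULL) {
  tab <- list(
    background = tissueProperties("background", k = 0.6, rho = 1000,
                                  cp = 4200, qm = 0, wb = 0),
    CSF = tissueProperties("CSF", k = 0.6,   rho = 1000,   cp = 4200,
                           qm = 0,       wb = 0),
    GM  = tissueProperties("GM",  k = 0.565, rho = 1035.5, cp = 3680,
                           qm = 16229,   wb = 0.013289),
    WM  = tissueProperties("WM",  k = 0.503, rho = 1027.4, cp = 3600,
                           qm = 4517.9,  wb = 0.0036956))
  if (!is.null(config)) {
    for (tn in names(config)) {
      if (!tn %in% names(tab))
        stop("unknown tissue in config: ", tn)
      for (fn in names(config[[tn]])) {
        if (!fn %in% c("k", "rho", "cp", "qm", "wb"))
          stop("unknown property field in config: ", fn)
        tab[[tn]][[fn]] <- config[[tn]][[fn]]
      }
      tab[[tn]] <- do.call(tissueProperties, tab[[tn]])
    }
  }
  tab
}

#' Derive ischemic lesion properties from a baseline tissue
#'
#' Ischemic tissue keeps the conductive properties (k, rho, cp) of its parent
#' tissue; blood perfusion is scaled by `perfusionFactor` and metabolic heat
#' generation by `metabolismFactor`. With the white-matter baseline, factors
#' (0.4, 0.7) give the penumbra and (0.2, 0) the infarct core.
#'
#' @param base a [tissueProperties()] object (typically white matter).
#' @param perfusionFactor fraction in [0, 1] applied to wb.
#' @param metabolismFactor fraction in [0, 1] applied to qm.
#' @param name label for the derived tissue.
#' @return A [tissueProperties()] object.
#' @export
#' @examples
#' wm <- baselineProperties()$WM
#' deriveLesionProperties(wm, 0.4, 0.7, "penumbra")
deriveLesionProperties <- function(base, perfusionFactor, metabolismFactor,
                                   name = "lesion") {
  stopifnot(inherits(base, "TissueProperties"))
  if (!is.finite(perfusionFactor) || perfusionFactor < 0 ||
      perfusionFactor > 1)
    stop("perfusionFactor must lie in [0, 1]")
  if (!is.finite(metabolismFactor) || metabolismFactor < 0 ||
      metabolismFactor > 1)
    stop("metabolismFactor must lie in [0, 1]")
  tissueProperties(name, k = base$k, rho = base$rho, cp = base$cp,
                   qm = base$qm * metabolismFactor,
                   wb = base$wb * perfusionFactor)
}

#' Full six-class property table including the stroke lesion tissues
#'
#' Extends [baselineProperties()] with the penumbra and infarct-core rows,
#' derived from white matter with the perfusion/metabolism reduction factors
#' of the lesion model (defaults 0.4/0.7 for penumbra, 0.2/0 for the core).
#'
#' @param config optional overrides, forwarded to [baselineProperties()].
#' @param lesion optional [lesionSpec()]; its reduction factors are used.
#' @return Named list of [tissueProperties()] for all six tissue classes.
#' @export
tissuePropertyTable <- function(config = NULL, lesion = lesionSpec()) {
  tab <- baselineProperties(config)
  tab$penumbra <- deriveLesionProperties(
    tab$WM, lesion$perfusion_factor_penumbra,
    lesion$metabolism_factor_penumbra, "penumbra")
  tab$infarct_core <- deriveLesionProperties(
    tab$WM, lesion$perfusion_factor_core,
    lesion$metabolism_factor_core, "infarct_core")
  tab
}

#' Per-pixel thermophysical property grids
#'
#' Expands a tissue label map into five real-valued matrices (k, rho, cp, qm,
#' wb) of the same shape, each pixel taking the property of its tissue class.
#'
#' @param map a [TissueLabelMap-class].
#' @param props named list of [tissueProperties()], e.g.
#'   [tissuePropertyTable()]; every label present in `map` must have an entry
#'   under its legend name.
#' @return List of matrices `k`, `rho`, `cp`, `qm`, `wb`, plus `background`,
#'   a logical matrix marking background pixels.
#' @export
propertyGrids <- function(map, props = tissuePropertyTable()) {
  stopifnot(is(map, "TissueLabelMap"))
  lab <- labelMatrix(map)
  legend <- labelLegend(map)
  present <- sort(unique(as.integer(lab)))
  nm <- names(legend)[match(present, legend)]
  missing <- nm[!nm %in% names(props)]
  if (length(missing))
    stop("no properties for tissue label(s): ", paste(missing, collapse = ", "))
  # lookup vectors indexed by label integer + 1
  maxlab <- max(legend)
  grids <- list()
  for (field in c("k", "rho", "cp", "qm", "wb")) {
    lut <- rep(NA_real_, maxlab + 1L)
    for (i in seq_along(nm))
      lut[present[i] + 1L] <- props[[nm[i]]][[field]]
    g <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
    grids[[field]] <- g
  }
  grids$background <- lab == legend[["background"]]
  grids
}

#' Read a tissue property configuration from YAML
#'
#' The YAML file mirrors the property table: top-level keys are tissue names
#' (CSF, GM, WM, background) with fields `k`, `rho`, `cp`, `qm`, `wb`, plus an
#' optional `blood` block with `rho_b`, `cp_b`, `t_a`.
#'
#' @param path path to a YAML file.
#' @return List with elements `tissues` (override list for
#'   [baselineProperties()]) and `blood` (a [bloodProperties()] object).
#' @export
readPropertyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  blood <- do.call(bloodProperties, as.list(cfg$blood %||% list()))
  cfg$blood <- NULL
  list(tissues = cfg, blood = blood)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
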