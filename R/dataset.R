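# Dataset construction bookkeeping: six-variant rigid augmentation,
# slice-selection, training manifests and subject-level k-fold
# crossvalidation splits.

rotCW <- function(m) t(m[nrow(m):1, , drop = FALSE])
flipH <- function(m) m[, ncol(m):1, drop = FALSE]
flipV <- function(m) m[nrow(m):1, , drop = FALSE]

#' Six-variant rigid augmentation
#'
#' Returns the identity plus the 90/180/270-degree rotations and the
#' horizontal and vertical flips of an image, each with its lesion mask
#' transformed identically. Quarter-turn rotations require a square image.
#'
#' @param image a [ThermalImage-class] (or a plain matrix, in which case
#'   plain matrices are returned).
#' @return Named list of 6 variants: `identity`, `rot90`, `rot180`,
#'   `rot270`, `flip_h`, `flip_v`.
#' @export
augmentSix <- function(image) {
  plain <- !is(image, "ThermalImage")
  px <- if (plain) image else pixelMatrix(image)
  if (nrow(px) != ncol(px))
    stop("quarter-turn rotations require a square image")
  tf <- list(identity = identity,
             rot90 = rotCW,
             rot180 = function(m) rotCW(rotCW(m)),
             rot270 = function(m) rotCW(rotCW(rotCW(m))),
             flip_h = flipH,
             flip_v = flipV)
  if (plain) return(lapply(tf, function(f) f(px)))
  m <- imageMask(image)
  lapply(tf, function(f)
    ThermalImage(f(px), sourceRange(image),
                 mask = if (is.null(m)) NULL else f(m),
                 seed = image@seed))
}

#' Select the slices with the largest lesion area
#'
#' Operationalizes "slices that contain the lesion" as the `n` slices with
#' the largest penumbra pixel count, ties broken by lower slice index.
#'
#' @param areas numeric vector of per-slice lesion pixel counts.
#' @param n number of slices to keep.
#' @return Sorted integer indices of the selected slices.
#' @export
selectLesionSlices <- function(areas, n = 19) {
  if (n > length(areas)) stop("fewer slices than requested")
  sort(order(-areas, seq_along(areas))[seq_len(n)])
}

#' Build a dataset manifest
#'
#' One entry per (subject, slice) pair, times six when `augment = TRUE`.
#' With the study bookkeeping of 28 training subjects and 19 slices each this
#' gives 532 base images and 3192 after augmentation; the 2 held-out test
#' subjects contribute 38.
#'
#' @param subjects number of subjects (>= 1).
#' @param slicesPerSubject slices kept per subject (>= 1), default 19.
#' @param augment include the six rigid variants per slice?
#' @param dir directory prefix used for the image/mask paths.
#' @param firstSubject subject id of the first entry (default 1), so test
#'   manifests can start at subject 29.
#' @return A `DatasetManifest` data.frame with columns `subject`, `slice`,
#'   `variant`, `image`, `mask`, `fold` (NA until [kfoldSplit()]).
#' @export
#' @examples
#' nrow(buildManifest(28, 19))             # 532
#' nrow(buildManifest(28, 19, augment = TRUE))  # 3192
buildManifest <- function(subjects, slicesPerSubject = 19, augment = FALSE,
                          dir = "dataset", firstSubject = 1) {
  stopifnot(subjects >= 1, slicesPerSubject >= 1)
  variants <- if (augment)
    c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")
  else "identity"
  grid <- expand.grid(variant = variants,
                      slice = seq_len(slicesPerSubject),
                      subject = seq.int(firstSubject,
                                        firstSubject + subjects - 1),
                      stringsAsFactors = FALSE)
  stem <- sprintf("sub%02d_slice%02d_%s", grid$subject, grid$slice,
                  grid$variant)
  man <- data.frame(subject = grid$subject, slice = grid$slice,
                    variant = grid$variant,
                    image = file.path(dir, paste0(stem, ".png")),
                    mask = file.path(dir, paste0(stem, "_mask.png")),
                    fold = NA_integer_, stringsAsFactors = FALSE)
  man <- man[order(man$subject, man$slice, match(man$variant, variants)), ]
  rownames(man) <- NULL
  structure(man, class = c("DatasetManifest", "data.frame"),
            n_subjects = as.integer(subjects),
            slices_per_subject = as.integer(slicesPerSubject),
            augmented = augment)
}

#' Subject-level k-fold crossvalidation split
#'
#' Partitions the subjects of a manifest into `k` near-equal groups (sizes
#' differ by at most one); fold i uses group i for validation and the
#' remaining groups for training. All slices and augmented variants of one
#' subject stay on the same side of every fold, so augmentation never leaks
#' across the split. Deterministic for a fixed seed.
#'
#' @param manifest a [buildManifest()] data.frame.
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed RNG seed for the subject shuffle.
#' @return List of `k` folds, each a list with `train` and `validation`
#'   manifests (their `fold` column set to the fold index).
#' @export
kfoldSplit <- function(manifest, k = 5, seed = 1) {
  subjects <- unique(manifest$subject)
  if (k < 2) stop("k must be at least 2")
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  shuffled <- withSeed(seed, sample(subjects))
  sizes <- rep(length(subjects) %/% k, k)
  extra <- length(subjects) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  groups <- split(shuffled, rep(seq_len(k), sizes))
  lapply(seq_len(k), function(i) {
    val <- manifest[manifest$subject %in% groups[[i]], ]
    trn <- manifest[!manifest$subject %in% groups[[i]], ]
    val$fold <- i; trn$fold <- i
    list(train = trn, validation = val)
  })
}
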