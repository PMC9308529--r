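# Segmentation evaluation: pixel confusion counts, the four standard
# metrics (accuracy, precision, recall, Dice), slice aggregation, and the
# exclusive-agreement percentages comparing two segmentations of the same
# ground truth.

#' Pixelwise confusion counts of a binary segmentation
#'
#' @param pred,truth binary (0/1 or logical) matrices of one shape; positive
#'   means lesion.
#' @return A [ConfusionCounts-class].
#' @export
#' @examples
#' confusionCounts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must share one shape")
  p <- as.logical(pred); t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) stop("masks must be binary with no missing values")
  new("ConfusionCounts",
      tp = sum(p & t), fp = sum(p & !t),
      tn = sum(!p & !t), fn = sum(!p & t))
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and Dice `2TP/(2TP+FP+FN)`. A metric whose denominator is
#' zero is reported as `NA` and flagged as undefined rather than coerced
#' to 0.
#'
#' @param c a [ConfusionCounts-class] (or a list with tp/fp/tn/fn).
#' @return List with `values` (named numeric, `NA` when undefined) and
#'   `defined` (named logical).
#' @export
segmentationMetrics <- function(c) {
  if (is(c, "ConfusionCounts"))
    c <- list(tp = c@tp, fp = c@fp, tn = c@tn, fn = c@fn)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  v <- c(accuracy = ratio(c$tp + c$tn, c$tp + c$fn + c$tn + c$fp),
         precision = ratio(c$tp, c$tp + c$fp),
         recall = ratio(c$tp, c$tp + c$fn),
         dice = ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn))
  list(values = v, defined = !is.na(v))
}

#' Aggregate per-slice metrics as mean and standard deviation
#'
#' @param metricList list of [segmentationMetrics()] results, one per slice.
#' @return data.frame with one row per metric: `mean`, `sd`, `n_defined`.
#' @export
aggregateMetrics <- function(metricList) {
  vals <- do.call(rbind, lapply(metricList, function(m) m$values))
  data.frame(metric = colnames(vals),
             mean = apply(vals, 2, mean, na.rm = TRUE),
             sd = apply(vals, 2, sd, na.rm = TRUE),
             n_defined = colSums(!is.na(vals)),
             row.names = NULL)
}

#' Exclusive-agreement percentages between two segmentations
#'
#' Quantifies what one segmentation captures that another misses, relative
#' to ground truth: `penumbra_pct` is the percentage of true-lesion pixels
#' correctly labelled lesion by `thermal_pred` but not by `other_pred`;
#' `background_pct` is the percentage of true-background pixels correctly
#' labelled background by `thermal_pred` while `other_pred` labels them
#' lesion. Denominators are the ground-truth lesion and background pixel
#' counts; a percentage with an empty denominator is `NA` and flagged.
#'
#' @param thermal_pred,other_pred,truth binary matrices of one shape.
#' @return List with `values` (named numeric `penumbra_pct`,
#'   `background_pct`, in percent) and `defined` (named logical).
#' @export
exclusiveAgreementPct <- function(thermal_pred, other_pred, truth) {
  if (!identical(dim(thermal_pred), dim(truth)) ||
      !identical(dim(other_pred), dim(truth)))
    stop("all three masks must share one shape")
  th <- as.logical(thermal_pred); ot <- as.logical(other_pred)
  tr <- as.logical(truth)
  nles <- sum(tr); nbg <- sum(!tr)
  pen <- if (nles > 0) 100 * sum(tr & th & !ot) / nles else NA_real_
  bg <- if (nbg > 0) 100 * sum(!tr & !th & ot) / nbg else NA_real_
  v <- c(penumbra_pct = pen, background_pct = bg)
  list(values = v, defined = !is.na(v))
}
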