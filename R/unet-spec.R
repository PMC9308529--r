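# Constructible U-Net architecture specification: a layer table carrying
# kernel sizes, channel counts, output shapes and per-layer parameter
# counts, from which the exact trainable-parameter total is derived.

unetVariants <- c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")

#' Build the U-Net layer specification
#'
#' Emits the encoder-decoder topology as an ordered layer table: five encoder
#' blocks of two 3x3 same-padded conv+ReLU layers with base channel widths
#' 64/128/256/512/1024, 2x2 max-pooling after blocks 1-4, dropout (p = 0.5)
#' after blocks 4 and 5, four decoder stages of a 2x2 stride-2 learned
#' up-convolution followed by skip concatenation and two 3x3 conv+ReLU
#' layers, and a final 1x1 convolution with sigmoid activation to a single
#' penumbra-probability channel. Output shapes are recorded per layer; at
#' 96 x 96 input the bottleneck is 6 x 6 x 1024 and the total trainable
#' parameter count is 31,030,593.
#'
#' @param input_rows,input_cols input image size; both must be divisible by
#'   16 (four 2x halvings).
#' @param widthScale optional fraction scaling every channel width (minimum
#'   1 channel); 1 reproduces the full-size network.
#' @return A `UNetSpec` data.frame, one row per layer, with columns `name`,
#'   `kind` (input/conv/max_pool/dropout/up_conv/concat/output), `kernel_h`,
#'   `kernel_w`, `in_channels`, `out_channels`, `stride`, `padding`,
#'   `activation`, `dropout_p`, `ref1`, `ref2` (concat inputs), `out_rows`,
#'   `out_cols`, `params`.
#' @export
#' @examples
#' spec <- buildUnetSpec(96, 96)
#' spec[spec$name == "conv5b", c("out_rows", "out_cols", "out_channels")]
#' countParameters(spec)
buildUnetSpec <- function(input_rows, input_cols, widthScale = 1) {
  if (input_rows %% 16 != 0 || input_cols %% 16 != 0)
    stop("input dimensions must be divisible by 16")
  input_rows <- as.integer(input_rows)
  input_cols <- as.integer(input_cols)
  ch <- pmax(1L, as.integer(round(c(64, 128, 256, 512, 1024) * widthScale)))
  rows <- list()
  add <- function(name, kind, kh = NA, kw = NA, cin = NA, cout, stride = 1L,
                  padding = NA, activation = "none", dropout_p = NA,
                  ref1 = NA, ref2 = NA, or, oc) {
    params <- if (kind %in% c("conv", "up_conv"))
      kh * kw * cin * cout + cout else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, kernel_h = kh, kernel_w = kw,
      in_channels = cin, out_channels = cout, stride = stride,
      padding = padding, activation = activation, dropout_p = dropout_p,
      ref1 = ref1, ref2 = ref2, out_rows = or, out_cols = oc,
      params = params, stringsAsFactors = FALSE)
  }
  r <- input_rows; c <- input_cols
  add("input", "input", cout = 1L, or = r, oc = c)
  prevC <- 1L
  convBlock <- function(stem, cin, cout, r, c) {
    add(paste0(stem, "a"), "conv", 3L, 3L, cin, cout, padding = "same",
        activation = "relu", or = r, oc = c)
    add(paste0(stem, "b"), "conv", 3L, 3L, cout, cout, padding = "same",
        activation = "relu", or = r, oc = c)
  }
  # encoder
  for (b in 1:5) {
    convBlock(paste0("conv", b), prevC, ch[b], r, c)
    prevC <- ch[b]
    if (b %in% c(4, 5))
      add(paste0("drop", b), "dropout", cout = prevC, dropout_p = 0.5,
          or = r, oc = c)
    if (b < 5) {
      r <- r %/% 2L; c <- c %/% 2L
      add(paste0("pool", b), "max_pool", 2L, 2L, prevC, prevC, stride = 2L,
          or = r, oc = c)
    }
  }
  # decoder
  skips <- c("drop4", "conv3b", "conv2b", "conv1b")
  for (s in 1:4) {
    b <- 5 - s                      # target encoder level 4,3,2,1
    r <- r * 2L; c <- c * 2L
    add(paste0("up", 5 + s), "up_conv", 2L, 2L, prevC, ch[b], stride = 2L,
        activation = "relu", or = r, oc = c)
    add(paste0("concat", 5 + s), "concat", cin = 2L * ch[b],
        cout = 2L * ch[b], ref1 = skips[s], ref2 = paste0("up", 5 + s),
        or = r, oc = c)
    convBlock(paste0("conv", 5 + s), 2L * ch[b], ch[b], r, c)
    prevC <- ch[b]
  }
  add("conv10", "conv", 1L, 1L, prevC, 1L, padding = "same",
      activation = "sigmoid", or = r, oc = c)
  add("output", "output", cout = 1L, or = r, oc = c)
  spec <- do.call(rbind, rows)
  structure(spec, class = c("UNetSpec", "data.frame"),
            channels = ch, input = c(input_rows, input_cols),
            widthScale = widthScale)
}

#' Total trainable parameter count of a U-Net specification
#'
#' Sums kernel weights plus biases (`kh*kw*in*out + out`) over all conv and
#' up-conv layers; pooling, concatenation and dropout layers carry no
#' trainable parameters.
#'
#' @param spec a [buildUnetSpec()] layer table.
#' @return Integer-valued parameter total.
#' @export
countParameters <- function(spec) {
  stopifnot(is.data.frame(spec))
  tr <- spec$kind %in% c("conv", "up_conv")
  sum(spec$kernel_h[tr] * spec$kernel_w[tr] * spec$in_channels[tr] *
        spec$out_channels[tr] + spec$out_channels[tr])
}

#' Layer counts under several counting conventions
#'
#' Reported layer totals depend on whether pooling, dropout, concatenation
#' and the input/output markers are counted as layers; rather than asserting
#' one convention, this tabulates the total under each.
#'
#' @param spec a [buildUnetSpec()] layer table.
#' @return Named integer vector of cumulative conventions.
#' @export
layerCounts <- function(spec) {
  n <- function(kinds) sum(spec$kind %in% kinds)
  weighted <- n(c("conv", "up_conv"))
  c(weighted_only = weighted,
    plus_pooling = weighted + n("max_pool"),
    plus_dropout = weighted + n(c("max_pool", "dropout")),
    plus_concat = weighted + n(c("max_pool", "dropout", "concat")),
    all_rows = nrow(spec))
}

#' Serialize a U-Net specification to JSON
#'
#' @param spec a [buildUnetSpec()] layer table.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
unetSpecToJSON <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(
    list(input = attr(spec, "input"), channels = attr(spec, "channels"),
         total_parameters = countParameters(spec),
         layers = as.data.frame(spec)),
    dataframe = "rows", auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Training hyperparameter configuration
#'
#' The full-scale training recipe: Adam with learning rate 1e-4, batch size
#' 22, up to 100 epochs, weights initialized from N(0, 0.01^2), zero biases,
#' soft Dice loss on a sigmoid output. The scaled-down demo overrides the
#' rate/epoch fields (see [trainDemo()]).
#'
#' @param learning_rate Adam step size.
#' @param batch_size images per gradient step.
#' @param max_epochs epoch cap.
#' @param weight_init_sd standard deviation of the normal weight init.
#' @param bias_init initial bias value.
#' @param dice_eps smoothing constant of the soft Dice loss.
#' @return A `TrainingConfig` list.
#' @export
trainingConfig <- function(learning_rate = 1e-4, batch_size = 22,
                           max_epochs = 100, weight_init_sd = 0.01,
                           bias_init = 0, dice_eps = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            weight_init_sd > 0, dice_eps >= 0)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_init_sd = weight_init_sd, bias_init = bias_init,
                 loss = "soft_dice", dice_eps = dice_eps),
            class = "TrainingConfig")
}

#' Soft Dice loss
#'
#' `1 - (2*sum(pred*truth) + eps) / (sum(pred) + sum(truth) + eps)` for a
#' probabilistic prediction against a binary ground truth; the smoothing
#' constant `eps` keeps the loss defined on empty masks.
#'
#' @param pred numeric matrix of probabilities in [0, 1].
#' @param truth binary matrix of the same shape.
#' @param eps smoothing constant, default 1.
#' @return Scalar loss in [0, 1].
#' @export
softDiceLoss <- function(pred, truth, eps = 1) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must share one shape")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}
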