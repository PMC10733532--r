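# Training loss and evaluation metrics.

check_binary <- function(m, what) {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1)))
    stop(what, " must be strictly binary (values in {0, 1})")
  invisible(NULL)
}

#' Per-image confusion counts
#'
#' Pixel-wise true/false positives/negatives of a binary prediction against a
#' binary ground-truth mask.
#'
#' @param pred_mask,gt_mask binary matrices/arrays of identical shape.
#' @return a `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(gt_mask) %||% length(gt_mask)))
    stop("prediction and ground truth must have identical shapes")
  check_binary(pred_mask, "pred_mask")
  check_binary(gt_mask, "gt_mask")
  p <- as.vector(pred_mask) > 0.5
  g <- as.vector(gt_mask) > 0.5
  structure(list(tp = sum(p & g), tn = sum(!p & !g),
                 fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d tn=%d fp=%d fn=%d (n=%d)\n", x$tp, x$tn, x$fp, x$fn,
              x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Overlap and pixel metrics
#'
#' `dice` is `2*TP / (FP + FN + 2*TP)`, `iou` is `TP / (FP + FN + TP)`,
#' `accuracy` is `(TP + TN) / (TP + TN + FP + FN)` and `precision` is
#' `TP / (TP + FP)`. When both masks are empty (`TP = FP = FN = 0`) Dice and
#' IoU are defined as 1 by convention (logged); precision with no predicted
#' positives is undefined and returned as `NA` (logged), to be excluded from
#' summaries.
#'
#' @param c a [confusion_counts()] object.
#' @return a fraction in `[0, 1]` (or `NA` for undefined precision).
#' @export
dice <- function(c) {
  if (c$tp + c$fp + c$fn == 0) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * c$tp / (c$fp + c$fn + 2 * c$tp)
}

#' @rdname dice
#' @export
iou <- function(c) {
  if (c$tp + c$fp + c$fn == 0) {
    message("iou: both masks empty; returning 1 by convention")
    return(1)
  }
  c$tp / (c$fp + c$fn + c$tp)
}

#' @rdname dice
#' @export
accuracy <- function(c) {
  n <- c$tp + c$tn + c$fp + c$fn
  if (n == 0) stop("accuracy undefined for zero evaluated pixels")
  (c$tp + c$tn) / n
}

#' @rdname dice
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) {
    message("precision: no predicted positives; returning NA")
    return(NA_real_)
  }
  c$tp / (c$tp + c$fp)
}

metric_record <- function(pred_mask, gt_mask, image_id) {
  cc <- confusion_counts(pred_mask, gt_mask)
  data.frame(image_id = image_id, dice = dice(cc), iou = iou(cc),
             accuracy = accuracy(cc), precision = precision(cc),
             stringsAsFactors = FALSE)
}

#' Compound BCE + soft-Dice loss
#'
#' Training loss for binary segmentation: the per-image mean binary
#' cross-entropy of the predicted probabilities plus the per-image soft Dice
#' complement `1 - 2*S / (2*S + FP~ + FN~)` with probabilistic counts
#' `S = sum(p*g)`, `FP~ = sum(p*(1-g))`, `FN~ = sum((1-p)*g)`, both averaged
#' over the batch. Probabilities exactly 0 or 1 are clamped at `1e-7` for the
#' logarithms (logged).
#'
#' @param pred_probs probability maps in `(0, 1)`; `H x W`, `H x W x N` or a
#'   4-d feature map.
#' @param gt binary masks of matching shape.
#' @return a `loss_value` list with `total`, `bce_part` and `dice_part`
#'   (`total = bce_part + dice_part`).
#' @export
bce_dice_loss <- function(pred_probs, gt) {
  p <- as_feature_map(pred_probs)
  g <- as_feature_map(gt)
  if (!identical(dim(p), dim(g)))
    stop("prediction and ground truth must have identical shapes")
  check_binary(g, "gt")
  if (any(p < 0) || any(p > 1)) stop("pred_probs must lie in [0, 1]")
  eps <- 1e-7
  if (any(p <= 0) || any(p >= 1)) {
    message("bce_dice_loss: probabilities at 0/1 clamped at eps = 1e-7")
    p <- pmin(pmax(p, eps), 1 - eps)
    dim(p) <- dim(g)
  }
  n <- dim(p)[4]
  npix <- prod(dim(p)[1:3])
  bce <- 0; dsc <- 0
  for (i in seq_len(n)) {
    pi_ <- p[, , , i]; gi <- g[, , , i]
    bce <- bce - sum(gi * log(pi_) + (1 - gi) * log(1 - pi_)) / npix
    S <- sum(pi_ * gi)
    fp <- sum(pi_ * (1 - gi)); fn <- sum((1 - pi_) * gi)
    dsc <- dsc + if (2 * S + fp + fn > 0) 1 - 2 * S / (2 * S + fp + fn) else 0
  }
  structure(list(total = bce / n + dsc / n, bce_part = bce / n,
                 dice_part = dsc / n), class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("BCE-Dice loss: %.5f (bce %.5f + dice %.5f)\n",
              x$total, x$bce_part, x$dice_part))
  invisible(x)
}

#' Per-image metric summary
#'
#' Mean and sample standard deviation of each metric across images (the
#' per-image-then-average protocol used for benchmark tables). Undefined
#' precision values (`NA`) are excluded from the precision summary (logged).
#'
#' @param records data.frame of per-image metrics (from [evaluate()] or
#'   rbind-ed [confusion_counts()] records) with columns `dice`, `iou`,
#'   `accuracy`, `precision`.
#' @return data.frame with columns `metric`, `mean`, `std`, `n`.
#' @export
summarize_metrics <- function(records) {
  if (NROW(records) < 1) stop("summarize_metrics needs at least one record")
  mets <- c("dice", "iou", "accuracy", "precision")
  rows <- lapply(mets, function(m) {
    v <- records[[m]]
    if (anyNA(v)) {
      message("summarize_metrics: excluding ", sum(is.na(v)),
              " undefined ", m, " value(s)")
      v <- v[!is.na(v)]
    }
    data.frame(metric = m, mean = mean(v),
               std = if (length(v) > 1) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative improvement percentage
#'
#' `100 * (a - b) / b`: the improvement of metric value `a` over reference
#' `b`, as used in model-comparison tables.
#'
#' @param a,b metric values (vectors recycle).
#' @return percentage(s).
#' @export
improvement_pct <- function(a, b) 100 * (a - b) / b

#' Pairwise model improvement table
#'
#' @param summaries named list of [summarize_metrics()] outputs, one per model.
#' @param model name of the model being assessed.
#' @param over name of the reference model.
#' @return data.frame with columns `metric`, `improvement_pct`.
#' @export
improvement_table <- function(summaries, model, over) {
  a <- summaries[[model]]; b <- summaries[[over]]
  if (is.null(a) || is.null(b)) stop("both models must be in `summaries`")
  data.frame(metric = a$metric,
             improvement_pct = improvement_pct(a$mean, b$mean),
             stringsAsFactors = FALSE)
}

#' Write metric summaries as CSV
#'
#' One row per (model, metric) with columns `model`, `metric`, `mean`, `std`.
#'
#' @param summaries named list of [summarize_metrics()] outputs.
#' @param path output file.
#' @export
write_metrics_csv <- function(summaries, path) {
  rows <- lapply(names(summaries), function(nm)
    cbind(model = nm, summaries[[nm]][, c("metric", "mean", "std")]))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
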