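# Training loop and evaluation pipeline.

#' Training configuration
#'
#' The benchmark recipe: Adam, cosine-annealing learning-rate schedule with
#' period 10 and floor 1e-4, 140 epochs, batch size 4, inputs resized to
#' 576 x 576. The base learning rate defaults to the Adam convention 1e-3
#' (only the scheduler floor is pinned by the recipe).
#'
#' @param base_lr initial learning rate.
#' @param min_lr scheduler floor.
#' @param t_max cosine period in epochs.
#' @param epochs total training epochs.
#' @param batch_size samples per optimization step.
#' @param input_size square input side (divisible by 16).
#' @param seed seed for shuffling (weights are seeded by [model_config()]).
#' @param checkpoint_path optional path; when set, a checkpoint is written
#'   after every epoch.
#' @param device descriptor (informational; this implementation runs on CPU).
#' @return a `train_config` object.
#' @export
train_config <- function(base_lr = 1e-3, min_lr = 1e-4, t_max = 10L,
                         epochs = 140L, batch_size = 4L, input_size = 576L,
                         seed = 1L, checkpoint_path = NULL, device = "cpu") {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  if (min_lr > base_lr) stop("min_lr must not exceed base_lr")
  if (input_size %% 16L) stop("input_size must be divisible by 16")
  structure(list(base_lr = base_lr, min_lr = min_lr, t_max = as.integer(t_max),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 checkpoint_path = checkpoint_path, device = device),
            class = "train_config")
}

#' Cosine-annealing learning rate
#'
#' `min_lr + (base_lr - min_lr) * (1 + cos(pi * epoch / t_max)) / 2`, the
#' closed form of the cosine-annealing schedule (no restarts), with `epoch`
#' counted from 0.
#'
#' @param epoch 0-based epoch index.
#' @param base_lr,min_lr,t_max schedule parameters.
#' @return learning rate.
#' @export
cosine_lr <- function(epoch, base_lr, min_lr, t_max) {
  min_lr + (base_lr - min_lr) * (1 + cos(pi * epoch / t_max)) / 2
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$value <- p$value - lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

prep_samples <- function(samples, size) {
  lapply(samples, function(s) {
    if (!is.null(s$x)) s else preprocess(s, size)
  })
}

batch_tensors <- function(prepped, idx) {
  size <- nrow(prepped[[1]]$x)
  nb <- length(idx)
  x <- array(0, c(size, size, 3L, nb))
  g <- array(0, c(size, size, 1L, nb))
  for (j in seq_along(idx)) {
    x[, , , j] <- prepped[[idx[j]]]$x
    g[, , 1L, j] <- prepped[[idx[j]]]$mask
  }
  list(x = x, g = g)
}

#' Train a segmentation model
#'
#' Runs `epochs x ceiling(n / batch_size)` Adam steps on the compound
#' BCE + soft-Dice loss with the cosine-annealing schedule. With a fixed
#' seed the run is reproducible on one machine. When `val_samples` is given,
#' the held-out mean Dice is recorded each epoch; if `stop_dice` is also set,
#' training stops once the held-out Dice reaches it (early stopping is off by
#' default).
#'
#' @param model a [build_model()] result (updated in place and returned).
#' @param samples list of `fundus_sample`s (or already-preprocessed pairs).
#' @param config a [train_config()].
#' @param val_samples optional held-out samples.
#' @param stop_dice optional Dice target for early stopping.
#' @param verbose print one line per epoch.
#' @return list with `model` and `history` (data.frame: epoch, loss, lr,
#'   val_dice), one row per completed epoch.
#' @export
train <- function(model, samples, config, val_samples = NULL,
                  stop_dice = NULL, verbose = FALSE) {
  if (!length(samples)) stop("train needs at least one sample")
  if (!inherits(config, "train_config")) stop("config must be a train_config")
  prepped <- prep_samples(samples, config$input_size)
  vprep <- if (!is.null(val_samples))
    prep_samples(val_samples, config$input_size)
  params <- model_params(model)
  opt <- adam_new(params)
  hist <- list()
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr <- cosine_lr(ep - 1L, config$base_lr, config$min_lr, config$t_max)
      ord <- sample.int(length(prepped))
      nsteps <- ceiling(length(prepped) / config$batch_size)
      ep_loss <- 0
      for (st in seq_len(nsteps)) {
        idx <- ord[(((st - 1L) * config$batch_size) + 1L):
                     min(st * config$batch_size, length(prepped))]
        bt <- batch_tensors(prepped, idx)
        tape <- tape_new()
        zero_grads(params)
        vals <- run_prog(model, bt$x, tape = tape, training = TRUE)
        loss <- op_bce_dice_logits(tape, vals[[model$logits_id]], bt$g)
        if (!is.finite(loss$value)) {
          if (!is.null(config$checkpoint_path))
            stop("non-finite loss at epoch ", ep, " step ", st,
                 "; last good checkpoint at ", config$checkpoint_path)
          stop("non-finite loss at epoch ", ep, " step ", st)
        }
        tape_backward(tape, loss)
        opt <- adam_step(opt, params, lr)
        ep_loss <- ep_loss + loss$value
      }
      vd <- NA_real_
      if (!is.null(val_samples)) {
        ev <- evaluate(model, vprep, threshold = 0.5,
                       input_size = config$input_size)
        vd <- mean(ev$records$dice)
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nsteps, lr = lr,
                               val_dice = vd)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %.2e  val_dice %s", ep,
                        ep_loss / nsteps, lr,
                        if (is.na(vd)) "-" else sprintf("%.3f", vd)))
      if (!is.null(config$checkpoint_path))
        save_checkpoint(model, config$checkpoint_path)
      if (!is.null(stop_dice) && !is.na(vd) && vd >= stop_dice) break
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Evaluate a model on labeled samples
#'
#' For each sample: preprocess, forward, binarize the probability map at
#' `threshold`, accumulate confusion counts against the ground truth, and
#' compute Dice / IoU / accuracy / precision. Metrics are computed per image
#' and then averaged (`pooled = FALSE`, the benchmark-table protocol) or
#' pooled over all pixels (`pooled = TRUE`).
#'
#' @param model a `segmentation_model`, or a function mapping an input batch
#'   to probability maps (useful for fixture predictions).
#' @param samples list of `fundus_sample`s or preprocessed pairs.
#' @param threshold binarization threshold for the probability map.
#' @param input_size square input side.
#' @param pooled pool pixels across images instead of per-image averaging.
#' @return list with `records` (one MetricRecord row per image) and
#'   `summary` (from [summarize_metrics()]).
#' @export
evaluate <- function(model, samples, threshold = 0.5, input_size = 576L,
                     pooled = FALSE) {
  if (!length(samples)) stop("evaluate needs at least one sample")
  predict_fn <- if (is.function(model)) model
    else function(x) forward(model, x)
  prepped <- prep_samples(samples, input_size)
  recs <- list()
  pool <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(prepped)) {
    p <- prepped[[i]]
    x <- array(p$x, c(dim(p$x), 1L))
    prob <- predict_fn(x)
    pred <- matrix(as.integer(prob[, , 1, 1] >= threshold),
                   nrow(p$mask), ncol(p$mask))
    if (pooled) {
      cc <- confusion_counts(pred, p$mask)
      for (f in names(pool)) pool[[f]] <- pool[[f]] + cc[[f]]
    } else {
      recs[[i]] <- metric_record(pred, p$mask, p$image_id %||% as.character(i))
    }
  }
  if (pooled) {
    cc <- structure(pool, class = "confusion_counts")
    recs <- list(data.frame(image_id = "pooled", dice = dice(cc),
                            iou = iou(cc), accuracy = accuracy(cc),
                            precision = precision(cc),
                            stringsAsFactors = FALSE))
  }
  records <- do.call(rbind, recs)
  list(records = records, summary = summarize_metrics(records))
}

#' Read a YAML experiment configuration
#'
#' Top-level keys `variant`, `channel_schedule`, `gate_kernel`,
#' `final_kernel`, `seed` populate [model_config()]; keys under `train`
#' populate [train_config()].
#'
#' @param path YAML file.
#' @return list with `model` ([model_config()]) and `train`
#'   ([train_config()]).
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mc_args <- y[intersect(names(y), names(formals(model_config)))]
  tc_args <- (y$train %||% list())
  tc_args <- tc_args[intersect(names(tc_args), names(formals(train_config)))]
  list(model = do.call(model_config, mc_args),
       train = do.call(train_config, tc_args))
}
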