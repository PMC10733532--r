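# Declarative network construction.
#
# A model is a small instruction program (SSA-like list of steps over feature
# maps) plus a table of learned modules. The same program is interpreted two
# ways: forward() executes it on tensors (optionally recording a gradient
# tape), and the complexity profiler walks it over shapes only, so parameter,
# FLOP and memory accounting never needs a full-size forward pass.

pb_new <- function(order = "conv_bn_relu") {
  pb <- new.env(parent = emptyenv())
  pb$steps <- list()
  pb$modules <- list()
  pb$order <- order
  pb
}

pb_emit <- function(pb, op, ins = integer(0), module = NA_character_) {
  pb$steps[[length(pb$steps) + 1L]] <- list(op = op, ins = as.integer(ins),
                                            module = module)
  length(pb$steps)
}

pb_add_module <- function(pb, name, ly) {
  pb$modules[[name]] <- ly
  name
}

emit_conv_bn_relu <- function(pb, name, x, cin, cout, k = 3L) {
  cv <- pb_add_module(pb, paste0(name, ".conv"), new_conv_layer(cin, cout, k))
  bn <- pb_add_module(pb, paste0(name, ".bn"), new_bn_layer(cout))
  if (pb$order == "conv_bn_relu") {
    pb_emit(pb, "relu", pb_emit(pb, "bn", pb_emit(pb, "conv", x, cv), bn))
  } else {
    pb_emit(pb, "bn", pb_emit(pb, "relu", pb_emit(pb, "conv", x, cv)), bn)
  }
}

emit_conv_block <- function(pb, name, x, cin, cout) {
  h <- emit_conv_bn_relu(pb, paste0(name, ".1"), x, cin, cout)
  emit_conv_bn_relu(pb, paste0(name, ".2"), h, cout, cout)
}

emit_up_conv <- function(pb, name, x, cin, cout) {
  up <- pb_emit(pb, "upsample2", x)
  emit_conv_bn_relu(pb, name, up, cin, cout)
}

# Additive attention gate; gates (multiplies) the `d` input.
emit_gate <- function(pb, name, e, d, ce, cd, fint, k) {
  ge <- pb_emit(pb, "bn",
                pb_emit(pb, "conv", e,
                        pb_add_module(pb, paste0(name, ".w_g"),
                                      new_conv_layer(ce, fint, k))),
                pb_add_module(pb, paste0(name, ".w_g_bn"), new_bn_layer(fint)))
  gd <- pb_emit(pb, "bn",
                pb_emit(pb, "conv", d,
                        pb_add_module(pb, paste0(name, ".w_x"),
                                      new_conv_layer(cd, fint, k))),
                pb_add_module(pb, paste0(name, ".w_x_bn"), new_bn_layer(fint)))
  q <- pb_emit(pb, "relu", pb_emit(pb, "add", c(ge, gd)))
  alpha <- pb_emit(pb, "sigmoid",
                   pb_emit(pb, "bn",
                           pb_emit(pb, "conv", q,
                                   pb_add_module(pb, paste0(name, ".w_alpha"),
                                                 new_conv_layer(fint, 1L, k))),
                           pb_add_module(pb, paste0(name, ".w_alpha_bn"),
                                         new_bn_layer(1L))))
  pb_emit(pb, "gatemul", c(d, alpha))
}

#' Architecture configuration
#'
#' Hyperparameters that fully determine one of the three networks. The
#' channel schedule must have 5 entries, each double its predecessor; the
#' four decoder levels each carry one attention gate for `nau_net` and
#' `attention_unet`.
#'
#' @param variant one of `"nau_net"`, `"attention_unet"`, `"unet_pp"`.
#' @param in_channels input channels (3 for RGB fundus photographs).
#' @param out_channels output channels (1: vessel probability).
#' @param channel_schedule encoder widths per level.
#' @param gate_kernel odd side of the square attention-gate convolutions;
#'   defaults to 3 for NAU-Net and 1 for the attention U-Net baseline.
#' @param final_kernel odd side of the output-head convolution; defaults to 3
#'   for NAU-Net and 1 for the baselines.
#' @param seed seed for weight initialization.
#' @param block_order `"conv_bn_relu"` (default) or `"conv_relu_bn"` stage
#'   ordering inside convolution blocks (parameter count is identical).
#' @return a `model_config` object.
#' @export
model_config <- function(variant = c("nau_net", "attention_unet", "unet_pp"),
                         in_channels = 3L, out_channels = 1L,
                         channel_schedule = c(64L, 128L, 256L, 512L, 1024L),
                         gate_kernel = NULL, final_kernel = NULL, seed = 1L,
                         block_order = c("conv_bn_relu", "conv_relu_bn")) {
  variant <- match.arg(variant)
  block_order <- match.arg(block_order)
  if (length(channel_schedule) != 5L)
    stop("channel_schedule must have 5 entries")
  if (any(channel_schedule[-1] != 2L * channel_schedule[-5]))
    stop("each channel_schedule entry must double its predecessor")
  if (in_channels < 1 || out_channels < 1)
    stop("in_channels and out_channels must be positive counts")
  gate_kernel <- as.integer(gate_kernel %||%
                              if (variant == "nau_net") 3L else 1L)
  final_kernel <- as.integer(final_kernel %||%
                               if (variant == "nau_net") 3L else 1L)
  if (gate_kernel %% 2L != 1L || final_kernel %% 2L != 1L)
    stop("gate_kernel and final_kernel must be odd")
  structure(list(variant = variant,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 channel_schedule = as.integer(channel_schedule),
                 gate_kernel = gate_kernel, final_kernel = final_kernel,
                 seed = as.integer(seed), block_order = block_order),
            class = "model_config")
}

build_encoder <- function(pb, cfg) {
  sch <- cfg$channel_schedule
  enc <- integer(5)
  x <- pb_emit(pb, "input")
  prev <- cfg$in_channels
  for (L in 1:5) {
    if (L > 1) x <- pb_emit(pb, "maxpool2", x)
    x <- emit_conv_block(pb, paste0("enc", L), x, prev, sch[L])
    enc[L] <- x
    prev <- sch[L]
  }
  enc
}

build_nau_net <- function(pb, cfg) {
  sch <- cfg$channel_schedule
  enc <- build_encoder(pb, cfg)
  dec <- enc[5]
  for (L in 4:1) {
    ch <- sch[L]
    # neighbored fusion e'_L = [up_conv(e_{L+1}) || e_L], 2*ch channels
    fup <- emit_up_conv(pb, paste0("fuse", L), enc[L + 1], 2L * ch, ch)
    ef <- pb_emit(pb, "concat", c(fup, enc[L]))
    # decoder up-conv d_L
    d <- emit_up_conv(pb, paste0("up", L), dec, 2L * ch, ch)
    # gate: alpha from (e'_L, d_L); d'_L = alpha * d_L
    dg <- emit_gate(pb, paste0("gate", L), ef, d, 2L * ch, ch,
                    max(ch %/% 2L, 1L), cfg$gate_kernel)
    # decoder block consumes [d'_L || e'_L] (3*ch channels)
    dec <- emit_conv_block(pb, paste0("dec", L),
                           pb_emit(pb, "concat", c(dg, ef)), 3L * ch, ch)
  }
  dec
}

build_attention_unet <- function(pb, cfg) {
  sch <- cfg$channel_schedule
  enc <- build_encoder(pb, cfg)
  dec <- enc[5]
  for (L in 4:1) {
    ch <- sch[L]
    d <- emit_up_conv(pb, paste0("up", L), dec, 2L * ch, ch)
    # standard same-level gate: gating signal is the decoder map, the gated
    # tensor is the encoder skip
    eg <- emit_gate(pb, paste0("gate", L), d, enc[L], ch, ch,
                    max(ch %/% 2L, 1L), cfg$gate_kernel)
    dec <- emit_conv_block(pb, paste0("dec", L),
                           pb_emit(pb, "concat", c(eg, d)), 2L * ch, ch)
  }
  dec
}

build_unet_pp <- function(pb, cfg) {
  sch <- cfg$channel_schedule
  x <- pb_emit(pb, "input")
  X <- vector("list", 5) # X[[i+1]][[j+1]] = node (i, j) of the nested grid
  for (i in 0:4) X[[i + 1]] <- vector("list", 5 - i)
  prev <- cfg$in_channels
  for (i in 0:4) {
    if (i > 0) x <- pb_emit(pb, "maxpool2", x)
    x <- emit_conv_block(pb, sprintf("x%d_0", i), x, prev, sch[i + 1])
    X[[i + 1]][[1]] <- x
    prev <- sch[i + 1]
  }
  for (j in 1:4) {
    for (i in 0:(4 - j)) {
      up <- pb_emit(pb, "upsample2", X[[i + 2]][[j]])
      ins <- c(vapply(1:j, function(t) X[[i + 1]][[t]], integer(1)), up)
      cin <- sch[i + 1] * j + sch[i + 2]
      X[[i + 1]][[j + 1]] <- emit_conv_block(pb, sprintf("x%d_%d", i, j),
                                             pb_emit(pb, "concat", ins),
                                             cin, sch[i + 1])
    }
  }
  X[[1]][[5]]
}

#' Build a segmentation network
#'
#' Constructs the network described by a [model_config()]: the
#' neighbored-attention U-Net (5-level encoder, four neighbor-fusion blocks
#' feeding four attention gates, 4-level decoder), the attention U-Net
#' baseline (standard same-level gated skips) or U-Net++ (nested dense skip
#' pathways). Weights are He-initialized from `config$seed`.
#'
#' @param config a [model_config()].
#' @return a `segmentation_model` object.
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) stop("config must be a model_config")
  with_seed(config$seed, {
    pb <- pb_new(config$block_order)
    body <- switch(config$variant,
                   nau_net = build_nau_net(pb, config),
                   attention_unet = build_attention_unet(pb, config),
                   unet_pp = build_unet_pp(pb, config),
                   stop("unsupported variant: ", config$variant))
    head <- pb_add_module(pb, "head",
                          new_conv_layer(config$channel_schedule[1],
                                         config$out_channels,
                                         config$final_kernel))
    logits <- pb_emit(pb, "conv", body, head)
    out <- pb_emit(pb, "sigmoid", logits)
    structure(list(config = config, prog = pb$steps, modules = pb$modules,
                   logits_id = logits, output_id = out),
              class = "segmentation_model")
  })
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model: %s>\n", x$config$variant))
  cat(sprintf("  channel schedule: %s\n",
              paste(x$config$channel_schedule, collapse = ", ")))
  cat(sprintf("  gates: %d (kernel %dx%d), head kernel %dx%d\n",
              n_gates(x), x$config$gate_kernel, x$config$gate_kernel,
              x$config$final_kernel, x$config$final_kernel))
  cat(sprintf("  learnable parameters: %s (%.2f M)\n",
              format(count_params(x), big.mark = ","),
              count_params(x) / 1e6))
  invisible(x)
}

n_gates <- function(model) {
  sum(grepl("^gate[0-9]+\\.w_alpha$", names(model$modules)))
}

model_params <- function(model) {
  out <- list()
  for (nm in names(model$modules)) {
    ps <- layer_params(model$modules[[nm]])
    names(ps) <- paste0(nm, ".", names(ps))
    out <- c(out, ps)
  }
  out
}

# Execute the instruction program on a batch of tensors. Returns the list of
# result nodes (one per step).
run_prog <- function(model, x, tape = NULL, training = FALSE) {
  vals <- vector("list", length(model$prog))
  for (i in seq_along(model$prog)) {
    st <- model$prog[[i]]
    vals[[i]] <- switch(
      st$op,
      input = node_new(x),
      conv = op_conv(tape, vals[[st$ins[1]]], model$modules[[st$module]]),
      bn = op_bn(tape, vals[[st$ins[1]]], model$modules[[st$module]], training),
      relu = op_relu(tape, vals[[st$ins[1]]]),
      sigmoid = op_sigmoid(tape, vals[[st$ins[1]]]),
      maxpool2 = op_maxpool2(tape, vals[[st$ins[1]]]),
      upsample2 = op_upsample2(tape, vals[[st$ins[1]]]),
      concat = op_concat(tape, vals[st$ins]),
      add = op_add(tape, vals[[st$ins[1]]], vals[[st$ins[2]]]),
      gatemul = op_gatemul(tape, vals[[st$ins[1]]], vals[[st$ins[2]]]),
      stop("unknown op: ", st$op))
  }
  vals
}

#' Forward pass
#'
#' Runs a batch of images through the network and returns the single-channel
#' vessel probability map (values strictly in (0, 1)).
#'
#' @param model a [build_model()] result.
#' @param images array with `dim = c(H, W, C, N)` (or `H x W x C`); `H` and
#'   `W` must be divisible by 16.
#' @param training logical; use batch statistics in batch normalization and
#'   update running statistics.
#' @return probability maps, `dim = c(H, W, out_channels, N)`.
#' @export
forward <- function(model, images, training = FALSE) {
  x <- as_feature_map(images)
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial dims must be divisible by 16 (got ", d[1], " x ",
         d[2], "); resize the images first, e.g. with preprocess()")
  if (d[3] != model$config$in_channels)
    stop("input has ", d[3], " channels; model expects ",
         model$config$in_channels)
  vals <- run_prog(model, x, tape = NULL, training = training)
  vals[[model$output_id]]$value
}

## ---- checkpoints ------------------------------------------------------------

model_state <- function(model) {
  st <- lapply(model_params(model), function(p) p$value)
  for (nm in names(model$modules)) {
    ly <- model$modules[[nm]]
    if (ly$kind == "bn") {
      st[[paste0(nm, ".running_mean")]] <- ly$running_mean
      st[[paste0(nm, ".running_var")]] <- ly$running_var
    }
  }
  st
}

set_model_state <- function(model, st) {
  ps <- model_params(model)
  for (nm in names(ps)) {
    if (is.null(st[[nm]])) stop("checkpoint is missing parameter ", nm)
    stopifnot(length(st[[nm]]) == length(ps[[nm]]$value))
    v <- st[[nm]]
    if (!is.null(dim(ps[[nm]]$value))) dim(v) <- dim(ps[[nm]]$value)
    ps[[nm]]$value <- v
  }
  for (nm in names(model$modules)) {
    ly <- model$modules[[nm]]
    if (ly$kind == "bn") {
      ly$running_mean <- st[[paste0(nm, ".running_mean")]] %||% ly$running_mean
      ly$running_var <- st[[paste0(nm, ".running_var")]] %||% ly$running_var
    }
  }
  invisible(model)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding every weight array, the batch-norm
#' running statistics, the full [model_config()] and the package version;
#' loading rebuilds an identical network.
#'
#' @param model a `segmentation_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, state = model_state(model),
               version = as.character(utils::packageVersion("naunet"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  set_model_state(model, ck$state)
  model
}
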