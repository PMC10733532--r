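# Learned layers and the building blocks of the U-Net family.
#
# A layer is an environment holding its parameter nodes plus the static
# metadata (kernel size, channel counts) that the complexity profiler walks.

new_conv_layer <- function(cin, cout, k = 3L, bias = TRUE) {
  if (cout < 1) stop("out_channels must be a positive count, got ", cout)
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$k <- as.integer(k)
  ly$cin <- as.integer(cin)
  ly$cout <- as.integer(cout)
  ly$pad <- (as.integer(k) - 1L) %/% 2L
  # He-normal initialization for ReLU networks
  w <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  ly$w <- param_node(w)
  ly$b <- param_node(numeric(cout))
  ly
}

new_bn_layer <- function(c) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "bn"
  ly$c <- as.integer(c)
  ly$eps <- 1e-5
  ly$momentum <- 0.1
  ly$gamma <- param_node(rep(1, c))
  ly$beta <- param_node(numeric(c))
  ly$running_mean <- numeric(c)
  ly$running_var <- rep(1, c)
  ly
}

layer_params <- function(ly) {
  switch(ly$kind,
         conv = list(w = ly$w, b = ly$b),
         bn = list(gamma = ly$gamma, beta = ly$beta))
}

## ---- composite blocks (constructor + apply) --------------------------------

# conv_block: two successive (3x3 conv -> BN -> ReLU) stages.
new_conv_block <- function(cin, cout, order = c("conv_bn_relu", "conv_relu_bn")) {
  order <- match.arg(order)
  list(conv1 = new_conv_layer(cin, cout, 3L), bn1 = new_bn_layer(cout),
       conv2 = new_conv_layer(cout, cout, 3L), bn2 = new_bn_layer(cout),
       order = order)
}

apply_conv_block <- function(blk, x, tape = NULL, training = FALSE) {
  stage <- function(x, cv, bn) {
    x <- op_conv(tape, x, cv)
    if (blk$order == "conv_bn_relu") {
      op_relu(tape, op_bn(tape, x, bn, training))
    } else {
      op_bn(tape, op_relu(tape, x), bn, training)
    }
  }
  stage(stage(x, blk$conv1, blk$bn1), blk$conv2, blk$bn2)
}

# up_conv: x2 nearest-neighbor up-sampling, then 3x3 conv -> BN -> ReLU.
new_up_conv <- function(cin, cout) {
  list(conv = new_conv_layer(cin, cout, 3L), bn = new_bn_layer(cout))
}

apply_up_conv <- function(blk, x, tape = NULL, training = FALSE) {
  x <- op_upsample2(tape, x)
  op_relu(tape, op_bn(tape, op_conv(tape, x, blk$conv), blk$bn, training))
}

## ---- exported functional operations ----------------------------------------

#' Two-stage convolution block
#'
#' Applies two successive (3x3 convolution, stride 1, padding 1 -> batch
#' normalization -> ReLU) stages, the elementary block of the encoder and
#' decoder. Spatial dimensions are preserved.
#'
#' @param x feature map, array with `dim = c(H, W, C, N)` (an `H x W x C`
#'   array is promoted to batch size 1).
#' @param out_channels positive number of output channels.
#' @param block optional block created by a previous call (returned as
#'   attribute `"block"`); when `NULL` a fresh He-initialized block is created.
#' @param seed seed for weight initialization of a fresh block.
#' @return feature map with `out_channels` channels and the spatial dims of
#'   `x`; the block used is attached as attribute `"block"`.
#' @export
conv_block <- function(x, out_channels, block = NULL, seed = 1L) {
  x <- as_feature_map(x)
  if (out_channels < 1) stop("out_channels must be a positive count")
  if (any(dim(x)[1:2] < 3)) stop("conv_block needs spatial dims >= 3")
  if (is.null(block))
    block <- with_seed(seed, new_conv_block(dim(x)[3], out_channels))
  out <- apply_conv_block(block, node_new(x))$value
  attr(out, "block") <- block
  out
}

#' 2x2 max-pooling downsampling
#'
#' Halves both spatial dimensions with a 2x2 max pool of stride 2; channels
#' are unchanged.
#'
#' @inheritParams conv_block
#' @return feature map with halved spatial dims.
#' @export
downsample <- function(x) {
  x <- as_feature_map(x)
  op_maxpool2(NULL, node_new(x))$value
}

#' Up-convolution
#'
#' Doubles both spatial dimensions by nearest-neighbor up-sampling followed by
#' a 3x3 convolution, batch normalization and ReLU.
#'
#' @inheritParams conv_block
#' @return feature map with doubled spatial dims and `out_channels` channels;
#'   the block used is attached as attribute `"block"`.
#' @export
up_conv <- function(x, out_channels, block = NULL, seed = 1L) {
  x <- as_feature_map(x)
  if (out_channels < 1) stop("out_channels must be a positive count")
  if (is.null(block))
    block <- with_seed(seed, new_up_conv(dim(x)[3], out_channels))
  out <- apply_up_conv(block, node_new(x))$value
  attr(out, "block") <- block
  out
}

#' Neighbored encoder feature fusion
#'
#' Fuses the encoder feature maps of two neighboring resolution levels: the
#' deeper map (level L+1, `2*ch` channels, half the spatial size) is
#' up-convolved to `ch` channels at the shallower resolution and concatenated
#' with the level-L map, giving the fused skip `e'` with `2*ch` channels.
#' Channel order is `[transformed deep, shallow]`.
#'
#' @param e_deep encoder feature map of level L+1 (`2*ch` channels).
#' @param e_shallow encoder feature map of level L (`ch` channels).
#' @inheritParams conv_block
#' @return fused feature map with `2*ch` channels at the spatial dims of
#'   `e_shallow`; the up-conv block used is attached as attribute `"block"`.
#' @export
neighbor_fuse <- function(e_deep, e_shallow, block = NULL, seed = 1L) {
  e_deep <- as_feature_map(e_deep)
  e_shallow <- as_feature_map(e_shallow)
  dd <- dim(e_deep); ds <- dim(e_shallow)
  if (dd[3] != 2L * ds[3] || any(dd[1:2] * 2L != ds[1:2]))
    stop(sprintf(paste0(
      "neighbor_fuse expects the deep map to have 2x the channels and half ",
      "the spatial dims of the shallow map; got deep %s vs shallow %s"),
      paste(dd, collapse = "x"), paste(ds, collapse = "x")))
  if (is.null(block))
    block <- with_seed(seed, new_up_conv(dd[3], ds[3]))
  up <- apply_up_conv(block, node_new(e_deep))
  out <- op_concat(NULL, list(up, node_new(e_shallow)))$value
  attr(out, "block") <- block
  out
}

#' Attention-gate specification
#'
#' Creates the learned maps of an additive attention gate: `w_g` (convolution
#' + batch normalization on the fused encoder skip), `w_x` (convolution +
#' batch normalization on the decoder map) and `w_alpha` (convolution + batch
#' normalization + sigmoid producing the single-channel attention coefficient
#' map). All gate convolutions share `kernel` (3 for NAU-Net, 1 for the
#' attention U-Net baseline) with stride 1.
#'
#' @param channels_e channels of the encoder-side input `e'`.
#' @param channels_d channels of the decoder-side input `d`.
#' @param inter_channels common intermediate width that `w_g` and `w_x` map
#'   to; defaults to half the decoder-side channels.
#' @param kernel odd convolution kernel side.
#' @param seed seed for weight initialization.
#' @return an `attention_gate_spec` object; the individual layers are
#'   accessible as `$w_g`, `$w_g_bn`, `$w_x`, `$w_x_bn`, `$w_alpha`,
#'   `$w_alpha_bn` for inspection or manual weight surgery.
#' @export
attention_gate_spec <- function(channels_e, channels_d,
                                inter_channels = max(channels_d %/% 2L, 1L),
                                kernel = 3L, seed = 1L) {
  if (kernel %% 2L != 1L) stop("gate kernel must be odd")
  with_seed(seed, {
    spec <- list(
      w_g = new_conv_layer(channels_e, inter_channels, kernel),
      w_g_bn = new_bn_layer(inter_channels),
      w_x = new_conv_layer(channels_d, inter_channels, kernel),
      w_x_bn = new_bn_layer(inter_channels),
      w_alpha = new_conv_layer(inter_channels, 1L, kernel),
      w_alpha_bn = new_bn_layer(1L),
      inter_channels = as.integer(inter_channels),
      kernel = as.integer(kernel))
    class(spec) <- "attention_gate_spec"
    spec
  })
}

apply_attention_gate <- function(spec, e, d, tape = NULL, training = FALSE) {
  g <- op_bn(tape, op_conv(tape, e, spec$w_g), spec$w_g_bn, training)
  x <- op_bn(tape, op_conv(tape, d, spec$w_x), spec$w_x_bn, training)
  q <- op_relu(tape, op_add(tape, g, x))
  alpha <- op_sigmoid(
    tape, op_bn(tape, op_conv(tape, q, spec$w_alpha), spec$w_alpha_bn, training))
  list(out = op_gatemul(tape, d, alpha), alpha = alpha)
}

#' Additive attention gate
#'
#' Computes `q = ReLU(w_g e' + w_x d)`, the attention coefficient map
#' `alpha = sigmoid(w_alpha q)` (values strictly in (0, 1)), and returns the
#' gated decoder map `d' = alpha * d` (elementwise, alpha broadcast across
#' channels).
#'
#' @param e_fused encoder-side input (the fused skip `e'`).
#' @param d decoder-side input; `d'` has its shape.
#' @param spec an [attention_gate_spec()]; created with default width when
#'   omitted.
#' @param seed seed used when `spec` is `NULL`.
#' @return the gated map `d'`, with `alpha` attached as attribute `"alpha"`.
#' @export
attention_gate <- function(e_fused, d, spec = NULL, seed = 1L) {
  e_fused <- as_feature_map(e_fused)
  d <- as_feature_map(d)
  if (any(dim(e_fused)[1:2] != dim(d)[1:2]))
    stop(sprintf("attention_gate inputs must share spatial dims; got %s vs %s",
                 paste(dim(e_fused), collapse = "x"),
                 paste(dim(d), collapse = "x")))
  if (is.null(spec))
    spec <- attention_gate_spec(dim(e_fused)[3], dim(d)[3], seed = seed)
  r <- apply_attention_gate(spec, node_new(e_fused), node_new(d))
  out <- r$out$value
  attr(out, "alpha") <- r$alpha$value
  attr(out, "spec") <- spec
  out
}
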