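# Static complexity accounting.
#
# The profiler walks the model's instruction program over shapes only, so no
# tensor is ever allocated. Counting convention (documented in the methods
# vignette):
#   * convolution (stride 1, same padding, with bias):
#       MACs  = k^2 * c_in * c_out * H_out * W_out
#       FLOPs += MACs
#       MAdds += 2*MACs - c_out*H_out*W_out + c_out*H_out*W_out (bias adds)
#             = 2*MACs
#   * batch normalization: 2 FLOPs / element (scale, shift)
#   * ReLU, up-sampling, gating multiply, add: 1 FLOP / element
#   * sigmoid: 4 FLOPs / element
#   * 2x2 max pooling: 4 FLOPs / output element
#   (elementwise MAdds are taken equal to FLOPs)
#   * memory = 4 bytes per activation element, summed over the input and the
#     output of every instruction, plus 4 bytes per parameter.

#' Count learnable parameters
#'
#' Enumerates every weight array of the built model (convolution kernels and
#' biases, batch-normalization scales and shifts; running statistics are
#' buffers, not parameters).
#'
#' @param model a [build_model()] result.
#' @return total number of learnable scalars.
#' @export
count_params <- function(model) {
  sum(vapply(model_params(model), function(p) length(p$value), numeric(1)))
}

#' Static FLOPs / MAdds / memory profile
#'
#' Walks the network's instruction program at a stated input size and
#' aggregates per-layer costs under the convention in the package vignette:
#' convolution FLOPs are multiply-accumulate counts
#' (`k^2 * c_in * c_out * H_out * W_out`), MAdds twice that, and elementwise
#' layers contribute a constant number of operations per element. Activation
#' memory assumes 4-byte values at batch size 1.
#'
#' @param model a [build_model()] result.
#' @param input_dims `c(channels, height, width)`; height and width must be
#'   divisible by 16.
#' @return a `complexity_report`: `n_params`, `total_memory` (bytes),
#'   `flops`, `madds`, `input_dims`, and a per-layer breakdown in
#'   `$by_layer`.
#' @export
count_flops <- function(model, input_dims = c(3L, 576L, 576L)) {
  ci <- input_dims[1]; hi <- input_dims[2]; wi <- input_dims[3]
  if (hi %% 16L || wi %% 16L)
    stop("input spatial dims must be divisible by 16")
  if (ci != model$config$in_channels)
    stop("input_dims channels do not match the model")
  n <- length(model$prog)
  shp <- vector("list", n) # c(C, H, W) per step
  flops <- numeric(n); madds <- numeric(n); elems <- numeric(n)
  kinds <- character(n)
  for (i in seq_len(n)) {
    st <- model$prog[[i]]
    s1 <- if (length(st$ins)) shp[[st$ins[1]]] else NULL
    out <- switch(
      st$op,
      input = c(ci, hi, wi),
      conv = {
        ly <- model$modules[[st$module]]
        if (ly$cin != s1[1])
          stop("layer ", st$module, ": expected ", ly$cin, " channels, got ",
               s1[1])
        c(ly$cout, s1[2], s1[3])
      },
      bn = s1,
      relu = s1,
      sigmoid = s1,
      maxpool2 = c(s1[1], s1[2] %/% 2L, s1[3] %/% 2L),
      upsample2 = c(s1[1], s1[2] * 2L, s1[3] * 2L),
      concat = c(sum(vapply(shp[st$ins], `[`, numeric(1), 1L)), s1[2], s1[3]),
      add = s1,
      gatemul = s1,
      stop("unsupported layer kind: ", st$op))
    ne <- prod(out)
    f <- switch(st$op,
                input = 0,
                conv = {
                  ly <- model$modules[[st$module]]
                  ly$k^2 * ly$cin * ly$cout * out[2] * out[3]
                },
                bn = 2 * ne,
                relu = ne,
                sigmoid = 4 * ne,
                maxpool2 = 4 * ne,
                upsample2 = ne,
                concat = 0,
                add = ne,
                gatemul = ne)
    shp[[i]] <- out
    elems[i] <- ne
    kinds[i] <- st$op
    flops[i] <- f
    madds[i] <- if (st$op == "conv") 2 * f else f
  }
  np <- count_params(model)
  rep_ <- list(
    n_params = np,
    total_memory = 4 * (sum(elems) + np),
    flops = sum(flops),
    madds = sum(madds),
    input_dims = c(ci, hi, wi),
    by_layer = data.frame(
      step = seq_len(n), op = kinds,
      module = vapply(model$prog, function(s) s$module, character(1)),
      out_shape = vapply(shp, paste, character(1), collapse = "x"),
      flops = flops, madds = madds, stringsAsFactors = FALSE))
  class(rep_) <- "complexity_report"
  rep_
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("input %s | params %.2f M | memory %.2f GB | FLOPs %.2f G | MAdds %.2f G\n",
              paste(x$input_dims, collapse = "x"), x$n_params / 1e6,
              x$total_memory / 2^30, x$flops / 1e9, x$madds / 1e9))
  invisible(x)
}

#' Activation + parameter memory estimate
#'
#' Best-effort forward-pass memory at batch size 1: 4 bytes per activation
#' element over all layers (input and each instruction's output) plus 4 bytes
#' per parameter; optimizer state is excluded.
#'
#' @inheritParams count_flops
#' @return bytes.
#' @export
memory_estimate <- function(model, input_dims = c(3L, 576L, 576L)) {
  count_flops(model, input_dims)$total_memory
}

#' Profile several models into a comparison table
#'
#' @param models named list of `segmentation_model`s (or of [model_config()]s,
#'   which are built on the fly).
#' @param input_dims `c(channels, height, width)`.
#' @return data.frame with one row per model: parameters in millions, memory
#'   in GB, FLOPs and MAdds in G.
#' @export
complexity_table <- function(models, input_dims = c(3L, 576L, 576L)) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (inherits(m, "model_config")) m <- build_model(m)
    r <- count_flops(m, input_dims)
    data.frame(model = nm,
               params_m = round(r$n_params / 1e6, 2),
               memory_gb = round(r$total_memory / 2^30, 2),
               flops_g = round(r$flops / 1e9, 2),
               madds_g = round(r$madds / 1e9, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
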