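# Reverse-mode gradient tape.
#
# A node is an environment holding a value, an accumulated gradient, its
# parent nodes and a backward closure mapping the node's gradient to the
# parents' gradients. Executing an op appends the node to the tape;
# tape_backward() walks the tape in reverse execution order, which is a
# valid reverse topological order of the DAG, so fan-out (a tensor consumed
# by several ops, as in the dense U-Net++ skips) is handled by plain
# accumulation.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  tp
}

node_new <- function(value, parents = list(), backward = NULL, tape = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) {
    tp <- tape
    tp$k <- tp$k + 1L
    if (tp$k > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$k]] <- nd
  }
  nd
}

param_node <- function(value) {
  nd <- node_new(value)
  nd$is_param <- TRUE
  nd
}

accumulate_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Seed `out` with gradient 1 (scalar loss) and propagate back through the tape.
tape_backward <- function(tape, out) {
  out$grad <- 1
  for (i in rev(seq_len(tape$k))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(gs))
      if (!is.null(gs[[j]])) accumulate_grad(nd$parents[[j]], gs[[j]])
    nd$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}

## ---- tape ops -------------------------------------------------------------

op_conv <- function(tape, x, ly) {
  y <- .conv2d_fwd(x$value, ly$w$value, ly$b$value, ly$pad)
  node_new(y, list(x, ly$w, ly$b), backward = function(g) {
    r <- .conv2d_bwd(x$value, ly$w$value, g, ly$pad)
    list(r$gx, r$gw, r$gb)
  }, tape)
}

op_bn <- function(tape, x, ly, training) {
  if (training) {
    r <- .bn_fwd(x$value, ly$gamma$value, ly$beta$value, ly$eps)
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * r$mean
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * r$var_unbiased
    node_new(r$y, list(x, ly$gamma, ly$beta), backward = function(g) {
      b <- .bn_bwd(x$value, g, ly$gamma$value, r$mean, r$invstd)
      list(b$gx, b$ggamma, b$gbeta)
    }, tape)
  } else {
    d <- dim(x$value)
    a <- ly$gamma$value / sqrt(ly$running_var + ly$eps)
    b0 <- ly$beta$value - a * ly$running_mean
    scale <- rep(rep(a, each = d[1] * d[2]), times = d[4])
    shift <- rep(rep(b0, each = d[1] * d[2]), times = d[4])
    node_new(array(scale * as.vector(x$value) + shift, d), list(x),
             backward = function(g) list(array(scale * as.vector(g), d)), tape)
  }
}

op_relu <- function(tape, x) {
  v <- x$value
  v[v < 0] <- 0
  node_new(v, list(x), backward = function(g) list(g * (x$value > 0)), tape)
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  node_new(s, list(x), backward = function(g) list(g * s * (1 - s)), tape)
}

op_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("downsample needs even spatial dims, got ", d[1], " x ", d[2],
         " (inputs are expected to be resized to a multiple of 16)")
  r <- .maxpool2_fwd(x$value)
  node_new(r$y, list(x), backward = function(g)
    list(.maxpool2_bwd(g, r$idx, d)), tape)
}

op_upsample2 <- function(tape, x) {
  node_new(.upsample2_fwd(x$value), list(x), backward = function(g)
    list(.upsample2_bwd(g)), tape)
}

op_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, `[`, 1L, 3L)
  d1 <- ds[[1]]
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cs[i]), ] <- xs[[i]]$value
    off <- off + cs[i]
  }
  node_new(out, xs, backward = function(g) {
    off <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <<- off + cs[i]
      gi
    })
  }, tape)
}

# Multiply a feature map by a single-channel attention coefficient map,
# broadcast across channels.
op_gatemul <- function(tape, x, alpha) {
  d <- dim(x$value)
  ae <- alpha$value[, , rep(1L, d[3]), , drop = FALSE]
  node_new(x$value * ae, list(x, alpha), backward = function(g) {
    gx <- g * ae
    m <- aperm(g * x$value, c(1, 2, 4, 3))
    dim(m) <- c(d[1] * d[2] * d[4], d[3])
    ga <- array(rowSums(m), c(d[1], d[2], 1L, d[4]))
    list(gx, ga)
  }, tape)
}

op_add <- function(tape, x, y) {
  node_new(x$value + y$value, list(x, y),
           backward = function(g) list(g, g), tape)
}

# Compound BCE + soft-Dice loss straight from logits, with an analytic
# gradient (numerically stable: no clamped log of a saturated sigmoid).
op_bce_dice_logits <- function(tape, z, gt) {
  d <- dim(z$value)
  n <- d[4]
  p <- 1 / (1 + exp(-z$value))
  g4 <- gt
  npix <- d[1] * d[2] * d[3]
  bce <- 0
  dice <- 0
  sums <- vector("list", n)
  for (i in seq_len(n)) {
    zi <- z$value[, , , i, drop = FALSE]
    gi <- g4[, , , i, drop = FALSE]
    # log(1 + exp(-|z|)) formulation of BCE with logits
    bce <- bce + sum(pmax(zi, 0) - zi * gi + log1p(exp(-abs(zi)))) / npix
    pi_ <- p[, , , i, drop = FALSE]
    S <- sum(pi_ * gi)
    D <- sum(pi_) + sum(gi)
    dice <- dice + (1 - 2 * S / D)
    sums[[i]] <- c(S = S, D = D)
  }
  bce <- bce / n
  dice <- dice / n
  nd <- node_new(bce + dice, list(z), backward = function(g) {
    gz <- (p - g4) / (npix * n) # BCE part
    for (i in seq_len(n)) {
      S <- sums[[i]]["S"]; D <- sums[[i]]["D"]
      pi_ <- p[, , , i, drop = FALSE]
      gi <- g4[, , , i, drop = FALSE]
      dldp <- -(2 * gi * D - 2 * S) / D^2 / n
      gz[, , , i] <- gz[, , , i, drop = FALSE] + dldp * pi_ * (1 - pi_)
    }
    list(g * gz)
  }, tape)
  nd$bce_part <- bce
  nd$dice_part <- dice
  nd
}
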