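test_that("conv_block preserves spatial dims and sets channels", {
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  y <- conv_block(x, 64L, seed = 3)
  expect_equal(dim(y), c(64L, 64L, 64L, 1L))
  y2 <- conv_block(array(rnorm(32 * 32 * 64), c(32, 32, 64, 1)), 128L, seed = 3)
  expect_equal(dim(y2), c(32L, 32L, 128L, 1L))
  expect_error(conv_block(x, 0L), "positive")
})

test_that("conv_block parameter cost matches the closed-form layer sum", {
  blk <- attr(conv_block(array(0, c(8, 8, 3, 1)), 64L, seed = 1), "block")
  n <- length(blk$conv1$w$value) + length(blk$conv1$b$value) +
    length(blk$conv2$w$value) + length(blk$conv2$b$value) +
    length(blk$bn1$gamma$value) + length(blk$bn1$beta$value) +
    length(blk$bn2$gamma$value) + length(blk$bn2$beta$value)
  # (3*3*3*64 + 64) + (3*3*64*64 + 64) + 2*(2*64)
  expect_equal(n, 38976)
})

test_that("downsample halves dims by 2x2 max pooling", {
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 2))
  y <- downsample(x)
  expect_equal(dim(y), c(8L, 8L, 4L, 2L))
  cx <- array(7, c(6, 6, 1, 1))
  expect_true(all(downsample(cx) == 7))
  m <- array(c(1, 3, 2, 4), c(2, 2, 1, 1)) # [[1,2],[3,4]] row-major
  expect_equal(as.vector(downsample(m)), 4)
  expect_error(downsample(array(0, c(5, 6, 1, 1))), "even")
})

test_that("up_conv doubles spatial dims", {
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  y <- up_conv(x, 4L, seed = 2)
  expect_equal(dim(y), c(32L, 32L, 4L, 1L))
})

test_that("nearest up-sampling keeps per-channel constants constant", {
  x <- array(rep(c(1, -2, 0.5), each = 16), c(4, 4, 3, 1))
  u <- naunet:::op_upsample2(NULL, naunet:::node_new(x))$value
  expect_equal(dim(u), c(8L, 8L, 3L, 1L))
  for (ch in 1:3) expect_true(all(u[, , ch, 1] == x[1, 1, ch, 1]))
})

test_that("neighbor_fuse output carries 2x the shallow channels", {
  e_deep <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
  e_shallow <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  ef <- neighbor_fuse(e_deep, e_shallow, seed = 5)
  expect_equal(dim(ef), c(16L, 16L, 16L, 1L))
  # channel order [transformed deep, shallow]: trailing channels are e_shallow
  expect_equal(ef[, , 9:16, 1], e_shallow[, , , 1])
  bad <- array(0, c(8, 8, 24, 1)) # 3x, not 2x, the shallow channels
  expect_error(neighbor_fuse(bad, e_shallow), "8x8x24x1")
})

identity_gate_spec <- function(kernel = 1L) {
  sp <- attention_gate_spec(1L, 1L, inter_channels = 1L, kernel = kernel,
                            seed = 1)
  for (w in list(sp$w_g, sp$w_x, sp$w_alpha)) {
    w$w$value[] <- 0
    w$w$value[(kernel %/% 2L) + 1L, (kernel %/% 2L) + 1L, 1, 1] <- 1
    w$b$value[] <- 0
  }
  sp
}

test_that("attention gate reproduces the hand-computed single-pixel case", {
  sp <- identity_gate_spec()
  e <- array(2, c(1, 1, 1, 1))
  d <- array(3, c(1, 1, 1, 1))
  out <- attention_gate(e, d, sp)
  # q = ReLU(2 + 3) = 5; alpha = sigmoid(5) ~ 0.99331; d' = alpha * 3
  expect_equal(as.vector(attr(out, "alpha")), 1 / (1 + exp(-5)),
               tolerance = 1e-5)
  expect_equal(as.vector(out), 2.97992, tolerance = 1e-5)
})

test_that("attention gate limits give identity and zero gating", {
  sp <- attention_gate_spec(4L, 4L, inter_channels = 2L, kernel = 3L, seed = 2)
  e <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  d <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  sp$w_alpha$w$value[] <- 0
  sp$w_alpha$b$value[] <- 40 # saturate the sigmoid -> alpha ~ 1
  expect_equal(attention_gate(e, d, sp), d, ignore_attr = TRUE)
  sp$w_alpha$b$value[] <- -40 # alpha ~ 0
  expect_equal(max(abs(attention_gate(e, d, sp))), 0)
})

test_that("attention coefficients lie in (0,1) and shrink the gated map", {
  sp <- attention_gate_spec(8L, 4L, kernel = 3L, seed = 3)
  e <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  d <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  out <- attention_gate(e, d, sp)
  a <- attr(out, "alpha")
  expect_true(all(a > 0 & a < 1))
  expect_true(all(abs(out) <= abs(d)))
  expect_error(attention_gate(e, array(0, c(4, 4, 4, 1)), sp), "spatial")
})

test_that("built variants have four gates and preserve input dims", {
  for (v in c("nau_net", "attention_unet", "unet_pp")) {
    m <- tiny_model(v)
    x <- array(rnorm(48 * 48 * 3), c(48, 48, 3, 1))
    p <- forward(m, x)
    expect_equal(dim(p), c(48L, 48L, 1L, 1L))
    expect_true(all(p > 0 & p < 1))
    if (v != "unet_pp") expect_equal(naunet:::n_gates(m), 4L)
  }
})

test_that("forward is deterministic and validates input dims", {
  m <- tiny_model("nau_net")
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(forward(m, x), forward(m, x))
  expect_error(forward(m, array(0, c(30, 30, 3, 1))), "divisible by 16")
  expect_error(forward(m, array(0, c(32, 32, 4, 1))), "channels")
})

test_that("model_config enforces the architecture invariants", {
  expect_error(model_config(channel_schedule = c(64L, 128L)), "5 entries")
  expect_error(model_config(channel_schedule = c(64L, 100L, 200L, 400L, 800L)),
               "double")
  expect_error(model_config(gate_kernel = 2L), "odd")
  expect_error(model_config("fcn"), "arg")
  expect_equal(model_config("nau_net")$gate_kernel, 3L)
  expect_equal(model_config("attention_unet")$gate_kernel, 1L)
})

test_that("parameter enumeration matches the closed-form layer oracle", {
  for (v in c("nau_net", "attention_unet", "unet_pp")) {
    m <- tiny_model(v)
    expect_equal(count_params(m), closed_form_params(m))
  }
})

test_that("fusion arithmetic holds at every level of the built NAU-Net", {
  m <- tiny_model("nau_net")
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  vals <- naunet:::run_prog(m, x)
  # fused skip at level L has 2 * schedule[L] channels at the level's dims
  for (L in 1:4) {
    concat_ids <- which(vapply(m$prog, function(s)
      s$op == "concat", logical(1)))
    szs <- vapply(concat_ids, function(i) dim(vals[[i]]$value)[3], integer(1))
    expect_true((2L * tiny_schedule[L]) %in% szs)
  }
})

test_that("one optimization step moves every fusion and gate weight", {
  m <- tiny_model("nau_net")
  ns <- asNamespace("naunet")
  params <- ns$model_params(m)
  before <- lapply(params, function(p) p$value)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  g <- array(rbinom(32 * 32, 1, 0.2), c(32, 32, 1, 1))
  tape <- ns$tape_new()
  vals <- ns$run_prog(m, x, tape = tape, training = TRUE)
  loss <- ns$op_bce_dice_logits(tape, vals[[m$logits_id]], g)
  ns$tape_backward(tape, loss)
  opt <- ns$adam_step(ns$adam_new(params), params, 1e-3)
  # every gate and fusion branch receives gradient: all convolution kernels
  # and batch-norm scales change (biases absorbed by a following batch norm
  # legitimately have zero gradient)
  moved <- vapply(names(params), function(nm)
    any(params[[nm]]$value != before[[nm]]), logical(1))
  check <- grepl("^(gate|fuse)", names(params)) &
    grepl("(\\.w|gamma|beta)$", names(params))
  expect_true(all(moved[check]))
})

test_that("checkpoints rebuild an identical network", {
  m <- tiny_model("attention_unet", seed = 9L)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- forward(m, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(forward(m2, x), p1)
})
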