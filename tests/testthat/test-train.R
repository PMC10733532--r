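test_that("train_config validates its invariants", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(base_lr = 1e-5, min_lr = 1e-4), "min_lr")
  expect_error(train_config(input_size = 100), "divisible")
  cfg <- train_config()
  expect_equal(cfg$t_max, 10L)
  expect_equal(cfg$min_lr, 1e-4)
  expect_equal(cfg$epochs, 140L)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$input_size, 576L)
})

test_that("cosine annealing follows its closed form", {
  expect_equal(cosine_lr(0, 1e-3, 1e-4, 10), 1e-3)
  expect_equal(cosine_lr(10, 1e-3, 1e-4, 10), 1e-4)
  # half-period: midpoint of base and floor
  expect_equal(cosine_lr(5, 1e-3, 1e-4, 10), (1e-3 + 1e-4) / 2)
})

test_that("one epoch over four samples in batches of four is one step", {
  m <- tiny_model("nau_net")
  samples <- synth_batch(4, 300, size = 32)
  cfg <- train_config(epochs = 1, batch_size = 4, input_size = 32, seed = 2)
  r <- train(m, samples, cfg)
  expect_equal(nrow(r$history), 1)
  expect_equal(r$history$lr, cosine_lr(0, cfg$base_lr, cfg$min_lr, cfg$t_max))
  expect_true(is.finite(r$history$loss))
  expect_error(train(m, list(), cfg), "at least one")
})

test_that("seeded runs are reproducible end to end", {
  samples <- synth_batch(6, 400, size = 32)
  run <- function() {
    m <- tiny_model("nau_net", seed = 5L)
    r <- train(m, samples, train_config(epochs = 2, batch_size = 2,
                                        input_size = 32, seed = 7))
    x <- array(preprocess(samples[[1]], 32)$x, c(32, 32, 3, 1))
    list(hist = r$history, out = forward(r$model, x))
  }
  a <- run()
  b <- run()
  expect_identical(a$hist, b$hist)
  expect_identical(a$out, b$out)
})

test_that("evaluating the ground truth against itself scores 1 everywhere", {
  samples <- synth_batch(3, 500, size = 32)
  prepped <- lapply(samples, preprocess, size = 32L)
  k <- 0
  oracle <- function(x) {
    k <<- k + 1
    array(prepped[[k]]$mask * 0.98 + 0.01, c(32, 32, 1, 1))
  }
  ev <- evaluate(oracle, samples, threshold = 0.5, input_size = 32)
  expect_equal(ev$records$dice, rep(1, 3))
  expect_equal(ev$summary$mean, rep(1, 4))
  expect_equal(ev$summary$std, rep(0, 4))
})

test_that("a constant-zero predictor has zero Dice on non-empty masks", {
  samples <- synth_batch(2, 600, size = 32)
  zero <- function(x) array(0.01, c(32, 32, 1, 1))
  suppressMessages(ev <- evaluate(zero, samples, input_size = 32))
  expect_equal(ev$records$dice, c(0, 0))
  expect_true(all(is.na(ev$records$precision)))
})

test_that("summary columns match hand-computed values on fixture records", {
  recs <- data.frame(image_id = c("a", "b", "c"),
                     dice = c(0.70, 0.75, 0.80),
                     iou = c(0.54, 0.60, 0.66),
                     accuracy = c(0.96, 0.95, 0.97),
                     precision = c(0.80, 0.85, 0.90))
  s <- summarize_metrics(recs)
  expect_equal(s$mean, c(0.75, 0.60, 0.96, 0.85))
  expect_equal(s$std, c(sd(recs$dice), sd(recs$iou), sd(recs$accuracy),
                        sd(recs$precision)))
})

test_that("pixel-pooled evaluation is available behind a flag", {
  samples <- synth_batch(2, 700, size = 32)
  prepped <- lapply(samples, preprocess, size = 32L)
  k <- 0
  oracle <- function(x) {
    k <<- k + 1
    array(prepped[[k]]$mask * 0.98 + 0.01, c(32, 32, 1, 1))
  }
  ev <- evaluate(oracle, samples, input_size = 32, pooled = TRUE)
  expect_equal(nrow(ev$records), 1)
  expect_equal(ev$records$dice, 1)
})

test_that("YAML configs populate the model and training settings", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("variant: nau_net",
               "channel_schedule: [8, 16, 32, 64, 128]",
               "gate_kernel: 3",
               "final_kernel: 3",
               "seed: 4",
               "train:",
               "  epochs: 30",
               "  batch_size: 4",
               "  input_size: 128",
               "  base_lr: 0.001"), f)
  cfg <- config_from_yaml(f)
  expect_equal(cfg$model$variant, "nau_net")
  expect_equal(cfg$model$channel_schedule, c(8L, 16L, 32L, 64L, 128L))
  expect_equal(cfg$train$epochs, 30L)
  expect_equal(cfg$train$input_size, 128L)
})
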