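test_that("confusion counts match direct enumeration on small examples", {
  ones <- matrix(1, 4, 4)
  cc <- confusion_counts(ones, ones)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 16L, tn = 0L, fp = 0L, fn = 0L))
  gt <- matrix(c(1, 0, 1, 0), 2, 2)
  cc <- confusion_counts(1 - gt, gt) # complement prediction
  expect_equal(cc$tp, 0L)
  expect_equal(cc$tn, 0L)
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("metric formulas evaluate their defining ratios", {
  cc <- structure(list(tp = 3, fp = 1, fn = 2, tn = 0),
                  class = "confusion_counts")
  expect_equal(dice(cc), 6 / 9)
  expect_equal(iou(cc), 0.5)
  perfect <- confusion_counts(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_equal(dice(perfect), 1)
  expect_equal(iou(perfect), 1)
  expect_equal(accuracy(perfect), 1)
  none <- structure(list(tp = 0, fp = 0, fn = 5, tn = 11),
                    class = "confusion_counts")
  expect_equal(dice(none), 0)
  four <- structure(list(tp = 1, fp = 1, fn = 1, tn = 1),
                    class = "confusion_counts")
  expect_equal(accuracy(four), 0.5)
  expect_equal(precision(four), 0.5)
})

test_that("empty-mask conventions are applied and logged", {
  empty <- confusion_counts(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_message(v <- dice(empty), "convention")
  expect_equal(v, 1)
  expect_message(v <- iou(empty), "convention")
  expect_equal(v, 1)
  expect_message(p <- precision(empty), "NA")
  expect_true(is.na(p))
})

test_that("metrics agree with brute-force enumeration on random masks", {
  set.seed(41)
  for (i in 1:300) {
    pred <- random_mask(16, runif(1, 0.1, 0.9))
    gt <- random_mask(16, runif(1, 0.1, 0.9))
    cc <- confusion_counts(pred, gt)
    bf <- enumerate_confusion(pred, gt)
    expect_equal(cc$tp, bf$tp)
    expect_equal(cc$tn, bf$tn)
    expect_equal(cc$fp, bf$fp)
    expect_equal(cc$fn, bf$fn)
    d <- 2 * bf$tp / (bf$fp + bf$fn + 2 * bf$tp)
    j <- bf$tp / (bf$fp + bf$fn + bf$tp)
    expect_equal(dice(cc), d)
    expect_equal(iou(cc), j)
    expect_equal(accuracy(cc), (bf$tp + bf$tn) / 256)
    # algebraic identity and ordering between the two overlap metrics
    expect_equal(d, 2 * j / (1 + j))
    expect_gte(dice(cc), iou(cc))
  }
})

test_that("both overlap metrics reach 1 only for identical non-empty masks", {
  set.seed(7)
  m <- random_mask(8, 0.4)
  expect_equal(dice(confusion_counts(m, m)), 1)
  m2 <- m
  m2[1, 1] <- 1 - m2[1, 1]
  expect_lt(dice(confusion_counts(m2, m)), 1)
})

test_that("BCE-Dice loss matches closed forms", {
  g <- array(rbinom(64, 1, 0.4), c(8, 8, 1, 1))
  half <- array(0.5, c(8, 8, 1, 1))
  l <- bce_dice_loss(half, g)
  expect_equal(l$bce_part, log(2), tolerance = 1e-12)
  expect_equal(l$total, l$bce_part + l$dice_part)
  expect_gte(l$dice_part, 0)
  expect_lte(l$dice_part, 1)
  # perfect prediction (clamped): loss ~ 0
  expect_message(lp <- bce_dice_loss(g, g), "clamped")
  expect_lt(lp$total, 1e-5)
  expect_error(bce_dice_loss(half - 1, g), "0, 1")
})

test_that("loss decreases monotonically as p approaches the mask", {
  set.seed(11)
  g <- array(rbinom(256, 1, 0.3), c(16, 16, 1, 1))
  start <- 0.5 * g + 0.25
  losses <- sapply(seq(0, 0.98, length.out = 12), function(t) {
    p <- (1 - t) * start + t * g
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    dim(p) <- dim(g)
    bce_dice_loss(p, g)$total
  })
  expect_true(all(diff(losses) < 0))
})

test_that("summaries use per-image mean and sample standard deviation", {
  one <- data.frame(image_id = "a", dice = 0.9, iou = 0.8, accuracy = 0.99,
                    precision = 0.95)
  s1 <- summarize_metrics(one)
  expect_equal(s1$std, rep(0, 4))
  two <- rbind(one, data.frame(image_id = "b", dice = 0.7, iou = 0.6,
                               accuracy = 0.97, precision = 0.85))
  two$dice <- c(0.7, 0.8)
  s2 <- summarize_metrics(two)
  expect_equal(s2$mean[s2$metric == "dice"], 0.75)
  expect_equal(s2$std[s2$metric == "dice"], sd(c(0.7, 0.8)))
  expect_equal(s2$std[s2$metric == "dice"], 0.0707, tolerance = 1e-3)
})

test_that("improvement rows use the 100*(a-b)/b ratio", {
  expect_equal(improvement_pct(0.750, 0.745), 100 * 0.005 / 0.745)
  expect_equal(improvement_pct(0.750, 0.745), 0.671, tolerance = 1e-3)
  sums <- list(
    nau = data.frame(metric = c("dice", "iou"), mean = c(0.75, 0.613),
                     std = 0, n = 20),
    att = data.frame(metric = c("dice", "iou"), mean = c(0.73, 0.592),
                     std = 0, n = 20))
  it <- improvement_table(sums, "nau", "att")
  expect_equal(it$improvement_pct,
               100 * (sums$nau$mean - sums$att$mean) / sums$att$mean)
})

test_that("metric summaries export in the model/metric/mean/std CSV shape", {
  recs <- data.frame(image_id = c("a", "b"), dice = c(0.7, 0.8),
                     iou = c(0.6, 0.7), accuracy = c(0.9, 0.95),
                     precision = c(0.8, 0.9))
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(list(nau_net = summarize_metrics(recs)), f)
  tab <- read.csv(f)
  expect_equal(names(tab), c("model", "metric", "mean", "std"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$mean[tab$metric == "dice"], 0.75)
})
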