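# cohort-like feature matrix with a planted additive signal, for network
# level tests that need more width than the ZLU fixtures
wide_signal_data <- function(seed, n = 60, p = 8, informative = c(1, 5)) {
  set.seed(seed)
  x <- matrix(runif(n * p), ncol = p)
  score <- rowMeans(x[, informative, drop = FALSE])
  y <- as.integer(score > stats::median(score))
  list(x = x, y = y)
}

test_that("split_features produces contiguous equal blocks or fails loudly", {
  blocks <- split_features(320, 16)
  expect_length(blocks, 16)
  expect_true(all(lengths(blocks) == 20))
  expect_identical(unlist(blocks), 1:320)
  expect_identical(split_features(8, 1), list(1:8))
  err <- tryCatch(split_features(32, 5), error = conditionMessage)
  expect_match(err, "32")
  expect_match(err, "5")
})

test_that("layer configs are validated before any training", {
  d <- wide_signal_data(1)
  expect_error(znn(d$x, d$y, layers = c(3)), "not divisible")
  expect_error(znn(d$x, d$y, layers = c(4, 3)), "TSDs")
  expect_error(znn(d$x, d$y, layers = integer(0)), "positive")
})

test_that("dimension bookkeeping holds across random layer configs", {
  set.seed(11)
  for (rep in 1:5) {
    k1 <- sample(c(2, 4, 8), 1)
    k2 <- sample(c(1, 2, 4), 1) # divides 2*k1 for all choices
    d <- wide_signal_data(rep, n = 40, p = 8 * k1 / ifelse(k1 > 4, 2, 1))
    p <- ncol(d$x)
    if (p %% k1 != 0) next
    net <- znn(d$x, d$y, layers = c(k1, k2), max_epochs = 5)
    tsd1 <- zoomnn:::znn_forward(net, d$x, upto = 1)
    expect_equal(ncol(tsd1), 2 * k1)
    tsd2 <- zoomnn:::znn_forward(net, d$x, upto = 2)
    expect_equal(ncol(tsd2), 2 * k2)
    expect_equal(net$output$n_features, 2 * k2)
    expect_true(all(tsd2 >= 0 & tsd2 <= 1))
  }
})

test_that("a single-ZLU config degenerates to one unit plus the output NEWFM", {
  d <- wide_signal_data(2, p = 4, informative = c(1, 3))
  net <- znn(d$x, d$y, layers = 1, max_epochs = 10)
  expect_length(net$layers, 1)
  expect_length(net$layers[[1]], 1)
  expect_equal(net$output$n_features, 2)
  pred <- predict(net, d$x)
  expect_true(all(pred %in% 0:1))
  tsd <- predict(net, d$x, type = "tsd")
  expect_true(all(tsd >= 0 & tsd <= 1))
})

test_that("training is deterministic and the forward pass reproduces the fit accuracy", {
  d <- wide_signal_data(3)
  a <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 10)
  b <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 10)
  expect_identical(a$output$weights, b$output$weights)
  expect_identical(predict(a, d$x), predict(b, d$x))
  expect_equal(mean(predict(a, d$x) == d$y), a$train_accuracy)
})

test_that("the test path never consults the standard NEWFMs", {
  d <- wide_signal_data(4)
  net <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 10)
  ref <- predict(net, d$x, type = "tsd")
  # poison every standard model; predictions must be unchanged
  poisoned <- net
  for (i in seq_along(poisoned$layers)) {
    for (j in seq_along(poisoned$layers[[i]])) {
      u <- poisoned$layers[[i]][[j]]
      if (!u$subpattern_fallback && !u$refined_fallback) {
        u$standard$weights[] <- NA_real_
        poisoned$layers[[i]][[j]] <- u
      }
    }
  }
  expect_identical(predict(poisoned, d$x, type = "tsd"), ref)
})

test_that("layer accuracies report every ZLU layer plus the output layer", {
  d <- wide_signal_data(5)
  net <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 10)
  acc <- layer_accuracies(net, d$x, d$y)
  expect_equal(acc$layer, c("zlu_1", "zlu_2", "output"))
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
  expect_equal(acc$accuracy[3], net$train_accuracy)
})

test_that("ZNN models serialize and round-trip through JSON", {
  d <- wide_signal_data(6, n = 40)
  net <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(net, path)
  back <- read_model(path)
  expect_identical(predict(back, d$x, type = "tsd"),
                   predict(net, d$x, type = "tsd"))
  expect_identical(back$layer_config, net$layer_config)
})

test_that("tidiers summarise fitted networks", {
  d <- wide_signal_data(7, n = 40)
  net <- znn(d$x, d$y, layers = c(4, 2), max_epochs = 5)
  td <- tidy(net)
  expect_equal(nrow(td), 6)
  expect_true(all(td$n_mi + td$n_cci == 40))
  gl <- glance(net)
  expect_equal(gl$n_layers, 2)
  expect_equal(gl$n_zlus, 6)
})
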