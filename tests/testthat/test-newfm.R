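test_that("initial membership functions are evenly spaced with zero weight", {
  init <- zoomnn:::newfm_init_state(rbind(0, 1), m = 3)
  expect_equal(init$centers[, 1, 1], c(0, 0.5, 1))
  expect_equal(init$centers[, 2, 1], c(0, 0.5, 1))
  expect_true(all(init$weights == 0))
  # zero weights mean zero activation everywhere
  model <- random_newfm(p = 1)
  model$weights[] <- 0
  expect_equal(newfm_bswfm(model, 1, 0, seq(0, 1, 0.1)), rep(0, 11))
})

test_that("training separates separable 1-D data and is deterministic", {
  d <- separable_1d()
  fit <- newfm(d$x, d$y)
  expect_equal(fit$train_accuracy, 1)
  expect_lte(fit$epochs_run, 50)
  expect_equal(predict(fit, d$x), d$y)

  fit2 <- newfm(d$x, d$y)
  expect_identical(fit$centers, fit2$centers)
  expect_identical(fit$weights, fit2$weights)

  expect_error(newfm(d$x, rep(0, 4)), "both classes")
  expect_error(newfm(d$x[0, , drop = FALSE], integer(0)), "instances")
})

test_that("duplicating every instance preserves the decision pattern on a probe grid", {
  d <- separable_1d()
  fit1 <- newfm(d$x, d$y, max_epochs = 20)
  fit2 <- newfm(rbind(d$x, d$x), c(d$y, d$y), max_epochs = 20)
  grid <- matrix(seq(0.05, 0.95, length.out = 37), ncol = 1)
  expect_equal(predict(fit1, grid), predict(fit2, grid))
})

test_that("BSWFM activations and TSD outputs are bounded", {
  set.seed(3)
  for (rep in 1:20) {
    model <- random_newfm(p = 3)
    x <- matrix(runif(30, -0.5, 1.5), ncol = 3)
    sc <- predict(model, x, type = "score")
    expect_true(all(sc >= 0 & sc <= 3 + 1e-12))
    tsd <- predict(model, x, type = "tsd")
    expect_true(all(tsd >= 0 & tsd <= 1))
    b <- newfm_bswfm(model, 1, 1, seq(-1, 2, length.out = 50))
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("TSD agrees in sign with the classification decision", {
  set.seed(17)
  for (rep in 1:200) {
    model <- random_newfm(p = sample(1:5, 1))
    x <- matrix(runif(10 * model$n_features), ncol = model$n_features)
    sc <- predict(model, x, type = "score")
    tsd <- predict(model, x, type = "tsd")
    cls <- predict(model, x)
    pos <- sc[, 1] + sc[, 2] > 0
    expect_equal(tsd[pos] > 0.5, cls[pos] == 1)
    expect_equal(tsd[!pos], rep(0.5, sum(!pos)))
  }
})

test_that("a model with silent class-1 memberships always answers class 0", {
  model <- random_newfm(p = 2)
  model$weights[, 2, ] <- 0 # class 1 silent
  x <- matrix(runif(20), ncol = 2)
  expect_equal(predict(model, x), rep(0L, 10))
  # and the TSD collapses to the class-0 extreme wherever class 0 activates
  tsd <- predict(model, x, type = "tsd")
  sc <- predict(model, x, type = "score")
  expect_equal(tsd[sc[, 1] > 0], rep(0, sum(sc[, 1] > 0)))
})

test_that("a class-mirrored model classifies mirrored points oppositely", {
  set.seed(5)
  for (rep in 1:20) {
    model <- random_newfm(p = 1)
    # make class 1 the mirror image of class 0 about the range midpoint
    model$centers[, 2, 1] <- rev(1 - model$centers[, 1, 1])
    model$weights[, 2, 1] <- rev(model$weights[, 1, 1])
    x <- matrix(runif(50), ncol = 1)
    cls <- predict(model, x)
    cls_m <- predict(model, 1 - x)
    sc <- predict(model, x, type = "score")
    untied <- abs(sc[, 1] - sc[, 2]) > 1e-9
    expect_equal(cls[untied], 1L - cls_m[untied])
  }
})

test_that("feature selection ranks separating features above noise", {
  # identical class curves -> zero non-overlap area, ranked last
  model <- random_newfm(p = 2)
  model$centers[, 2, 1] <- model$centers[, 1, 1]
  model$weights[, 2, 1] <- model$weights[, 1, 1]
  sel <- newfm_select_features(model, 2)
  expect_equal(sel[2], 1L)
  expect_setequal(sel, 1:2)

  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    x <- cbind(runif(n), c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)))
    y <- rep(0:1, each = n / 2)
    fit <- newfm(x, y)
    if (newfm_select_features(fit, 1) == 2L) wins <- wins + 1
  }
  expect_gte(wins, 18)

  d <- separable_1d()
  fit <- newfm(d$x, d$y)
  expect_error(newfm_select_features(fit, 0), "between 1")
})

test_that("degenerate feature ranges are widened instead of failing", {
  x <- cbind(c(0.1, 0.2, 0.8, 0.9), rep(1, 4))
  y <- c(0, 0, 1, 1)
  fit <- newfm(x, y)
  expect_equal(fit$train_accuracy, 1)
  expect_true(all(fit$feature_ranges[2, ] > fit$feature_ranges[1, ]))
})

test_that("models serialize to JSON and round-trip bit-exactly", {
  set.seed(2)
  x <- matrix(runif(80), ncol = 4)
  y <- as.integer(x[, 2] > 0.5)
  fit <- newfm(x, y, n_select = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$centers, fit$centers)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$selected_features, fit$selected_features)
  expect_equal(predict(back, x, type = "tsd"), predict(fit, x, type = "tsd"))

  # tampered format field is rejected
  doc <- jsonlite::read_json(path)
  doc$format <- "zoomnn/newfm@99"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "format-version")
})
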