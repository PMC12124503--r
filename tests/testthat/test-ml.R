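test_that("train/test split is seeded, disjoint, exhaustive", {
  d <- data.frame(y = rep(0:1, each = 5), x = 1:10)
  sp <- split_train_test(d, 0.5, seed = 1)
  expect_equal(nrow(sp$train), 5)
  expect_equal(nrow(sp$test), 5)
  expect_setequal(c(sp$train$x, sp$test$x), 1:10)
  sp2 <- split_train_test(d, 0.5, seed = 1)
  expect_identical(sp$train, sp2$train)
  # stratified split keeps both classes in train
  sps <- split_train_test(d, 0.6, seed = 2, stratify_by = "y")
  expect_true(all(0:1 %in% sps$train$y))
  # tiny stratum: warning and fallback
  d2 <- data.frame(y = c(0, rep(1, 9)), x = 1:10)
  expect_warning(split_train_test(d2, 0.5, seed = 3, stratify_by = "y"),
                 "fewer than 2")
  expect_error(split_train_test(d, 1.5), "fraction")
})

test_that("mlp_forward matches hand arithmetic on a fixed 2-2-1 net", {
  model <- structure(list(
    W1 = matrix(c(0.5, -0.25, 0.1, 0.3), 2, 2), b1 = c(0.1, -0.2),
    W2 = matrix(c(0.7, -0.4), 2, 1), b2 = 0.05,
    center = c(0, 0), scale = c(1, 1), features = c("f1", "f2")),
    class = "mlp_model")
  x <- c(1, 2)
  h <- 1 / (1 + exp(-(c(0.5 * 1 - 0.25 * 2, 0.1 * 1 + 0.3 * 2) -
                        c(0.1, -0.2))))
  want <- 1 / (1 + exp(-(0.7 * h[1] - 0.4 * h[2] - 0.05)))
  expect_equal(mlp_forward(model, x), want, tolerance = 1e-12)
  # zero weights and biases give exactly 0.5
  z <- structure(list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
                      W2 = matrix(0, 2, 1), b2 = 0, center = c(0, 0),
                      scale = c(1, 1), features = c("f1", "f2")),
                 class = "mlp_model")
  expect_equal(mlp_forward(z, c(3, -4)), 0.5)
  expect_error(mlp_forward(z, c(1, 2, 3)), "features")
})

test_that("MLP learns a separable problem and is seed-reproducible", {
  d <- make_blobs(n = 500, seed = 61)
  sp <- split_train_test(d, 0.7, seed = 62, stratify_by = "y")
  feats <- setdiff(names(d), "y")
  m1 <- train_mlp(sp$train, "y", feats, epochs = 200, seed = 63)
  m2 <- train_mlp(sp$train, "y", feats, epochs = 200, seed = 63)
  expect_identical(m1$W1, m2$W1)
  ev <- evaluate_model(m1, sp$test)
  expect_gte(ev$accuracy, 90)
})

test_that("random forest learns, votes, and is seed-reproducible", {
  d <- make_blobs(n = 500, seed = 64)
  sp <- split_train_test(d, 0.7, seed = 65, stratify_by = "y")
  feats <- setdiff(names(d), "y")
  rf1 <- train_rf(sp$train, "y", feats, ntree = 150, seed = 66)
  rf2 <- train_rf(sp$train, "y", feats, ntree = 150, seed = 66)
  expect_identical(predict(rf1, sp$test, type = "prob"),
                   predict(rf2, sp$test, type = "prob"))
  expect_gte(evaluate_model(rf1, sp$test)$accuracy, 90)
  expect_error(train_rf(data.frame(y = rep(1, 20), x = rnorm(20)),
                        "y", "x"), "single outcome class")
})

test_that("null outcome yields near-majority accuracy", {
  set.seed(67)
  n <- 800
  d <- data.frame(y = rbinom(n, 1, 0.35),
                  f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  sp <- split_train_test(d, 0.7, seed = 68, stratify_by = "y")
  maj <- 100 * max(mean(sp$test$y), 1 - mean(sp$test$y))
  for (m in list(train_rf(sp$train, "y", c("f1", "f2", "f3"), ntree = 150,
                          seed = 69),
                 train_mlp(sp$train, "y", c("f1", "f2", "f3"), seed = 69))) {
    acc <- evaluate_model(m, sp$test)$accuracy
    expect_lt(abs(acc - maj), 7.5)
  }
})

test_that("majority vote of a hand-traceable stump ensemble", {
  # three stumps: two vote by f1 > 0, one by f2 > 0
  stump <- function(v) list(leaf = FALSE, var = v, split = 0,
                            left = list(leaf = TRUE, prob = 0),
                            right = list(leaf = TRUE, prob = 1))
  rf <- structure(list(trees = list(stump(1), stump(1), stump(2)),
                       features = c("f1", "f2"), outcome = "y", ntree = 3,
                       mtry = 1, gini = matrix(0, 2, 3)),
                  class = "rf_model")
  nd <- data.frame(f1 = c(1, 1, -1), f2 = c(-1, 1, 1))
  # votes: (2/3, 3/3, 1/3)
  expect_equal(predict(rf, nd, type = "prob"), c(2 / 3, 1, 1 / 3))
  expect_equal(predict(rf, nd), c(1L, 1L, 0L))
})

test_that("variable importance ranks a planted signal first", {
  set.seed(70)
  n <- 500
  a <- rbinom(n, 1, 0.5)
  d <- data.frame(y = a, A = a, n1 = rnorm(n), n2 = rbinom(n, 1, 0.5))
  sp <- split_train_test(d, 0.7, seed = 71, stratify_by = "y")
  rf <- train_rf(sp$train, "y", c("A", "n1", "n2"), ntree = 100, seed = 72)
  mda <- var_importance(rf, sp$test, "mean_decrease_accuracy", seed = 73)
  mdg <- var_importance(rf, sp$test, "mean_decrease_gini")
  expect_equal(mda$variable[1], "A")
  expect_equal(mdg$variable[1], "A")
  expect_equal(nrow(mda), 3)
  # constant feature permutes to zero drop
  d2 <- sp$test; d2$const <- 1
  rf2 <- train_rf(cbind(sp$train, const = 1), "y", c("A", "const"),
                  ntree = 50, seed = 74)
  mda2 <- var_importance(rf2, d2, "mean_decrease_accuracy", seed = 75)
  expect_equal(mda2$importance[mda2$variable == "const"], 0)
  # gini importance undefined for the network
  nn <- train_mlp(sp$train, "y", c("A", "n1"), epochs = 20, seed = 76)
  expect_error(var_importance(nn, sp$test, "mean_decrease_gini"),
               "random forests")
})

test_that("confusion metrics identities", {
  m <- confusion_metrics(c(rep(1, 60), rep(0, 40)),
                         c(rep(1, 50), rep(0, 10), rep(0, 30), rep(1, 10)))
  expect_equal(m$tp, 50); expect_equal(m$fp, 10)
  expect_equal(m$tn, 30); expect_equal(m$fn, 10)
  expect_equal(m$accuracy, 80)
  expect_equal(m$sensitivity, 100 * 50 / 60)
  expect_equal(m$specificity, 75)
  # perfect predictor
  p <- confusion_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_equal(c(p$accuracy, p$sensitivity, p$specificity), c(100, 100, 100))
  # all-negative predictor on balanced data
  q <- confusion_metrics(rep(0, 10), rep(0:1, 5))
  expect_equal(q$sensitivity, 0)
  expect_equal(q$specificity, 100)
})
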