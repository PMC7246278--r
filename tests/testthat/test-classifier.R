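test_that("window features match hand arithmetic", {
  f <- extract_features(c(0, 1, 0, -1))
  expect_equal(unname(f["mean"]), 0)
  expect_equal(unname(f["peak_to_peak"]), 2)
  expect_equal(unname(f["line_length"]), 3)   # |1| + |-1| + |-1|
  expect_equal(unname(f["energy"]), 2)
  expect_named(f, feature_names())
})

test_that("a constant window degrades gracefully to zero features", {
  f <- extract_features(rep(4.2, 50))
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  expect_equal(unname(f["zero_crossings"]), 0)
  expect_equal(unname(f["peak_to_peak"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("even-order features are invariant to negation", {
  set.seed(81)
  w <- rnorm(160)
  f1 <- extract_features(w)
  f2 <- extract_features(-w)
  for (nm in c("sd", "kurtosis", "peak_to_peak", "line_length", "energy",
               "zero_crossings"))
    expect_equal(f2[[nm]], f1[[nm]])
  expect_equal(f2[["skewness"]], -f1[["skewness"]])
})

test_that("mean-removed features ignore amplitude offsets", {
  set.seed(82)
  w <- rnorm(160)
  f1 <- extract_features(w)
  f2 <- extract_features(w + 100)
  for (nm in c("sd", "skewness", "kurtosis", "peak_to_peak", "line_length",
               "zero_crossings"))
    expect_equal(f2[[nm]], f1[[nm]])
  expect_equal(f2[["mean"]], f1[["mean"]] + 100)
})

make_clouds <- function(n_per_class, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
             matrix(rnorm(n_per_class * 2, mean = sep), ncol = 2))
  df <- as.data.frame(x)
  names(df) <- c("f1", "f2")
  df$label <- rep(c("a", "b"), each = n_per_class)
  df
}

test_that("stratified split gives exact 70/30 class-balanced partitions", {
  df <- make_clouds(400, seed = 2)            # 400 per class
  sp <- split_train_test(df, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 560L)
  expect_equal(nrow(sp$test), 240L)
  expect_equal(as.integer(table(sp$train$label)), c(280L, 280L))
  expect_equal(as.integer(table(sp$test$label)), c(120L, 120L))

  # deterministic for a fixed seed; together they reconstruct the dataset
  sp2 <- split_train_test(df, 0.7, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(df)))

  singleton <- df[c(1, 2, 801), ]
  expect_error(split_train_test(singleton, 0.7), "fewer than 2")
})

test_that("backprop training separates Gaussian clouds perfectly", {
  df <- make_clouds(50, sep = 6, seed = 3)
  m <- train_mlp(df, seed = 7)
  pred <- predict(m, df[, c("f1", "f2")])
  expect_equal(mean(pred$class == df$label), 1)
  expect_lte(length(m$loss_trace), 500L)
})

test_that("training is deterministic and inert at zero learning rate", {
  df <- make_clouds(30, seed = 4)
  m1 <- train_mlp(df, seed = 13)
  m2 <- train_mlp(df, seed = 13)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$W1, m2$W1)

  frozen_short <- train_mlp(df, learning_rate = 0, cycles = 2, seed = 13)
  frozen_long <- train_mlp(df, learning_rate = 0, cycles = 400, seed = 13)
  expect_identical(frozen_short$W1, frozen_long$W1)  # weights never move
  expect_true(all(diff(frozen_long$loss_trace) == 0))
})

test_that("loss decreases monotonically at a small learning rate", {
  df <- make_clouds(40, sep = 4, seed = 6)
  m <- train_mlp(df, learning_rate = 0.01, momentum = 0, epsilon = 0,
                 cycles = 300, seed = 17)
  expect_true(all(diff(m$loss_trace) <= 1e-12))
})

test_that("prediction memorizes separable training data and is consistent", {
  df <- make_clouds(40, sep = 6, seed = 8)
  m <- train_mlp(df, seed = 19)
  X <- df[, c("f1", "f2")]
  batch <- predict(m, X)
  expect_equal(batch$class, df$label)
  # batch prediction equals per-item prediction
  one <- predict(m, unlist(X[17, ]))
  expect_equal(one$class, batch$class[17])
  expect_equal(one$confidence, batch$confidence[17])

  expect_error(predict(m, matrix(1, 1, 5)), "dimension")
})

test_that("a zero-weight network is maximally uncertain, tie to first class", {
  m <- structure(
    list(W1 = matrix(0, 2, 3), b1 = numeric(3), W2 = matrix(0, 3, 2),
         b2 = numeric(2), classes = c("background", "spike"),
         center = c(f1 = 0, f2 = 0), scale = c(f1 = 1, f2 = 1),
         feature_names = c("f1", "f2")),
    class = "mlp_model")
  p <- predict(m, c(f1 = 3, f2 = -2))
  expect_equal(p$class, "background")
  expect_equal(p$confidence, 0.5)
})

test_that("model JSON round-trips bit-exactly through write/read", {
  df <- make_clouds(30, seed = 9)
  m <- train_mlp(df, seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(m, path)
  back <- read_mlp(path)
  expect_equal(back$W1, m$W1)
  expect_equal(back$b2, m$b2)
  expect_equal(back$classes, m$classes)
  X <- df[, c("f1", "f2")]
  expect_equal(predict(back, X), predict(m, X))
})

test_that("an independent learner agrees the fixture dataset is separable", {
  # nnet (BFGS-trained single-hidden-layer network) as a cross-check that
  # perfect held-out accuracy reflects the data, not our trainer
  df <- fixture_dataset()
  sp <- split_train_test(df, 0.7, seed = 5)
  ctr <- colMeans(sp$train[, feature_names()])
  scl <- sapply(sp$train[, feature_names()], sd)
  norm <- function(d) {
    out <- as.data.frame(scale(d[, feature_names()], ctr, scl))
    out$label <- factor(d$label)
    out
  }
  fit <- nnet::nnet(label ~ ., data = norm(sp$train), size = 5,
                    decay = 1e-4, maxit = 300, trace = FALSE)
  acc <- mean(predict(fit, norm(sp$test), type = "class") == sp$test$label)
  expect_equal(acc, 1)
})
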