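# Network module: loss/decay/noise arithmetic, reported layer shapes, gradient
# flow, determinism, and the literal-mode no-signal property.

test_that("cross-entropy matches its closed forms and a brute-force oracle", {
  Y <- diag(4)
  expect_lt(cross_entropy(Y, Y), 1e-10)
  U <- matrix(0.25, 5, 4)
  T5 <- cbind(1, matrix(0, 5, 3))
  expect_equal(cross_entropy(T5, U), log(4), tolerance = 1e-12)
  # independently coded double loop on random tables
  withr::with_seed(3, {
    p <- matrix(rexp(80), 20, 4)
    p <- p / rowSums(p)
    y <- sample(0:3, 20, replace = TRUE)
    Yr <- matrix(0, 20, 4); Yr[cbind(1:20, y + 1)] <- 1
    acc <- 0
    for (i in 1:20) for (c in 1:4) acc <- acc - Yr[i, c] * log(p[i, c])
    expect_equal(cross_entropy(Yr, p), acc / 20, tolerance = 1e-12)
  })
  expect_error(cross_entropy(Y, U), class = "qtremor_structural_error")
  expect_error(cross_entropy(T5, U * 2), class = "qtremor_domain_error")
})

test_that("polynomial decay interpolates lr0 to end_lr and clamps", {
  cfg <- list(lr0 = 1e-3, end_lr = 1e-5, power = 1, horizon = 100)
  expect_equal(polynomial_lr(0, cfg), 1e-3)
  expect_equal(polynomial_lr(100, cfg), 1e-5)
  expect_equal(polynomial_lr(50, cfg), (1e-3 + 1e-5) / 2)
  expect_equal(polynomial_lr(250, cfg), 1e-5)
  cfg$power <- 2
  expect_equal(polynomial_lr(50, cfg), 1e-5 + (1e-3 - 1e-5) * 0.25)
})

test_that("label noise flips the right fraction to different classes", {
  y <- rep(0:3, each = 250)
  expect_identical(add_label_noise(y, 0, seed = 1), y)
  y1 <- add_label_noise(y, 1, seed = 1)
  expect_true(all(y1 != y))
  expect_true(all(y1 %in% 0:3))
  y05 <- add_label_noise(y, 0.2, seed = 2)
  frac <- mean(y05 != y)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / 1000))
  expect_identical(add_label_noise(y, 0.2, seed = 2), y05)
  expect_error(add_label_noise(c(0, 9), 0.1), class = "qtremor_domain_error")
})

test_that("the classical baseline reproduces the reported layer shapes", {
  spec <- model_spec("classical", quantvolution = NULL)
  m <- build_model(spec, seed = 1)
  x <- array(withr::with_seed(1, runif(32 * 215 * 2)) - 0.5, c(32, 215, 1, 2))
  p <- qtremor:::model_forward(m, x, train = FALSE)
  # first conv output 32 x 215 x 16; pool reduces to 16 x 107 x 16
  conv1 <- m$layers[[1]]
  expect_equal(c(conv1$cache$H, conv1$cache$W, conv1$F), c(32L, 215L, 16L))
  pool <- Find(function(l) l$type == "pool", m$layers)
  expect_equal(c(pool$cache$H2, pool$cache$W2), c(16L, 107L))
  conv2 <- m$layers[[5]]
  expect_equal(c(conv2$cache$H, conv2$cache$W, conv2$F), c(16L, 107L, 16L))
  # flatten feeds dense-32 from the full 16*107*16 shape chain
  dense32 <- Find(function(l) l$type == "dense", m$layers)
  expect_equal(dense32$in_dim, 16L * 107L * 16L)
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(colSums(p), c(1, 1), tolerance = 1e-9)
})

test_that("the hybrid head emits a probability 4-vector", {
  spec <- model_spec("hybrid")   # quantvolution 2x2 + functional QuantClass
  m <- build_model(spec, seed = 2)
  x <- array(withr::with_seed(2, runif(16 * 107 * 4 * 3)) - 0.5, c(16, 107, 4, 3))
  p <- qtremor:::model_forward(m, x, train = FALSE)
  expect_equal(dim(p), c(4L, 3L))
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-9)
})

test_that("evaluation uses argmax with lowest-index tie-break", {
  # a constant uniform predictor on a balanced set predicts class 0 throughout
  mock <- structure(list(layers = list(qtremor:::layer_flatten(), qtremor:::layer_softmax())),
                    class = "qtremor_model")
  x <- array(0, c(1, 1, 4, 8))
  y <- rep(0:3, 2)
  ev <- evaluate_model(mock, x, y)
  expect_equal(ev$accuracy, 0.25)               # the class-0 fraction
  expect_equal(ev$loss, log(4), tolerance = 1e-12)
  # loss equals the cross_entropy oracle on the same predictions
  p <- qtremor:::model_forward(mock, x, FALSE)
  expect_equal(ev$loss, cross_entropy(t(qtremor:::one_hot(y)), t(p)))
  expect_error(evaluate_model(mock, x, integer(0)), class = "qtremor_domain_error")
})

make_tiny_data <- function(n_per = 6, seed = 7) {
  # 12 x 16 images, 4 classes by quadrant brightness: cheap but learnable
  withr::with_seed(seed, {
    n <- 4 * n_per
    y <- rep(0:3, n_per)
    x <- array(0, c(12, 16, 1, n))
    for (i in seq_len(n)) {
      base <- matrix(rnorm(12 * 16, 0, 0.05), 12, 16)
      r <- if (y[i] %in% c(2, 3)) 7:12 else 1:6
      c <- if (y[i] %in% c(1, 3)) 9:16 else 1:8
      base[r, c] <- base[r, c] + 0.8
      x[, , 1, i] <- base
    }
    split <- factor(rep(c("train", "train", "train", "train", "val", "test"),
                        length.out = n)[sample(n)],
                    levels = c("train", "val", "test"))
    list(x = x, y = y, split = split)
  })
}

test_that("training is deterministic and runs the fixed epoch count", {
  dat <- make_tiny_data()
  spec <- model_spec("classical", quantvolution = NULL, input_shape = c(12L, 16L))
  r1 <- train(build_model(spec, seed = 3), dat,
              train_config(epochs = 4, seed = 5, label_noise = 0.05))
  r2 <- train(build_model(spec, seed = 3), dat,
              train_config(epochs = 4, seed = 5, label_noise = 0.05))
  expect_identical(r1$epoch_loss, r2$epoch_loss)
  expect_length(r1$epoch_loss, 4L)
  expect_identical(r1$metrics, r2$metrics)
  expect_true(all(vapply(r1$metrics, function(m) m$loss >= 0 &&
                           m$accuracy >= 0 && m$accuracy <= 1, logical(1))))
})

test_that("a trainable model improves on separable data", {
  dat <- make_tiny_data()
  spec <- model_spec("hybrid", quantvolution = NULL, input_shape = c(12L, 16L),
                     fc_widths = c(32L, 16L, 8L, 2L))
  m <- build_model(spec, seed = 4)
  res <- train(m, dat, train_config(epochs = 30, lr0 = 3e-3, label_noise = 0,
                                    seed = 6))
  expect_lt(tail(res$epoch_loss, 1), res$epoch_loss[1])
  expect_gt(res$metrics$train$accuracy, 0.5)
})

test_that("the literal head passes no gradient to the network", {
  dat <- make_tiny_data()
  spec <- model_spec("hybrid", quantvolution = NULL, input_shape = c(12L, 16L),
                     head_mode = "literal", fc_widths = c(32L, 16L, 8L, 2L))
  m <- build_model(spec, seed = 4)
  get_dense_w <- function() {
    lapply(Filter(function(l) l$type %in% c("dense", "qclass"), m$layers),
           function(l) l$params)
  }
  before <- get_dense_w()
  res <- train(m, dat, train_config(epochs = 3, label_noise = 0, seed = 6))
  expect_identical(get_dense_w(), before)       # flat head: zero gradient
  expect_equal(res$metrics$train$loss, log(4), tolerance = 1e-9)
})

test_that("train results serialize to JSON + CSV", {
  dat <- make_tiny_data()
  spec <- model_spec("classical", quantvolution = NULL, input_shape = c(12L, 16L))
  res <- train(build_model(spec, seed = 3), dat, train_config(epochs = 2, seed = 5))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "result.json")
  write_train_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metrics$test$accuracy, res$metrics$test$accuracy)
  trace <- utils::read.csv(file.path(dir, "result_trace.csv"))
  expect_equal(trace$loss, res$epoch_loss)
})

test_that("model weights round-trip through the binary container", {
  dat <- make_tiny_data()
  spec <- model_spec("hybrid", quantvolution = NULL, input_shape = c(12L, 16L),
                     fc_widths = c(16L, 8L, 8L, 2L))
  m <- build_model(spec, seed = 9)
  train(m, dat, train_config(epochs = 2, seed = 9))
  path <- file.path(withr::local_tempdir(), "weights.bin")
  write_model_weights(m, path)
  m2 <- build_model(spec, seed = 123)           # different init
  read_model_weights(m2, path)
  x <- dat$x[, , , 1:4, drop = FALSE]
  expect_equal(qtremor:::model_forward(m2, x), qtremor:::model_forward(m, x),
               tolerance = 1e-12)
})
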