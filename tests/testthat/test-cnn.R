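test_that("network outputs valid probability vectors of the task dimension", {
  m2 <- build_model(tiny_model_spec("presence"), seed = 1L)
  m3 <- build_model(tiny_model_spec("count"), seed = 1L)
  withr::with_seed(2, x <- array(runif(12 * 12 * 24), c(12, 12, 24, 1)))
  p2 <- predict_cnn(m2, x)
  p3 <- predict_cnn(m3, x)
  expect_equal(ncol(p2), 2L)
  expect_equal(ncol(p3), 3L)
  expect_equal(colnames(p3), c("0", "1", "ge2"))
  expect_equal(rowSums(p2), 1, tolerance = 1e-6)
  expect_equal(rowSums(p3), 1, tolerance = 1e-6)
  expect_true(all(p2 >= 0) && all(p3 >= 0))
  expect_gt(n_parameters(m2), 0L)
})

test_that("degenerate all-zero input still yields a finite probability row", {
  m <- build_model(tiny_model_spec(), seed = 3L)
  p <- predict_cnn(m, array(0, c(12, 12, 24, 1)))
  expect_false(anyNA(p))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("prediction is batch-invariant and deterministic", {
  m <- build_model(tiny_model_spec(), seed = 4L)
  withr::with_seed(5, xs <- lapply(1:4, function(i)
    array(runif(12 * 12 * 24), c(12, 12, 24, 1))))
  pb <- predict_cnn(m, xs)
  for (i in 1:4) {
    expect_equal(pb[i, ], predict_cnn(m, xs[[i]])[1, ])
  }
  expect_identical(pb, predict_cnn(m, xs))
})

test_that("incompatible shapes are rejected at build or predict time", {
  bad <- model_spec("presence", input_shape = c(6L, 6L, 4L),
                    conv_blocks = list(list(channels = 2L,
                                            kernel = c(3L, 3L, 9L),
                                            pool = c(2L, 2L, 2L))),
                    input_pool_z = 1L)
  expect_error(build_model(bad), "incompatible")
  m <- build_model(tiny_model_spec(), seed = 1L)
  expect_error(predict_cnn(m, array(0, c(10, 10, 24, 1))))
})

test_that("analytic gradients agree with numerical differentiation", {
  spec <- model_spec("count", input_shape = c(7L, 7L, 10L),
                     conv_blocks = list(
                       list(channels = 2L, kernel = c(2L, 2L, 3L),
                            pool = c(2L, 2L, 2L)),
                       list(channels = 3L, kernel = c(2L, 2L, 2L),
                            pool = c(1L, 1L, 1L))),
                     dense_widths = 4L, input_pool_z = 1L)
  m <- build_model(spec, seed = 6L)
  withr::with_seed(7, x <- array(runif(7 * 7 * 10), c(7, 7, 10, 1)))
  y <- 3L
  sg <- asariscan:::cnn_sample_grads(m, x, y)
  loss_at <- function(model) {
    f <- asariscan:::cnn_forward(model, x, keep_cache = FALSE)
    asariscan:::xent_loss_grad(f$logits, y)$loss
  }
  eps <- 1e-6
  withr::with_seed(8, {
    for (li in seq_along(m$layers)) {
      if (is.null(m$layers[[li]]$W)) next
      for (k in sample(length(m$layers[[li]]$W), 3L)) {
        mp <- m; mp$layers[[li]]$W[k] <- mp$layers[[li]]$W[k] + eps
        mm <- m; mm$layers[[li]]$W[k] <- mm$layers[[li]]$W[k] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(sg$grads[[li]]$dW[k], num, tolerance = 1e-4)
      }
      for (k in seq_along(m$layers[[li]]$b)) {
        mp <- m; mp$layers[[li]]$b[k] <- mp$layers[[li]]$b[k] + eps
        mm <- m; mm$layers[[li]]$b[k] <- mm$layers[[li]]$b[k] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(sg$grads[[li]]$db[k], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training drives loss toward zero on separable toy voxels", {
  ds <- toy_dataset(24, seed = 21L)
  tr <- cnn_dataset(lapply(1:16, ds$get_x), ds$y[1:16])
  va <- cnn_dataset(lapply(17:24, ds$get_x), ds$y[17:24])
  m <- build_model(tiny_model_spec(), seed = 9L)
  m <- train_cnn(m, tr, va, train_config(batch_size = 4L, lr = 5e-3,
                                         max_epochs = 25L, patience = 24L,
                                         seed = 10L))
  h <- attr(m, "history")
  expect_equal(h$train_acc[nrow(h)], 1.0)
  expect_lt(h$train_loss[nrow(h)], 0.2)
})

test_that("network memorizes a small sample set (capacity check)", {
  ds <- toy_dataset(20, seed = 31L)
  m <- build_model(tiny_model_spec(), seed = 11L)
  # train == val: monitors the memorized loss itself
  m <- train_cnn(m, ds, ds, train_config(batch_size = 4L, lr = 5e-3,
                                         max_epochs = 30L, patience = 29L,
                                         seed = 12L))
  h <- attr(m, "history")
  expect_lt(min(h$train_loss), 0.15)
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- toy_dataset(12, seed = 41L)
  m <- build_model(tiny_model_spec(), seed = 13L)
  # lr 0: nothing changes, validation never improves after the first epoch
  m0 <- train_cnn(m, ds, ds, train_config(batch_size = 4L, lr = 0,
                                          max_epochs = 20L, patience = 3L,
                                          seed = 14L))
  expect_equal(nrow(attr(m0, "history")), 1L + 3L)
  expect_equal(attr(m0, "best_epoch"), 1L)
  m1 <- train_cnn(m, ds, ds, train_config(batch_size = 4L, lr = 0,
                                          max_epochs = 20L, patience = 0L,
                                          seed = 14L))
  expect_equal(nrow(attr(m1, "history")), 1L)
})

test_that("training is reproducible under a fixed seed", {
  ds <- toy_dataset(12, seed = 51L)
  cfg <- train_config(batch_size = 3L, lr = 3e-3, max_epochs = 4L,
                      patience = 3L, seed = 15L)
  m1 <- train_cnn(build_model(tiny_model_spec(), seed = 16L),
                  ds, ds, cfg)
  m2 <- train_cnn(build_model(tiny_model_spec(), seed = 16L),
                  ds, ds, cfg)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(m1$layers, m2$layers)
})

test_that("empty splits and unknown labels are rejected", {
  ds <- toy_dataset(6, seed = 61L)
  empty <- cnn_dataset(list(), character(0))
  m <- build_model(tiny_model_spec(), seed = 17L)
  expect_error(train_cnn(m, empty, ds, train_config()), "empty")
  bad <- cnn_dataset(lapply(1:6, ds$get_x), rep("maybe", 6))
  expect_error(train_cnn(m, bad, ds, train_config()), "unknown class")
})

test_that("training on permuted labels stays near chance on held-out data", {
  withr::with_seed(71, {
    xs <- lapply(1:40, function(i) toy_voxel(i %% 2 == 0))
    ys <- sample(ifelse(seq_len(40) %% 2 == 0, "presence", "absence"))
  })
  tr <- cnn_dataset(xs[1:24], ys[1:24])
  va <- cnn_dataset(xs[25:32], ys[25:32])
  te <- cnn_dataset(xs[33:40], ys[33:40])
  m <- build_model(tiny_model_spec(), seed = 18L)
  m <- train_cnn(m, tr, va, train_config(batch_size = 4L, lr = 3e-3,
                                         max_epochs = 8L, patience = 7L,
                                         seed = 19L))
  probs <- predict_cnn(m, te)
  acc <- mean(attr(probs, "class_ids") == te$y)
  # binomial n=8 null: accuracy within [0, 7/8] with prob > 0.99
  expect_lte(acc, 7 / 8)
})
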