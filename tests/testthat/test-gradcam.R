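# toy two-channel network with hand-settable weights: 1x1x1 conv (so the
# feature maps equal scaled copies of the input), no pooling, global
# mean+max head, linear classifier
toy_cam_model <- function() {
  spec <- model_spec("presence", input_shape = c(4L, 4L, 3L),
                     conv_blocks = list(list(channels = 2L,
                                             kernel = c(1L, 1L, 1L),
                                             pool = c(1L, 1L, 1L))),
                     input_pool_z = 1L)
  m <- build_model(spec, seed = 1L)
  m$layers[[1]]$W[] <- c(1, 2)          # ch1 = x, ch2 = 2x
  m$layers[[1]]$b[] <- 0
  m$layers[[3]]$W[] <- matrix(c(0.3, -0.2, 0.5, 0.1,    # -> class 1
                                0.4, 0.6, -0.1, 0.2),   # -> class 2
                              4, 2)
  m$layers[[3]]$b[] <- 0
  m
}

test_that("Grad-CAM heat matches the closed-form weighted sum on a toy net", {
  m <- toy_cam_model()
  withr::with_seed(2, x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1)))
  att <- grad_cam(m, x, target_class = 2L)
  # hand computation: A_k = k * x (positive input, slope-1 region);
  # d logit2 / d A_k = V[k,2]/m everywhere + V[2+k,2] at the argmax voxel
  V <- m$layers[[3]]$W
  mvox <- 4 * 4 * 3
  alpha <- c(V[1, 2] / mvox + V[3, 2] / mvox,
             V[2, 2] / mvox + V[4, 2] / mvox)
  cam <- alpha[1] * x[, , , 1] + alpha[2] * (2 * x[, , , 1])
  cam[cam < 0] <- 0
  expect_gt(max(cam), 0)
  expect_equal(att$heat, cam / max(cam), tolerance = 1e-12)
  expect_equal(att$target_class, "presence")
})

test_that("heat is rectified, max-normalized, and input-shaped", {
  m <- build_model(tiny_model_spec(), seed = 5L)
  withr::with_seed(6, x <- array(runif(12 * 12 * 24), c(12, 12, 24, 1)))
  att <- grad_cam(m, x, target_class = "presence")
  expect_equal(dim(att$heat), c(12L, 12L, 24L))
  expect_gte(min(att$heat), 0)
  expect_equal(max(att$heat), 1)
})

test_that("heat ignores shifts of the non-target logit", {
  m <- toy_cam_model()
  withr::with_seed(7, x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1)))
  h1 <- grad_cam(m, x, target_class = 2L)$heat
  m$layers[[3]]$b[1] <- m$layers[[3]]$b[1] + 100   # other class only
  h2 <- grad_cam(m, x, target_class = 2L)$heat
  expect_identical(h1, h2)
})

test_that("all-zero gradients yield an all-zero heat with a warning", {
  m <- toy_cam_model()
  m$layers[[3]]$W[, 2] <- 0     # target logit constant in the features
  withr::with_seed(8, x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1)))
  expect_warning(att <- grad_cam(m, x, target_class = 2L), "all-zero")
  expect_true(all(att$heat == 0))
})

test_that("invalid layer or class requests are rejected", {
  m <- build_model(tiny_model_spec(), seed = 9L)
  x <- array(0.1, c(12, 12, 24, 1))
  expect_error(grad_cam(m, x, 1L, layer = 99L), "not a convolutional")
  expect_error(grad_cam(m, x, "mussel"), "unknown target class")
})

test_that("trained model's attention lands on the blob (logged sanity check)", {
  ds <- toy_dataset(24, seed = 81L)
  m <- build_model(tiny_model_spec(), seed = 10L)
  m <- train_cnn(m, ds, ds, train_config(batch_size = 4L, lr = 5e-3,
                                         max_epochs = 12L, patience = 11L,
                                         seed = 11L))
  withr::with_seed(12, {
    x <- array(abs(rnorm(12 * 12 * 24, sd = 0.02)), c(12, 12, 24, 1))
    x[5:9, 5:9, 10:16, 1] <- x[5:9, 5:9, 10:16, 1] + 0.5
  })
  att <- grad_cam(m, x, target_class = "presence")
  peak <- which(att$heat == max(att$heat), arr.ind = TRUE)[1, ]
  inside <- peak[1] %in% 3:11 && peak[2] %in% 3:11 && peak[3] %in% 7:19
  cat(sprintf("\n[grad-cam sanity] peak at (%d,%d,%d), inside blob box: %s\n",
              peak[1], peak[2], peak[3], inside))
  expect_gte(min(att$heat), 0)   # hard contracts only
  expect_equal(max(att$heat), 1)
})

test_that("depth averaging yields ceil(nz/block) panels and conserves the mean", {
  withr::with_seed(13, a <- array(runif(6 * 5 * 693), c(6, 5, 693)))
  panels <- z_average_panels(a, block = 10L)
  expect_length(panels, 70L)                       # ceil(693 / 10)
  slices <- attr(panels, "slices")
  expect_equal(slices[70], 3L)                     # remainder panel
  expect_equal(panels[[70]], rowMeans(a[, , 691:693, drop = FALSE],
                                      dims = 2L))
  # weighted mean over panels equals the volume mean
  wm <- Reduce(`+`, Map(`*`, panels, slices)) / sum(slices)
  expect_equal(mean(wm), mean(a), tolerance = 1e-12)
})

test_that("depth averaging degenerate blocks behave as documented", {
  withr::with_seed(14, a <- array(runif(4 * 4 * 6), c(4, 4, 6)))
  p1 <- z_average_panels(a, block = 1L)
  expect_length(p1, 6L)
  expect_equal(p1[[3]], a[, , 3])                  # identity
  pall <- z_average_panels(a, block = 100L)
  expect_length(pall, 1L)
  expect_equal(pall[[1]], rowMeans(a, dims = 2L))
  const <- array(3.5, c(4, 4, 6))
  expect_true(all(vapply(z_average_panels(const, 4L),
                         function(m) all(m == 3.5), logical(1))))
})

test_that("trilinear resize interpolates ramps exactly", {
  ramp <- array(rep(seq(0, 1, length.out = 5), each = 4), c(4, 1, 5))
  dim(ramp) <- c(4, 1, 5)
  up <- resize_trilinear(ramp, c(4L, 1L, 9L))
  expect_equal(up[1, 1, ], seq(0, 1, length.out = 9), tolerance = 1e-12)
  same <- resize_trilinear(ramp, c(4L, 1L, 5L))
  expect_identical(same, ramp)
})

test_that("explanation files encode provenance and regenerate byte-identically", {
  m <- toy_cam_model()
  withr::with_seed(15, x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1)))
  att <- grad_cam(m, x, target_class = 2L)
  out <- withr::local_tempdir()
  paths <- render_explanation(x, att, out, bucket_id = "A3", x0 = 75L,
                              y0 = 50L, predicted = "presence",
                              actual = "absence", block = 2L)
  expect_true(file.exists(paths$png))
  expect_true(file.exists(paths$csv))
  expect_match(basename(paths$png),
               "A3_x075_y050_pred-presence_true-absence")
  csv1 <- readBin(paths$csv, "raw", file.size(paths$csv))
  render_explanation(x, att, out, "A3", 75L, 50L, "presence", "absence",
                     block = 2L)
  csv2 <- readBin(paths$csv, "raw", file.size(paths$csv))
  expect_identical(csv1, csv2)
  expect_error(render_explanation(x, att, out, "A3", 0L, 0L, "p", "a",
                                  block = 2L) -> ., NA)
  bad <- att; bad$heat <- bad$heat[1:2, , ]
  expect_error(render_explanation(x, bad, out, "A3", 0L, 0L, "p", "a"),
               "shapes differ")
})
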