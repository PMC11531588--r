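test_that("window enumeration counts and order follow the stride formula", {
  org <- enumerate_windows(125, 100, 25, 1)
  expect_equal(nrow(org), 101L * 76L)           # 7,676 overlapping windows
  tiles <- enumerate_windows(125, 100, 25, 25)
  expect_equal(nrow(tiles), 20L)                # 5 x 4 bucket tiling
  expect_equal(nrow(enumerate_windows(25, 25, 25)), 1L)
  expect_equal(enumerate_windows(25, 25, 25), data.frame(x0 = 0L, y0 = 0L))
  # row-major, x fastest
  expect_equal(org$x0[1:3], c(0L, 1L, 2L))
  expect_equal(org$y0[1:3], c(0L, 0L, 0L))
  expect_error(enumerate_windows(20, 100, 25), "exceeds")
})

test_that("window-count formula matches enumeration on a parameter grid", {
  for (nx in c(10L, 17L, 25L)) for (w in c(5L, 10L)) for (s in c(1L, 3L, 5L)) {
    org <- enumerate_windows(nx, nx, w, s)
    expected <- (length(seq(0L, nx - w, by = s)))^2
    expect_equal(nrow(org), expected)
  }
})

test_that("distance-threshold labeling follows the strict 11-pixel rule", {
  org <- data.frame(x0 = 0L, y0 = 0L)
  lab_at <- function(x, y) {
    pos <- data.frame(bucket_id = "b", x = x, y = y, z = 0L, kind = "clam")
    assign_labels(org, pos, w = 25L, threshold_px = 11)$n_clams
  }
  expect_equal(lab_at(12, 12), 1L)   # inside the footprint
  expect_equal(lab_at(36, 12), 0L)   # distance 12 from boundary pixel 24
  expect_equal(lab_at(34, 12), 1L)   # distance 10 < 11
  expect_equal(lab_at(35, 12), 0L)   # distance exactly 11: strict <
})

test_that("labeling matches a brute-force point-to-rectangle oracle", {
  brute_count <- function(x0, y0, w, px, py, thr) {
    # exhaustive nearest-pixel search over the footprint
    d2 <- outer((x0:(x0 + w - 1) - px)^2, (y0:(y0 + w - 1) - py)^2, `+`)
    sqrt(min(d2)) < thr
  }
  withr::with_seed(11, {
    for (rep in 1:60) {
      nx <- sample(15:40, 1); ny <- sample(15:40, 1)
      w <- sample(5:min(12, nx, ny), 1)
      n_pos <- sample(1:6, 1)
      pos <- data.frame(bucket_id = "b",
                        x = sample(0:(nx - 1), n_pos, TRUE),
                        y = sample(0:(ny - 1), n_pos, TRUE),
                        z = 0L, kind = "clam")
      org <- enumerate_windows(nx, ny, w, sample(1:3, 1))
      thr <- sample(c(3, 7, 11), 1)
      lab <- assign_labels(org, pos, w, thr)
      oracle <- integer(nrow(org))
      for (i in seq_len(nrow(org))) {
        for (j in seq_len(n_pos)) {
          oracle[i] <- oracle[i] + brute_count(org$x0[i], org$y0[i], w,
                                               pos$x[j], pos$y[j], thr)
        }
      }
      expect_identical(lab$n_clams, oracle)
    }
  })
})

test_that("enlarging the threshold never removes an attribution", {
  withr::with_seed(3, {
    pos <- data.frame(bucket_id = "b", x = sample(0:39, 8, TRUE),
                      y = sample(0:39, 8, TRUE), z = 0L, kind = "clam")
    org <- enumerate_windows(40, 40, 10, 2)
    prev <- rep(0L, nrow(org))
    for (thr in c(1, 4, 8, 12, 20)) {
      cur <- assign_labels(org, pos, 10L, thr)$n_clams
      expect_true(all(cur >= prev))
      prev <- cur
    }
  })
})

test_that("presence and count labels are mutually consistent", {
  withr::with_seed(5, {
    pos <- data.frame(bucket_id = "b", x = sample(0:59, 10, TRUE),
                      y = sample(0:49, 10, TRUE), z = 0L, kind = "clam")
    lab <- assign_labels(enumerate_windows(60, 50, 25), pos, 25L, 11)
    expect_true(all((lab$presence == "presence") == (lab$count_label != "0")))
    expect_true(all((lab$count_label == "ge2") == (lab$n_clams >= 2)))
  })
})

test_that("positions outside the grid are rejected with offenders listed", {
  org <- enumerate_windows(30, 30, 10)
  pos <- data.frame(bucket_id = "b", x = c(5L, 35L), y = c(5L, 5L), z = 0L,
                    kind = "clam")
  expect_error(assign_labels(org, pos, 10L, 11, grid_nx = 30, grid_ny = 30),
               "\\(35,5\\)")
})

test_that("count collapse folds three-or-more into the two-or-more class", {
  expect_equal(collapse_count(0L), "0")
  expect_equal(collapse_count(1L), "1")
  expect_equal(collapse_count(2L), "ge2")
  expect_equal(collapse_count(3L), "ge2")
  expect_equal(collapse_count(c(0L, 1L, 5L)), c("0", "1", "ge2"))
  expect_error(collapse_count(-1L), "non-negative")
})

test_that("balanced sampling is stratified, capped, and reproducible", {
  withr::with_seed(2, {
    man <- data.frame(
      bucket_id = "b", bucket_type = "A",
      x0 = seq_len(230), y0 = 0L,
      n_clams = rep(c(0L, 1L), c(130, 100)))
  })
  man$presence <- ifelse(man$n_clams > 0, "presence", "absence")
  man$count_label <- collapse_count(man$n_clams)
  d1 <- build_balanced_dataset(man, "presence", per_label = 50L, seed = 10L)
  expect_equal(unname(table(d1$label)["absence"]), 50L)
  expect_equal(unname(table(d1$label)["presence"]), 50L)
  d2 <- build_balanced_dataset(man, "presence", per_label = 50L, seed = 10L)
  expect_identical(d1$x0, d2$x0)   # same sample identities
  d3 <- build_balanced_dataset(man, "presence", per_label = 51L, seed = 11L)
  expect_false(identical(d1$x0[d1$label == "absence"],
                         d3$x0[d3$label == "absence"]))
  # capping with warning when a stratum is short
  expect_warning(
    d4 <- build_balanced_dataset(man, "presence", per_label = 120L),
    "only 100")
  expect_equal(sum(d4$label == "presence"), 100L)
  # empty stratum errors
  expect_error(build_balanced_dataset(man, "count", 10L), "ge2")
})

test_that("extracted voxels carry the window contents", {
  sim <- simulate_bucket(tiny_sim_config("A", seed = 4L), "A1")
  v <- extract_voxel(sim$volume, 10L, 5L, 25L)
  expect_equal(dim(v), c(25L, 25L, 200L, 1L))
  expect_equal(v[1, 1, 50, 1], sim$volume$intensity[11, 6, 50])
  expect_error(extract_voxel(sim$volume, 50L, 5L, 25L), "out of bounds")
})
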