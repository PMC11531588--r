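# shared fixtures: small simulated buckets and toy networks, built in code

tiny_sim_config <- function(type = "A", seed = 1L, n_clams = NULL, ...) {
  args <- utils::modifyList(
    list(bucket_type = type,
         grid_nx = 60L, grid_ny = 50L, grid_nz = 200L,
         surface_z = 30L, multiple_z = 170L,
         n_clams = n_clams %||%
           (if (type %in% c("A", "AM")) 8L else 0L),
         n_confounders = if (type %in% c("M", "AM")) 6L else 0L,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable toy voxel: faint noise background, optional bright blob
toy_voxel <- function(blob, nx = 12L, nz = 24L, amp = 0.5, noise = 0.02) {
  a <- array(abs(stats::rnorm(nx * nx * nz, sd = noise)), c(nx, nx, nz, 1L))
  if (blob) {
    cx <- sample(4:(nx - 3), 1L)
    cz <- sample(6:(nz - 5), 1L)
    a[cx + (-2:2), cx + (-2:2), cz + (-3:3), 1] <-
      a[cx + (-2:2), cx + (-2:2), cz + (-3:3), 1] + amp
  }
  a
}

toy_dataset <- function(n, nx = 12L, nz = 24L, seed = 1L) {
  withr::with_seed(seed, {
    xs <- lapply(seq_len(n), function(i) toy_voxel(i %% 2 == 0, nx, nz))
    ys <- ifelse(seq_len(n) %% 2 == 0, "presence", "absence")
    cnn_dataset(xs, ys)
  })
}

tiny_model_spec <- function(task = "presence", nx = 12L, nz = 24L) {
  model_spec(task, input_shape = c(nx, nx, nz),
             conv_blocks = list(list(channels = 4L, kernel = c(3L, 3L, 3L),
                                     pool = c(2L, 2L, 2L))),
             input_pool_z = 2L)
}

# synthetic sample table for fold-plan tests: n_b buckets, balanced types
fold_sample_table <- function(n_b = 20L, per_bucket = 30L, seed = 1L) {
  types <- rep(c("C", "A", "M", "AM"), length.out = n_b)
  ids <- paste0(types, seq_len(n_b))
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_b), function(i) {
      lab <- if (types[i] %in% c("A", "AM")) {
        sample(c("absence", "presence"), per_bucket, TRUE, c(0.2, 0.8))
      } else rep("absence", per_bucket)
      data.frame(bucket_id = ids[i], bucket_type = types[i], label = lab,
                 stringsAsFactors = FALSE)
    }))
  })
}
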