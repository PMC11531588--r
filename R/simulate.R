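#' Configuration for a simulated bucket volume
#'
#' Defines the forward model for one experimental sediment bucket as seen
#' by a raster-scanning focused ultrasonic probe: a bright sediment-surface
#' reflection band, a weaker multiple-reflection band deeper in the record,
#' ellipsoidal backscatter blobs for buried clams (and weaker/smaller blobs
#' for mussel/stone confounders) strictly between the two bands,
#' exponential depth attenuation of the signal field, and additive receiver
#' noise clipped at zero (envelope-like non-negativity).
#'
#' Bucket types follow the four experimental conditions: `C` sand only,
#' `A` clams, `M` mussels (confounders only), `AM` clams plus confounders.
#' Defaults reproduce the study geometry: a 125 x 100 scan at 2 mm pitch
#' with 693 depth samples, 40 clams per A/AM bucket, and 100 dB/m
#' attenuation.
#'
#' @param bucket_type `"C"`, `"A"`, `"M"`, or `"AM"`
#' @param grid_nx,grid_ny,grid_nz grid extents (scan x, scan y, depth)
#' @param scan_pitch_mm horizontal scan pitch
#' @param n_clams clams to bury; default 40 for A/AM, 0 otherwise
#' @param n_confounders mussels/stones; default 30 for M/AM, 0 otherwise
#' @param surface_z,multiple_z 0-based depth indices of the two reflection
#'   bands; `multiple_z > surface_z`
#' @param clam_amplitude,confounder_amplitude,surface_amplitude peak
#'   (unattenuated) intensities of the respective structures
#' @param multiple_frac multiple-band amplitude as a fraction of
#'   `surface_amplitude`
#' @param band_sigma Gaussian half-width (z samples) of the reflection bands
#' @param clam_sigma,confounder_sigma length-3 Gaussian radii (x, y, z) of
#'   the backscatter blobs, in grid samples
#' @param depth_band fraction of the surface-to-multiple gap within which
#'   target centers are placed (uniformly)
#' @param attenuation_db_per_m one-way amplitude attenuation applied to the
#'   signal field (not the noise) as `10^(-dB/m * z_m / 20)`
#' @param z_step_mm depth-axis calibration used by the attenuation term
#' @param noise_sigma standard deviation of additive Gaussian receiver noise
#' @param min_separation_px minimum center-to-center distance between
#'   placed targets, in scan pixels
#' @param seed RNG seed; identical config + seed gives identical volumes
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(bucket_type,
                              grid_nx = 125L, grid_ny = 100L,
                              grid_nz = 693L,
                              scan_pitch_mm = 2.0,
                              n_clams = NULL, n_confounders = NULL,
                              surface_z = 100L, multiple_z = 600L,
                              clam_amplitude = 40,
                              confounder_amplitude = 20,
                              surface_amplitude = 100,
                              multiple_frac = 0.3,
                              band_sigma = 4,
                              clam_sigma = c(2.5, 2.5, 8),
                              confounder_sigma = c(1.8, 1.8, 5),
                              depth_band = c(0.15, 0.55),
                              attenuation_db_per_m = 100,
                              z_step_mm = 0.3,
                              noise_sigma = 2,
                              min_separation_px = 6,
                              seed = 1L) {
  bucket_type <- match.arg(bucket_type, c("C", "A", "M", "AM"))
  if (is.null(n_clams)) n_clams <- if (bucket_type %in% c("A", "AM")) 40L else 0L
  if (is.null(n_confounders)) {
    n_confounders <- if (bucket_type %in% c("M", "AM")) 30L else 0L
  }
  cfg <- list(bucket_type = bucket_type,
              grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              grid_nz = as.integer(grid_nz),
              scan_pitch_mm = scan_pitch_mm,
              n_clams = as.integer(n_clams),
              n_confounders = as.integer(n_confounders),
              surface_z = as.integer(surface_z),
              multiple_z = as.integer(multiple_z),
              clam_amplitude = clam_amplitude,
              confounder_amplitude = confounder_amplitude,
              surface_amplitude = surface_amplitude,
              multiple_frac = multiple_frac,
              band_sigma = band_sigma,
              clam_sigma = clam_sigma,
              confounder_sigma = confounder_sigma,
              depth_band = depth_band,
              attenuation_db_per_m = attenuation_db_per_m,
              z_step_mm = z_step_mm,
              noise_sigma = noise_sigma,
              min_separation_px = min_separation_px,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (!(grid_nz > multiple_z && multiple_z > surface_z && surface_z >= 0)) {
      stop("require grid_nz > multiple_z > surface_z >= 0")
    }
    if (any(c(clam_amplitude, confounder_amplitude, surface_amplitude) <= 0)) {
      stop("all amplitudes must be positive")
    }
    if (n_clams < 0 || n_confounders < 0) stop("target counts must be >= 0")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (!(depth_band[1] >= 0 && depth_band[2] <= 1 &&
          depth_band[1] < depth_band[2])) {
      stop("depth_band must be an increasing sub-interval of [0, 1]")
    }
    # density guard: each target claims a disc of radius min_separation/2
    claimed <- (n_clams + n_confounders) * pi * (min_separation_px / 2)^2
    if (claimed > 0.5 * grid_nx * grid_ny) {
      stop("too many targets for the grid at the configured separation")
    }
  })
  invisible(cfg)
}

#' Simulate one bucket volume and its ground truth
#'
#' @param config a [simulation_config()]
#' @param bucket_id identifier stored in the volume and ground truth
#' @return list with `volume` (an [acoustic_volume()]) and `truth`
#'   (a `ground_truth` data frame: bucket_id, x, y, z, kind; 0-based
#'   coordinates)
#' @export
simulate_bucket <- function(config, bucket_id = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(bucket_id)) {
    bucket_id <- paste0(config$bucket_type, config$seed)
  }
  with_seed(config$seed, simulate_bucket_impl(config, bucket_id))
}

simulate_bucket_impl <- function(cfg, bucket_id) {
  nx <- cfg$grid_nx; ny <- cfg$grid_ny; nz <- cfg$grid_nz
  signal <- array(0, c(nx, ny, nz))

  # reflection bands: Gaussian ridges in z, uniform across the scan plane
  add_band <- function(signal, z0, amp) {
    zi <- seq(max(0L, z0 - ceiling(4 * cfg$band_sigma)),
              min(nz - 1L, z0 + ceiling(4 * cfg$band_sigma)))
    w <- amp * exp(-0.5 * ((zi - z0) / cfg$band_sigma)^2)
    for (i in seq_along(zi)) {
      signal[, , zi[i] + 1L] <- signal[, , zi[i] + 1L] + w[i]
    }
    signal
  }
  signal <- add_band(signal, cfg$surface_z, cfg$surface_amplitude)
  signal <- add_band(signal, cfg$multiple_z,
                     cfg$surface_amplitude * cfg$multiple_frac)

  # place targets with a minimum horizontal separation (rejection sampling)
  n_total <- cfg$n_clams + cfg$n_confounders
  gap <- cfg$multiple_z - cfg$surface_z
  z_lo <- cfg$surface_z + ceiling(cfg$depth_band[1] * gap)
  z_hi <- cfg$surface_z + floor(cfg$depth_band[2] * gap)
  margin <- 3L
  xs <- ys <- zs <- integer(0)
  attempts <- 0L
  max_attempts <- 200L * max(n_total, 1L)
  while (length(xs) < n_total) {
    if (attempts >= max_attempts) {
      stop("could not place ", n_total, " targets at min separation ",
           cfg$min_separation_px, " within ", max_attempts, " attempts")
    }
    attempts <- attempts + 1L
    cx <- sample.int(nx - 2L * margin, 1L) + margin - 1L   # 0-based
    cy <- sample.int(ny - 2L * margin, 1L) + margin - 1L
    if (length(xs) &&
        any((xs - cx)^2 + (ys - cy)^2 < cfg$min_separation_px^2)) next
    xs <- c(xs, cx); ys <- c(ys, cy)
    zs <- c(zs, if (z_hi > z_lo) sample(z_lo:z_hi, 1L) else z_lo)
  }
  kind <- rep(c("clam", "confounder"), c(cfg$n_clams, cfg$n_confounders))

  # ellipsoidal Gaussian backscatter blobs, truncated at 3.5 sigma
  add_blob <- function(signal, cx, cy, cz, amp, sig) {
    rx <- ceiling(3.5 * sig[1]); ry <- ceiling(3.5 * sig[2])
    rz <- ceiling(3.5 * sig[3])
    ix <- max(0L, cx - rx):min(nx - 1L, cx + rx)
    iy <- max(0L, cy - ry):min(ny - 1L, cy + ry)
    iz <- max(0L, cz - rz):min(nz - 1L, cz + rz)
    gx <- exp(-0.5 * ((ix - cx) / sig[1])^2)
    gy <- exp(-0.5 * ((iy - cy) / sig[2])^2)
    gz <- exp(-0.5 * ((iz - cz) / sig[3])^2)
    blob <- amp * outer(outer(gx, gy), gz)
    signal[ix + 1L, iy + 1L, iz + 1L] <-
      signal[ix + 1L, iy + 1L, iz + 1L] + blob
    signal
  }
  if (n_total > 0) {
    for (i in seq_len(n_total)) {
      is_clam <- kind[i] == "clam"
      signal <- add_blob(signal, xs[i], ys[i], zs[i],
                         if (is_clam) cfg$clam_amplitude else
                           cfg$confounder_amplitude,
                         if (is_clam) cfg$clam_sigma else cfg$confounder_sigma)
    }
  }

  # one-way exponential depth attenuation of the signal field
  z_m <- (seq_len(nz) - 1L) * cfg$z_step_mm / 1000
  atten <- 10^(-cfg$attenuation_db_per_m * z_m / 20)
  signal <- sweep(signal, 3L, atten, `*`)

  # additive receiver noise (unattenuated), clipped to envelope positivity
  if (cfg$noise_sigma > 0) {
    signal <- signal + stats::rnorm(length(signal), sd = cfg$noise_sigma)
  }
  signal[signal < 0] <- 0

  vol <- acoustic_volume(signal, bucket_id, cfg$bucket_type,
                         cfg$scan_pitch_mm, provenance = "simulated",
                         meta = list(surface_z = cfg$surface_z,
                                     multiple_z = cfg$multiple_z,
                                     seed = cfg$seed))
  truth <- ground_truth(
    data.frame(bucket_id = rep(bucket_id, n_total),
               x = if (n_total) xs else integer(0),
               y = if (n_total) ys else integer(0),
               z = if (n_total) zs else integer(0),
               kind = if (n_total) kind else character(0),
               stringsAsFactors = FALSE),
    bucket_type = cfg$bucket_type)
  list(volume = vol, truth = truth)
}

#' Ground-truth target position table
#'
#' Positions of buried targets in scan coordinates (0-based x, y, z),
#' mirroring manually identified clam-position tables: one row per target,
#' with `kind` distinguishing clams from mussel/stone confounders.
#'
#' @param df data frame with columns bucket_id, x, y, z, kind
#' @param bucket_type the bucket's experimental condition
#' @return `ground_truth` data frame
#' @export
ground_truth <- function(df, bucket_type = NULL) {
  need <- c("bucket_id", "x", "y", "z", "kind")
  if (!all(need %in% names(df))) {
    stop("ground truth requires columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) && !all(df$kind %in% c("clam", "confounder"))) {
    stop("kind must be 'clam' or 'confounder'")
  }
  structure(as.data.frame(df[need]), class = c("ground_truth", "data.frame"),
            bucket_type = bucket_type)
}

#' Write / read ground-truth position tables
#'
#' Plain CSV with header `bucket_id,x,y,z,kind`; lossless round trip,
#' including the empty (header-only) table.
#'
#' @param gt a [ground_truth()] table
#' @param path CSV path
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the [ground_truth()] table.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  utils::write.csv(as.data.frame(gt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bucket_id = "character",
                                       x = "integer", y = "integer",
                                       z = "integer", kind = "character"))
  ground_truth(df)
}

#' Simulate a panel of buckets
#'
#' Convenience wrapper producing `n_per_type` buckets of each requested
#' type with per-bucket seeds derived from `seed`.
#'
#' @param n_per_type buckets per type
#' @param types character vector of bucket types
#' @param seed base seed; bucket b of type t gets a distinct derived seed
#' @param ... further arguments forwarded to [simulation_config()]
#' @return list with `volumes` (named list of [acoustic_volume()]) and
#'   `truth` (row-bound [ground_truth()] over all buckets)
#' @export
simulate_panel <- function(n_per_type = 5L, types = c("C", "A", "M", "AM"),
                           seed = 1L, ...) {
  volumes <- list()
  truths <- list()
  idx <- 0L
  for (ty in types) {
    for (b in seq_len(n_per_type)) {
      idx <- idx + 1L
      bid <- paste0(ty, b)
      cfg <- simulation_config(bucket_type = ty,
                               seed = (seed * 1000L + idx) %% .Machine$integer.max,
                               ...)
      sim <- simulate_bucket(cfg, bucket_id = bid)
      volumes[[bid]] <- sim$volume
      truths[[bid]] <- sim$truth
    }
  }
  truth_all <- do.call(rbind, lapply(truths, as.data.frame))
  rownames(truth_all) <- NULL
  list(volumes = volumes, truth = ground_truth(truth_all))
}
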