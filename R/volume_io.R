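#' Acoustic reflection-intensity volume
#'
#' Container for one bucket's 3D envelope-processed reflection volume, as
#' produced by raster-scanning a focused ultrasonic probe over the sediment
#' surface. Intensities are non-negative (post-envelope) and indexed
#' `(x, y, z)` where x/y are scan positions and z is the depth sample.
#' User-facing coordinates (ground-truth positions, window origins) are
#' 0-based; array storage is 1-based as usual in R.
#'
#' @param intensity 3D numeric array, all values >= 0
#' @param bucket_id character scalar, e.g. `"A1"`
#' @param bucket_type one of `"C"`, `"A"`, `"M"`, `"AM"`
#' @param scan_pitch_mm horizontal scan pitch in millimetres
#' @param provenance `"measured"` or `"simulated"`
#' @param meta optional named list of extra metadata (kept through I/O)
#' @return an object of class `acoustic_volume`
#' @export
acoustic_volume <- function(intensity, bucket_id, bucket_type,
                            scan_pitch_mm = 2.0,
                            provenance = c("simulated", "measured"),
                            meta = list()) {
  provenance <- match.arg(provenance)
  bucket_type <- match.arg(bucket_type, c("C", "A", "M", "AM"))
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    stop("`intensity` must be a 3D array")
  }
  if (anyNA(intensity) || min(intensity) < 0) {
    stop("intensities must be finite and non-negative (post-envelope)")
  }
  structure(
    list(intensity = intensity,
         bucket_id = as.character(bucket_id),
         bucket_type = bucket_type,
         scan_pitch_mm = as.numeric(scan_pitch_mm),
         provenance = provenance,
         meta = meta),
    class = "acoustic_volume")
}

#' @export
print.acoustic_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<acoustic_volume %s (type %s, %s)> %d x %d x %d, max %.3g\n",
              x$bucket_id, x$bucket_type, x$provenance,
              d[1], d[2], d[3], max(x$intensity)))
  invisible(x)
}

#' @export
dim.acoustic_volume <- function(x) dim(x$intensity)

#' Write / read an acoustic volume
#'
#' Volumes are serialized with their metadata so that
#' `read_volume(write_volume(v, p))` is lossless.
#'
#' @param vol an [acoustic_volume()]
#' @param path file path (conventionally `.rds`)
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the [acoustic_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "acoustic_volume"))
  saveRDS(unclass(vol), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("malformed volume container: ",
                                           conditionMessage(e), call. = FALSE))
  need <- c("intensity", "bucket_id", "bucket_type", "scan_pitch_mm",
            "provenance")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("volume container missing metadata keys: ",
         paste(missing, collapse = ", "))
  }
  acoustic_volume(obj$intensity, obj$bucket_id, obj$bucket_type,
                  obj$scan_pitch_mm, obj$provenance, obj$meta %||% list())
}

#' Read a raw binary volume dump with a user-supplied layout
#'
#' Adapter for externally deposited volumes stored as flat binary arrays
#' (e.g. little-endian float32 dumps). The caller supplies the layout:
#' grid dimensions, element type, endianness, and the axis order of the
#' file, which is permuted to the package's `(x, y, z)` convention.
#'
#' @param path binary file path
#' @param dims integer vector of length 3: extents in the file's axis order
#' @param dtype `"float32"`, `"float64"`, `"int16"`, or `"int32"`
#' @param endian `"little"` or `"big"`
#' @param axis_order character permutation of `c("x","y","z")` giving the
#'   meaning of `dims` (fastest-varying axis first)
#' @param bucket_id,bucket_type,scan_pitch_mm metadata for the resulting
#'   volume
#' @return an [acoustic_volume()] with provenance `"measured"`
#' @export
read_volume_raw <- function(path, dims, dtype = "float32", endian = "little",
                            axis_order = c("x", "y", "z"),
                            bucket_id = "unknown", bucket_type = "A",
                            scan_pitch_mm = 2.0) {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  if (!setequal(axis_order, c("x", "y", "z"))) {
    stop("`axis_order` must be a permutation of x, y, z")
  }
  size <- switch(dtype, float32 = 4L, float64 = 8L, int16 = 2L, int32 = 4L,
                 stop("unsupported dtype: ", dtype))
  what <- if (dtype %in% c("int16", "int32")) integer() else numeric()
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = what, n = n, size = size, endian = endian)
  if (length(raw_vals) != n) {
    stop("file holds ", length(raw_vals), " elements, expected ", n)
  }
  arr <- array(as.numeric(raw_vals), dim = dims)
  perm <- match(c("x", "y", "z"), axis_order)
  arr <- aperm(arr, perm)
  arr[arr < 0] <- 0
  acoustic_volume(arr, bucket_id, bucket_type, scan_pitch_mm,
                  provenance = "measured")
}

#' Summed-XY depth profile
#'
#' The total reflection intensity in the XY plane for each depth sample z;
#' the series whose two dominant peaks are the sediment-surface reflection
#' and its multiple.
#'
#' @param vol an [acoustic_volume()] or a 3D array
#' @return numeric vector of length `dim(vol)[3]`
#' @export
depth_profile <- function(vol) {
  a <- if (inherits(vol, "acoustic_volume")) vol$intensity else vol
  stopifnot(length(dim(a)) == 3L)
  d <- dim(a)
  colSums(matrix(a, nrow = d[1] * d[2], ncol = d[3]))
}

#' Locate the inter-reflection analysis window
#'
#' Smooths the depth profile, finds its local maxima, ranks them by
#' topographic prominence, and takes the two most prominent as the
#' sediment-surface reflection and its multiple. The analysis window is the
#' half-open depth interval between them, with a guard margin excluded
#' around each peak so the bright bands themselves are dropped.
#'
#' @param profile numeric depth profile (from [depth_profile()])
#' @param smooth_k moving-average width applied before peak finding
#' @param band_margin samples excluded on the inside of each reflection peak
#' @param min_peak_sep minimum separation (samples) between the two peaks
#' @return object of class `analysis_window`: list with `z_start`
#'   (inclusive), `z_end` (exclusive), `surface_z`, `multiple_z` (0-based
#'   peak indices) and the smoothed `profile`
#' @export
detect_analysis_window <- function(profile, smooth_k = 5L, band_margin = 20L,
                                   min_peak_sep = 50L) {
  stopifnot(is.numeric(profile), length(profile) >= 2L * band_margin + 4L)
  sm <- moving_average(profile, smooth_k)
  peaks <- local_maxima(sm)
  if (length(peaks) < 2L) {
    stop(windowing_error("fewer than two local maxima in depth profile", sm))
  }
  prom <- peak_prominence(sm, peaks)
  ord <- order(prom, decreasing = TRUE)
  # greedily take the most prominent, then the next one far enough away
  p1 <- peaks[ord[1]]
  rest <- peaks[ord[-1]]
  rest <- rest[abs(rest - p1) >= min_peak_sep]
  if (!length(rest)) {
    stop(windowing_error("no second prominent peak at sufficient separation",
                         sm))
  }
  p2 <- rest[1]
  zs <- sort(c(p1, p2))
  z_start <- zs[1] - 1L + band_margin        # convert to 0-based, then margin
  z_end <- zs[2] - 1L - band_margin          # exclusive bound
  if (z_end - z_start < 2L) {
    stop(windowing_error("reflections too close: empty analysis window", sm))
  }
  structure(list(z_start = as.integer(z_start), z_end = as.integer(z_end),
                 surface_z = zs[1] - 1L, multiple_z = zs[2] - 1L,
                 profile = sm),
            class = "analysis_window")
}

windowing_error <- function(msg, profile) {
  structure(class = c("windowing_error", "error", "condition"),
            list(message = paste0(msg, " (profile attached as $profile)"),
                 call = sys.call(-1), profile = profile))
}

#' Crop to the analysis window and standardize depth
#'
#' Restricts the volume to `[z_start, z_end)` and linearly resamples the
#' depth axis to `target_nz` samples so every bucket shares one grid.
#' x and y are untouched; intensities stay non-negative (linear
#' interpolation of non-negative values). The volume's pre-crop maximum is
#' recorded in `meta$scale_ref` for later intensity normalization against
#' the surface echo.
#'
#' @param vol an [acoustic_volume()]
#' @param window an `analysis_window` from [detect_analysis_window()]
#' @param target_nz standardized depth extent (default 693)
#' @return a standardized [acoustic_volume()]; `meta$window` records the
#'   crop and `meta$z_map` the linear map from standardized index to
#'   original 0-based depth
#' @export
standardize_volume <- function(vol, window, target_nz = 693L) {
  stopifnot(inherits(vol, "acoustic_volume"),
            inherits(window, "analysis_window"))
  d <- dim(vol$intensity)
  if (window$z_end > d[3] || window$z_start < 0) {
    stop("analysis window exceeds volume depth")
  }
  len <- window$z_end - window$z_start
  if (len < 2L) stop("analysis window shorter than 2 samples")
  scale_ref <- max(vol$intensity)
  cropped <- vol$intensity[, , (window$z_start + 1L):window$z_end,
                           drop = FALSE]
  if (len == target_nz) {
    out <- cropped
  } else {
    # positions of the target grid on the cropped 1-based axis
    pos <- seq(1, len, length.out = target_nz)
    lo <- pmin(floor(pos), len - 1L)
    fr <- pos - lo
    out <- array(0, c(d[1], d[2], target_nz))
    for (k in seq_len(target_nz)) {
      out[, , k] <- cropped[, , lo[k]] * (1 - fr[k]) +
        cropped[, , lo[k] + 1L] * fr[k]
    }
  }
  meta <- vol$meta
  meta$window <- list(z_start = window$z_start, z_end = window$z_end)
  meta$scale_ref <- scale_ref
  # standardized index k (0-based) maps to original depth z_start + k*step
  meta$z_map <- list(offset = window$z_start,
                     step = (len - 1) / max(target_nz - 1, 1))
  acoustic_volume(out, vol$bucket_id, vol$bucket_type, vol$scan_pitch_mm,
                  vol$provenance, meta)
}

#' Map a standardized depth index back to the original depth axis
#' @param vol a standardized volume carrying `meta$z_map`
#' @param k 0-based standardized depth index (vectorized)
#' @return 0-based original depth coordinate (fractional)
#' @export
standardized_to_original_z <- function(vol, k) {
  zm <- vol$meta$z_map
  if (is.null(zm)) stop("volume has no standardization map")
  zm$offset + k * zm$step
}

#' Block-average the depth axis
#'
#' Averages consecutive groups of `factor` depth samples (trailing
#' remainder dropped), reducing depth extent and averaging noise.
#'
#' @param vol [acoustic_volume()] or 3D array
#' @param factor integer >= 1
#' @return same type as the input, with `dim[3] %/% factor` depth samples
#' @export
downsample_z <- function(vol, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(vol)
  a <- if (inherits(vol, "acoustic_volume")) vol$intensity else vol
  d <- dim(a)
  nb <- d[3] %/% factor
  stopifnot(nb >= 1L)
  a <- a[, , seq_len(nb * factor), drop = FALSE]
  out <- array(0, c(d[1], d[2], nb))
  for (j in seq_len(factor)) {
    out <- out + a[, , seq(j, nb * factor, by = factor), drop = FALSE]
  }
  out <- out / factor
  if (inherits(vol, "acoustic_volume")) {
    meta <- vol$meta
    meta$z_downsample <- (meta$z_downsample %||% 1L) * factor
    acoustic_volume(out, vol$bucket_id, vol$bucket_type, vol$scan_pitch_mm,
                    vol$provenance, meta)
  } else out
}

#' Normalize volume intensities for model input
#'
#' @param vol a standardized [acoustic_volume()]
#' @param method `"none"`, `"max"` (divide by `meta$scale_ref`, the pre-crop
#'   maximum, i.e. the surface echo — keeps empty buckets dim), or
#'   `"window_max"` (divide by the post-crop maximum)
#' @return the volume with scaled intensities; `meta$normalized` records the
#'   method
#' @export
normalize_volume <- function(vol, method = c("max", "none", "window_max")) {
  method <- match.arg(method)
  if (method == "none") return(vol)
  ref <- switch(method,
                max = vol$meta$scale_ref %||% max(vol$intensity),
                window_max = max(vol$intensity))
  if (ref <= 0) ref <- 1
  meta <- vol$meta
  meta$normalized <- method
  acoustic_volume(vol$intensity / ref, vol$bucket_id, vol$bucket_type,
                  vol$scan_pitch_mm, vol$provenance, meta)
}

#' Full preprocessing of one bucket volume
#'
#' Depth profile, reflection-window detection, depth standardization,
#' optional block down-sampling, and intensity normalization in one call.
#'
#' @param vol an [acoustic_volume()]
#' @param target_nz standardized depth before down-sampling
#' @param z_downsample integer block size for [downsample_z()]
#' @param normalize method passed to [normalize_volume()]
#' @param smooth_k,band_margin,min_peak_sep passed to
#'   [detect_analysis_window()]
#' @return preprocessed [acoustic_volume()]
#' @export
preprocess_volume <- function(vol, target_nz = 693L, z_downsample = 1L,
                              normalize = "max", smooth_k = 5L,
                              band_margin = 20L, min_peak_sep = 50L) {
  win <- detect_analysis_window(depth_profile(vol), smooth_k = smooth_k,
                                band_margin = band_margin,
                                min_peak_sep = min_peak_sep)
  std <- standardize_volume(vol, win, target_nz = target_nz)
  std <- downsample_z(std, z_downsample)
  normalize_volume(std, normalize)
}
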