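#' Enumerate sliding-window origins
#'
#' All top-left origins `(x0, y0)` (0-based) of `w x w` windows on an
#' `nx x ny` scan grid at the given stride, in row-major order (x fastest).
#' Stride 1 gives the overlapping training windows; stride `w` gives the
#' non-overlapping bucket tiling.
#'
#' @param nx,ny scan-grid extents
#' @param w window side in scan pixels (default 25)
#' @param stride step between consecutive origins (default 1)
#' @return data frame with integer columns `x0`, `y0`
#' @export
enumerate_windows <- function(nx, ny, w = 25L, stride = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  w <- as.integer(w); stride <- as.integer(stride)
  if (w > nx || w > ny) stop("window side exceeds grid: w=", w,
                             " on ", nx, "x", ny)
  stopifnot(stride >= 1L)
  x0 <- seq(0L, nx - w, by = stride)
  y0 <- seq(0L, ny - w, by = stride)
  data.frame(x0 = rep(x0, times = length(y0)),
             y0 = rep(y0, each = length(x0)))
}

#' Point-to-window-footprint distance
#'
#' Euclidean distance in the XY plane from a point to the nearest pixel of
#' the `w x w` footprint whose pixels span `[x0, x0+w-1] x [y0, y0+w-1]`
#' (0 when the point lies inside). Chebyshev available as an alternative
#' reading of "shortest distance".
#'
#' @param x0,y0 window origins (vectorized)
#' @param px,py point coordinates (scalars)
#' @param w window side
#' @param metric `"euclidean"` (default) or `"chebyshev"`
#' @return numeric vector of distances
#' @export
window_distance <- function(x0, y0, px, py, w = 25L,
                            metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  dx <- pmax(x0 - px, px - (x0 + w - 1L), 0)
  dy <- pmax(y0 - py, py - (y0 + w - 1L), 0)
  if (metric == "euclidean") sqrt(dx^2 + dy^2) else pmax(dx, dy)
}

#' Attribute clams to windows and derive labels
#'
#' A clam belongs to a window when its position lies inside the window
#' footprint or within `threshold_px` (strictly less) of it, so backscatter
#' straddling a window boundary is still credited. Each clam may be
#' attributed to many overlapping windows. Presence and (collapsed) count
#' labels are derived from the per-window attributed-clam multiset.
#'
#' @param origins data frame from [enumerate_windows()]
#' @param positions a [ground_truth()] table (or data frame with x, y,
#'   kind); only `kind == "clam"` rows are attributed
#' @param w window side
#' @param threshold_px strict distance threshold in pixels (default 11)
#' @param grid_nx,grid_ny grid extents for validating positions; NULL skips
#' @param metric distance metric, see [window_distance()]
#' @return `origins` with added columns `n_clams` (attributed count),
#'   `presence` (`"absence"`/`"presence"`) and `count_label`
#'   (`"0"`/`"1"`/`"ge2"`)
#' @export
assign_labels <- function(origins, positions, w = 25L, threshold_px = 11,
                          grid_nx = NULL, grid_ny = NULL,
                          metric = "euclidean") {
  pos <- as.data.frame(positions)
  if (nrow(pos) && "kind" %in% names(pos)) {
    pos <- pos[pos$kind == "clam", , drop = FALSE]
  }
  if (!is.null(grid_nx) && nrow(pos)) {
    bad <- pos$x < 0 | pos$x >= grid_nx | pos$y < 0 | pos$y >= grid_ny
    if (any(bad)) {
      stop("positions outside the grid: ",
           paste(sprintf("(%d,%d)", pos$x[bad], pos$y[bad]), collapse = " "))
    }
  }
  n <- nrow(origins)
  counts <- integer(n)
  for (i in seq_len(nrow(pos))) {
    d <- window_distance(origins$x0, origins$y0, pos$x[i], pos$y[i], w,
                         metric)
    counts <- counts + as.integer(d < threshold_px)
  }
  origins$n_clams <- counts
  origins$presence <- ifelse(counts >= 1L, "presence", "absence")
  origins$count_label <- collapse_count(counts)
  origins
}

#' Collapse a clam count to the three-class label
#'
#' Counts of three or more are folded into the "2 or more" class.
#'
#' @param n non-negative integer count (vectorized)
#' @return character vector over `"0"`, `"1"`, `"ge2"`
#' @export
collapse_count <- function(n) {
  if (any(n < 0)) stop("counts must be non-negative")
  ifelse(n >= 2L, "ge2", as.character(as.integer(n)))
}

#' Extract one local voxel from a volume
#'
#' @param vol an [acoustic_volume()] (typically preprocessed)
#' @param x0,y0 0-based window origin
#' @param w window side
#' @return numeric 4D array `w x w x nz x 1` (trailing channel axis), ready
#'   as classifier input
#' @export
extract_voxel <- function(vol, x0, y0, w = 25L) {
  d <- dim(vol$intensity)
  if (x0 < 0 || y0 < 0 || x0 + w > d[1] || y0 + w > d[2]) {
    stop("voxel window out of bounds: origin (", x0, ",", y0, ")")
  }
  a <- vol$intensity[(x0 + 1L):(x0 + w), (y0 + 1L):(y0 + w), , drop = FALSE]
  dim(a) <- c(w, w, d[3], 1L)
  a
}

#' Label every sliding window of every bucket
#'
#' @param volumes named list of preprocessed volumes (names are bucket ids)
#' @param truth combined [ground_truth()] table over all buckets
#' @param w,stride,threshold_px,metric labeling parameters
#' @return manifest data frame: bucket_id, bucket_type, x0, y0, n_clams,
#'   presence, count_label
#' @export
build_voxel_manifest <- function(volumes, truth, w = 25L, stride = 1L,
                                 threshold_px = 11, metric = "euclidean") {
  pieces <- lapply(names(volumes), function(bid) {
    vol <- volumes[[bid]]
    d <- dim(vol$intensity)
    org <- enumerate_windows(d[1], d[2], w, stride)
    pos <- truth[truth$bucket_id == bid, , drop = FALSE]
    lab <- assign_labels(org, pos, w, threshold_px, d[1], d[2], metric)
    cbind(data.frame(bucket_id = bid, bucket_type = vol$bucket_type,
                     stringsAsFactors = FALSE), lab)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Draw a balanced labeled dataset
#'
#' Seeded uniform sampling without replacement within each label stratum.
#' Strata with fewer samples than the target are included in full with a
#' warning, mirroring balanced random extraction from the pool of all
#' sliding windows.
#'
#' @param manifest labeled window manifest from [build_voxel_manifest()]
#' @param task `"presence"` (2 strata) or `"count"` (3 strata)
#' @param per_label target samples per label
#' @param seed sampling seed
#' @return subset of `manifest` with a `label` column (stratum id), ordered
#'   by stratum then sampling order; attributes `per_label_counts` and
#'   `sampling_seed`
#' @export
build_balanced_dataset <- function(manifest, task = c("presence", "count"),
                                   per_label = 100L, seed = 1L) {
  task <- match.arg(task)
  lab <- if (task == "presence") manifest$presence else manifest$count_label
  levels <- if (task == "presence") c("absence", "presence") else
    c("0", "1", "ge2")
  missing <- setdiff(levels, unique(lab))
  if (length(missing)) {
    stop("empty stratum for label(s): ", paste(missing, collapse = ", "))
  }
  picks <- with_seed(seed, {
    lapply(levels, function(lv) {
      idx <- which(lab == lv)
      if (length(idx) <= per_label) {
        if (length(idx) < per_label) {
          warning(sprintf("stratum '%s' has only %d samples (target %d); using all",
                          lv, length(idx), per_label))
        }
        idx[sample.int(length(idx))]
      } else {
        idx[sample.int(length(idx), per_label)]
      }
    })
  })
  out <- manifest[unlist(picks), , drop = FALSE]
  out$label <- rep(levels, vapply(picks, length, integer(1)))
  rownames(out) <- NULL
  attr(out, "per_label_counts") <- stats::setNames(
    vapply(picks, length, integer(1)), levels)
  attr(out, "sampling_seed") <- seed
  out
}
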