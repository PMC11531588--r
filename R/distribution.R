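#' Integrate per-voxel count predictions into a bucket count
#'
#' Sums the predicted class of each tile of the bucket's non-overlapping
#' tiling under the mapping `0 -> 0`, `1 -> 1`, `ge2 -> ge2_value`. The
#' default `ge2_value = 2` is the class's lower bound, so dense buckets are
#' estimated conservatively.
#'
#' @param voxel_predictions character vector of classes over
#'   `{"0", "1", "ge2"}`
#' @param ge2_value numeric contribution of the "2 or more" class
#' @return non-negative numeric estimate
#' @export
integrate_counts <- function(voxel_predictions, ge2_value = 2) {
  if (length(voxel_predictions) == 0L) stop("no voxel predictions")
  v <- as.character(voxel_predictions)
  bad <- setdiff(unique(v), c("0", "1", "ge2"))
  if (length(bad)) stop("unknown class token(s): ",
                        paste(bad, collapse = ", "))
  sum(c(`0` = 0, `1` = 1, ge2 = ge2_value)[v])
}

#' Mean absolute error of count estimates
#' @param estimates,truths equal-length numeric vectors
#' @return mean of `|estimate - truth|`
#' @export
mae <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths), length(truths) >= 1L)
  mean(abs(estimates - truths))
}

#' Mean relative error of count estimates
#'
#' Relative error is undefined for a true count of zero; such entries are
#' dropped with a warning (empty buckets are excluded from MRE, as C/M
#' bucket types are).
#'
#' @param estimates,truths equal-length numeric vectors
#' @return mean of `|estimate - truth| / truth` over entries with
#'   `truth > 0`; `NA` if none remain
#' @export
mre <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  zero <- truths == 0
  if (any(zero)) {
    warning(sum(zero), " entr", if (sum(zero) == 1) "y" else "ies",
            " with zero true count excluded from MRE")
    estimates <- estimates[!zero]
    truths <- truths[!zero]
  }
  if (!length(truths)) return(NA_real_)
  mean(abs(estimates - truths) / truths)
}

#' Pearson correlation between estimated and true counts
#'
#' @param estimates,truths numeric vectors
#' @param subset optional logical/integer subset (e.g. clam-bearing bucket
#'   types only)
#' @return Pearson correlation coefficient
#' @export
count_correlation <- function(estimates, truths, subset = NULL) {
  if (!is.null(subset)) {
    estimates <- estimates[subset]
    truths <- truths[subset]
  }
  stopifnot(length(estimates) == length(truths))
  if (length(truths) < 2L || stats::sd(estimates) == 0 ||
      stats::sd(truths) == 0) {
    stop("correlation undefined: fewer than 2 points or zero variance")
  }
  stats::cor(estimates, truths)
}

#' Bucket-level count estimates from tile predictions
#'
#' @param tile_predictions data frame with columns `bucket_id`,
#'   `bucket_type`, `x0`, `y0`, `predicted` (class tokens)
#' @param truth a [ground_truth()] table giving true clam positions
#' @param ge2_value mapping for the "2 or more" class
#' @return data frame of class `bucket_estimates`: bucket_id, bucket_type,
#'   predicted_count, true_count, n_tiles
#' @export
bucket_estimates <- function(tile_predictions, truth, ge2_value = 2) {
  stopifnot(all(c("bucket_id", "bucket_type", "predicted") %in%
                  names(tile_predictions)))
  clams <- as.data.frame(truth)
  clams <- clams[clams$kind == "clam", , drop = FALSE]
  ids <- unique(tile_predictions$bucket_id)
  out <- do.call(rbind, lapply(ids, function(bid) {
    rows <- tile_predictions[tile_predictions$bucket_id == bid, ,
                             drop = FALSE]
    data.frame(bucket_id = bid,
               bucket_type = rows$bucket_type[1],
               predicted_count = integrate_counts(rows$predicted, ge2_value),
               true_count = sum(clams$bucket_id == bid),
               n_tiles = nrow(rows),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("bucket_estimates", "data.frame")
  out
}

#' Error metrics per bucket type plus correlations
#'
#' @param est a [bucket_estimates()] table
#' @param clam_types bucket types with non-zero true counts, over which MRE
#'   and the subset correlation are computed
#' @return list with `mae_by_type`, `mre_by_type` (clam types only),
#'   `correlation_overall`, `correlation_clam_types`
#' @export
distribution_metrics <- function(est, clam_types = c("A", "AM")) {
  stopifnot(inherits(est, "bucket_estimates"))
  types <- unique(est$bucket_type)
  mae_by_type <- vapply(types, function(ty) {
    r <- est[est$bucket_type == ty, ]
    mae(r$predicted_count, r$true_count)
  }, numeric(1))
  mre_by_type <- vapply(intersect(clam_types, types), function(ty) {
    r <- est[est$bucket_type == ty, ]
    mre(r$predicted_count, r$true_count)
  }, numeric(1))
  sub <- est$bucket_type %in% clam_types
  corr_sub <- if (sum(sub) >= 2L &&
                  stats::sd(est$true_count[sub]) > 0 &&
                  stats::sd(est$predicted_count[sub]) > 0) {
    count_correlation(est$predicted_count, est$true_count, sub)
  } else NA_real_
  list(mae_by_type = mae_by_type,
       mre_by_type = mre_by_type,
       correlation_overall = count_correlation(est$predicted_count,
                                               est$true_count),
       correlation_clam_types = corr_sub)
}

#' Render a bucket's predicted-class tiling as a map
#'
#' Builds the class-coloured grid aligned to scan coordinates (origin
#' top-left) for one bucket's non-overlapping tiling and optionally writes
#' it as PNG + CSV.
#'
#' @param tile_predictions data frame with `x0`, `y0`, `predicted` for one
#'   bucket
#' @param w tile side in scan pixels
#' @param expected_tiles error unless exactly this many tiles are present
#'   (NULL to skip the completeness check)
#' @param path optional output PNG path; a CSV with the same stem is
#'   written next to it
#' @return a ggplot object; the tile table is attached as
#'   `attr(, "tiles")`
#' @export
render_distribution_map <- function(tile_predictions, w = 25L,
                                    expected_tiles = NULL, path = NULL) {
  need <- c("x0", "y0", "predicted")
  stopifnot(all(need %in% names(tile_predictions)))
  if (!is.null(expected_tiles) &&
      nrow(tile_predictions) != expected_tiles) {
    stop("incomplete tiling: ", nrow(tile_predictions), " tiles, expected ",
         expected_tiles)
  }
  tiles <- data.frame(x0 = tile_predictions$x0, y0 = tile_predictions$y0,
                      cx = tile_predictions$x0 + w / 2,
                      cy = tile_predictions$y0 + w / 2,
                      predicted = factor(tile_predictions$predicted,
                                         levels = c("0", "1", "ge2")))
  p <- ggplot2::ggplot(tiles, ggplot2::aes(x = cx, y = cy,
                                           fill = predicted)) +
    ggplot2::geom_tile(width = w, height = w, colour = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey90", `1` = "steelblue", ge2 = "firebrick"),
      drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "scan x (px)", y = "scan y (px)", fill = "class")
  attr(p, "tiles") <- tiles
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
    utils::write.csv(tiles, sub("\\.[a-zA-Z]+$", ".csv", path),
                     row.names = FALSE)
  }
  p
}
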