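#' Grad-CAM attention volume for a voxel classifier
#'
#' Backpropagates the target-class logit to a convolutional feature map,
#' globally averages the gradient per channel into weights, forms the
#' weighted sum of the feature maps, rectifies negatives to zero,
#' trilinearly upsamples to the input voxel shape, and normalizes to a
#' maximum of 1 — localizing the evidence behind a prediction inside the
#' voxel.
#'
#' @param model a trained `cnn_model`
#' @param voxel input array `w x w x nz` (or with trailing channel axis)
#' @param target_class class name or index whose logit is explained
#' @param layer index of the conv layer to use; `NULL` = last conv block
#'   (the usual Grad-CAM choice)
#' @return object of class `attention_volume`: list with `heat` (array of
#'   the input's spatial shape, values in `[0, 1]`), `target_class`,
#'   `layer`, `raw_max` (pre-normalization maximum)
#' @export
grad_cam <- function(model, voxel, target_class, layer = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  conv_layers <- which(vapply(model$layers, function(l) l$type == "conv",
                              logical(1)))
  if (!length(conv_layers)) stop("model has no convolutional layer")
  layer <- layer %||% conv_layers[length(conv_layers)]
  if (!(layer %in% conv_layers)) {
    stop("layer ", layer, " is not a convolutional feature map")
  }
  if (is.character(target_class)) {
    target_class <- match(target_class, model$spec$class_names)
    if (is.na(target_class)) stop("unknown target class")
  }
  stopifnot(target_class >= 1L, target_class <= model$spec$n_classes)

  if (length(dim(voxel)) == 3L) dim(voxel) <- c(dim(voxel), 1L)
  fwd <- cnn_forward(model, voxel)
  dlogits <- as.numeric(seq_len(model$spec$n_classes) == target_class)
  bk <- cnn_backward(model, fwd$caches, dlogits, stop_at_conv = layer)

  A <- bk$activation            # ox x oy x oz x K
  dA <- bk$d_activation
  K <- dim(A)[4]
  m <- prod(dim(A)[1:3])
  alpha <- colMeans(matrix(dA, m, K))       # global-average-pooled gradients
  cam <- array(matrix(A, m, K) %*% alpha, dim(A)[1:3])
  cam[cam < 0] <- 0                         # rectification
  heat <- resize_trilinear(cam, dim(voxel)[1:3])
  raw_max <- max(heat)
  if (raw_max <= 0) {
    warning("zero gradient everywhere: attention volume is all-zero")
  } else {
    heat <- heat / raw_max
  }
  structure(list(heat = heat, target_class = model$spec$class_names[target_class],
                 layer = layer, raw_max = raw_max),
            class = "attention_volume")
}

#' Trilinear resize of a 3D array
#'
#' Separable linear interpolation along each axis, mapping the corner
#' samples of the input grid to the corners of the output grid.
#'
#' @param arr 3D numeric array
#' @param out_dim target extents, length 3
#' @return resized array
#' @export
resize_trilinear <- function(arr, out_dim) {
  stopifnot(length(dim(arr)) == 3L, length(out_dim) == 3L, all(out_dim >= 1))
  for (ax in 1:3) {
    n_in <- dim(arr)[ax]
    n_out <- out_dim[ax]
    if (n_in == n_out) next
    pos <- if (n_out == 1L) 1 else seq(1, n_in, length.out = n_out)
    if (n_in == 1L) {
      lo <- rep(1L, n_out); fr <- rep(0, n_out)
    } else {
      lo <- pmin(floor(pos), n_in - 1L)
      fr <- pos - lo
    }
    arr_lo <- index_axis(arr, ax, lo)
    arr_hi <- index_axis(arr, ax, lo + ifelse(n_in == 1L, 0L, 1L))
    wshape <- c(1L, 1L, 1L)
    wshape[ax] <- n_out
    w <- array(rep(fr, each = prod(dim(arr_lo)[seq_len(ax - 1L)])),
               dim(arr_lo))
    arr <- arr_lo * (1 - w) + arr_hi * w
  }
  arr
}

index_axis <- function(arr, ax, idx) {
  switch(ax,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Depth-averaged panels of a volume
#'
#' Averages the depth axis in consecutive blocks (default every 10
#' samples), yielding `ceiling(nz / block)` 2D panels; the final panel
#' averages the remainder. Used to page through a voxel or its attention
#' volume.
#'
#' @param vol 3D array (or `attention_volume`, whose heat is used)
#' @param block depth samples per panel; `block >= nz` gives one
#'   whole-volume mean panel
#' @return list of 2D matrices; `attr(, "slices")` gives each panel's slice
#'   count
#' @export
z_average_panels <- function(vol, block = 10L) {
  a <- if (inherits(vol, "attention_volume")) vol$heat else
    if (inherits(vol, "acoustic_volume")) vol$intensity else vol
  stopifnot(length(dim(a)) == 3L, block >= 1L)
  nz <- dim(a)[3]
  n_panels <- ceiling(nz / block)
  panels <- vector("list", n_panels)
  slices <- integer(n_panels)
  for (k in seq_len(n_panels)) {
    z0 <- (k - 1L) * block + 1L
    z1 <- min(k * block, nz)
    slices[k] <- z1 - z0 + 1L
    sub <- a[, , z0:z1, drop = FALSE]
    panels[[k]] <- rowMeans(sub, dims = 2L)
  }
  attr(panels, "slices") <- slices
  panels
}

#' Side-by-side voxel / attention explanation figure
#'
#' Writes a paired grayscale (input) and heat (Grad-CAM) panel figure plus
#' a CSV of the heat panel values. File names encode the bucket, window
#' origin, and the predicted and true labels.
#'
#' @param voxel input voxel array
#' @param attention an `attention_volume` from [grad_cam()]
#' @param out_dir output directory
#' @param bucket_id,x0,y0 provenance of the voxel
#' @param predicted,actual labels recorded in the file name and caption
#' @param block depth block for [z_average_panels()]
#' @param max_panels cap on panels drawn in the figure (CSV always holds
#'   all panels)
#' @return invisible list with `png` and `csv` paths
#' @export
render_explanation <- function(voxel, attention, out_dir, bucket_id, x0, y0,
                               predicted, actual, block = 10L,
                               max_panels = 24L) {
  if (length(dim(voxel)) == 4L) dim(voxel) <- dim(voxel)[1:3]
  if (!all(dim(voxel) == dim(attention$heat))) {
    stop("voxel and attention shapes differ")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_x%03d_y%03d_pred-%s_true-%s", bucket_id, x0, y0,
                  predicted, actual)
  vox_p <- z_average_panels(voxel, block)
  heat_p <- z_average_panels(attention$heat, block)

  heat_df <- do.call(rbind, lapply(seq_along(heat_p), function(k) {
    m <- heat_p[[k]]
    data.frame(panel = k,
               x = rep(seq_len(nrow(m)) - 1L, ncol(m)),
               y = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               heat = as.vector(m))
  }))
  csv_path <- file.path(out_dir, paste0(stem, "_heat.csv"))
  utils::write.csv(heat_df, csv_path, row.names = FALSE)

  keep <- unique(round(seq(1, length(vox_p),
                           length.out = min(max_panels, length(vox_p)))))
  plot_df <- do.call(rbind, lapply(keep, function(k) {
    rbind(panel_long(vox_p[[k]], k, "input"),
          panel_long(heat_p[[k]], k, "grad_cam"))
  }))
  p <- ggplot2::ggplot(plot_df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(source ~ panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(title = sprintf("%s (%d,%d)  pred %s / true %s",
                                  bucket_id, x0, y0, predicted, actual),
                  x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   strip.text = ggplot2::element_text(size = 5),
                   plot.title = ggplot2::element_text(size = 8))
  png_path <- file.path(out_dir, paste0(stem, ".png"))
  ggplot2::ggsave(png_path, p, width = min(12, 0.5 * length(keep) + 1),
                  height = 2.5, dpi = 100, limitsize = FALSE)
  invisible(list(png = png_path, csv = csv_path))
}

panel_long <- function(m, k, source) {
  mx <- max(m)
  data.frame(panel = k, source = source,
             x = rep(seq_len(nrow(m)) - 1L, ncol(m)),
             y = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
             value = as.vector(m) / if (mx > 0) mx else 1)
}
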