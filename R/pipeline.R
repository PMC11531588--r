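#' Configuration for an end-to-end synthetic experiment
#'
#' Nested stage configuration for [run_experiment()]: simulate a panel of
#' bucket volumes, preprocess them, build balanced presence/count
#' datasets, train both classifiers under grouped stratified
#' cross-validation, integrate count predictions into bucket estimates,
#' and render Grad-CAM explanations.
#'
#' @param seed global seed; every stage derives its own stream from it
#' @param out_dir output directory for artifacts
#' @param n_per_type buckets per type (types fixed at C/A/M/AM)
#' @param sim named list of overrides passed to [simulation_config()]
#' @param preprocess list: `target_nz`, `z_downsample`, `normalize`,
#'   `band_margin`, `smooth_k`, `min_peak_sep`
#' @param dataset list: `w`, `threshold_px`, `per_label_presence`,
#'   `per_label_count`, `metric`
#' @param model list: passed to [model_spec()] (minus task/input_shape)
#' @param train list: `lr`, `batch_size`, `max_epochs_presence`,
#'   `max_epochs_count`, `patience`
#' @param n_folds cross-validation folds
#' @param ge2_value count contribution of the "2 or more" class
#' @param gradcam list: `n_examples`, `block`
#' @param cache reuse `summary.json` when the config hash matches
#' @return nested list of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       out_dir = file.path(tempdir(), "asariscan-run"),
                       n_per_type = 5L,
                       sim = list(),
                       preprocess = list(),
                       dataset = list(),
                       model = list(),
                       train = list(),
                       n_folds = 5L,
                       ge2_value = 2,
                       gradcam = list(),
                       cache = FALSE) {
  merge_defaults <- function(user, defaults) {
    utils::modifyList(defaults, as.list(user))
  }
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_per_type = as.integer(n_per_type),
    sim = as.list(sim),
    preprocess = merge_defaults(preprocess, list(
      target_nz = 693L, z_downsample = 4L, normalize = "max",
      band_margin = 20L, smooth_k = 5L, min_peak_sep = 50L)),
    dataset = merge_defaults(dataset, list(
      w = 25L, threshold_px = 11, per_label_presence = 80L,
      per_label_count = 70L, metric = "euclidean")),
    model = as.list(model),
    train = merge_defaults(train, list(
      lr = 3e-3, batch_size = 3L, max_epochs_presence = 14L,
      max_epochs_count = 14L, patience = 4L)),
    n_folds = as.integer(n_folds),
    ge2_value = ge2_value,
    gradcam = merge_defaults(gradcam, list(n_examples = 4L, block = 10L)),
    cache = isTRUE(cache))
  structure(cfg, class = "run_config")
}

#' Stable hash of a run configuration
#'
#' FNV-1a over the canonical (recursively key-sorted) JSON encoding, so
#' reordering keys does not change the hash. Execution details that do not
#' affect the computed results (`out_dir`, `cache`) are excluded.
#'
#' @param config a [run_config()] (or any nested list)
#' @return 8-character hex string
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$cache <- NULL
  config_hash_string(canonical_json(x))
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

#' Run the full synthetic experiment
#'
#' Executes simulate, preprocess, dataset construction, grouped
#' cross-validated training of the presence and count classifiers, pooled
#' evaluation, bucket-count integration, and Grad-CAM rendering, writing
#' all artifacts under `config$out_dir` together with a run manifest and a
#' summary JSON of the headline metrics. A rerun with the same config and
#' seed reproduces the same summary.
#'
#' @param config a [run_config()]
#' @return list with `summary` (headline metrics), `presence_report`,
#'   `count_report` (pooled `metric_report`s), `bucket_estimates`,
#'   `distribution`, `history`, and the artifact `paths`; invisibly
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(config$out_dir, "summary.json")
  if (config$cache && file.exists(summary_path)) {
    prev <- jsonlite::fromJSON(summary_path)
    if (identical(prev$config_hash, hash)) {
      message("cache hit for config ", hash, "; reusing summary")
      return(invisible(list(summary = prev, paths = list(
        summary = summary_path))))
    }
  }

  # ---- simulate + preprocess, bucket by bucket ----
  types <- c("C", "A", "M", "AM")
  volumes <- list()
  truths <- list()
  idx <- 0L
  for (ty in types) for (b in seq_len(config$n_per_type)) {
    idx <- idx + 1L
    bid <- paste0(ty, b)
    sim_over <- config$sim
    # count overrides mean "per clam/confounder-bearing bucket"; the other
    # types keep their structural zeros
    if (!is.null(sim_over$n_clams) && !(ty %in% c("A", "AM"))) {
      sim_over$n_clams <- 0L
    }
    if (!is.null(sim_over$n_confounders) && !(ty %in% c("M", "AM"))) {
      sim_over$n_confounders <- 0L
    }
    sim_args <- c(list(bucket_type = ty,
                       seed = derive_seed(config$seed, idx)),
                  sim_over)
    cfg_b <- do.call(simulation_config, sim_args)
    sim <- simulate_bucket(cfg_b, bucket_id = bid)
    pp <- config$preprocess
    volumes[[bid]] <- preprocess_volume(sim$volume,
                                        target_nz = pp$target_nz,
                                        z_downsample = pp$z_downsample,
                                        normalize = pp$normalize,
                                        smooth_k = pp$smooth_k,
                                        band_margin = pp$band_margin,
                                        min_peak_sep = pp$min_peak_sep)
    truths[[bid]] <- as.data.frame(sim$truth)
  }
  truth <- ground_truth(do.call(rbind, c(truths, make.row.names = FALSE)))
  gt_path <- file.path(config$out_dir, "ground_truth.csv")
  write_ground_truth(truth, gt_path)

  # ---- labeled manifests and balanced datasets ----
  ds <- config$dataset
  manifest <- build_voxel_manifest(volumes, truth, w = ds$w, stride = 1L,
                                   threshold_px = ds$threshold_px,
                                   metric = ds$metric)
  tiles <- build_voxel_manifest(volumes, truth, w = ds$w, stride = ds$w,
                                threshold_px = ds$threshold_px,
                                metric = ds$metric)
  balanced <- list(
    presence = build_balanced_dataset(manifest, "presence",
                                      ds$per_label_presence,
                                      derive_seed(config$seed, 901L)),
    count = build_balanced_dataset(manifest, "count", ds$per_label_count,
                                   derive_seed(config$seed, 902L)))

  plan <- make_fold_plan(manifest, n_folds = config$n_folds,
                         seed = derive_seed(config$seed, 77L))

  nz <- dim(volumes[[1]]$intensity)[3]
  make_ds <- function(rows) {
    cnn_dataset(function(i) extract_voxel(volumes[[rows$bucket_id[i]]],
                                          rows$x0[i], rows$y0[i], ds$w),
                rows$label, n = nrow(rows))
  }

  # ---- cross-validated training of both models ----
  tr <- config$train
  reports <- list(presence = list(), count = list())
  histories <- list()
  tile_pred_rows <- list()
  fold_models <- list()
  for (fold in seq_len(config$n_folds)) {
    for (task in c("presence", "count")) {
      bal <- balanced[[task]]
      role <- sample_roles(plan, fold, bal)
      rows_tr <- bal[role == "train", , drop = FALSE]
      rows_va <- bal[role == "val", , drop = FALSE]
      rows_te <- bal[role == "test", , drop = FALSE]
      spec_args <- c(list(task = task, input_shape = c(ds$w, ds$w, nz)),
                     config$model)
      model <- build_model(do.call(model_spec, spec_args),
                           seed = derive_seed(config$seed,
                                              1000L + fold * 10L +
                                                (task == "count")))
      cfg_tr <- train_config(
        batch_size = tr$batch_size, lr = tr$lr,
        max_epochs = if (task == "presence") tr$max_epochs_presence else
          tr$max_epochs_count,
        patience = tr$patience,
        seed = derive_seed(config$seed, 2000L + fold * 10L +
                             (task == "count")))
      model <- train_cnn(model, make_ds(rows_tr), make_ds(rows_va), cfg_tr)
      histories[[paste(task, fold, sep = "_")]] <-
        cbind(task = task, fold = fold, attr(model, "history"))
      reports[[task]][[fold]] <- evaluate_fold(model, make_ds(rows_te),
                                               rows_te$label,
                                               rows_te$bucket_id)
      if (task == "presence" && fold == 1L) fold_models$presence1 <- model
      if (task == "count") {
        test_buckets <- fold_roles(plan, fold)$test
        trows <- tiles[tiles$bucket_id %in% test_buckets, , drop = FALSE]
        if (nrow(trows)) {
          probs <- predict_cnn(model, make_ds_cols(volumes, trows, ds$w))
          trows$predicted <- attr(probs, "class_ids")
          tile_pred_rows[[fold]] <- trows
        }
      }
    }
  }
  pooled <- list(presence = aggregate_folds(reports$presence),
                 count = aggregate_folds(reports$count))

  # ---- bucket-count integration ----
  tile_pred <- do.call(rbind, tile_pred_rows)
  est <- bucket_estimates(tile_pred, truth, ge2_value = config$ge2_value)
  dist_metrics <- distribution_metrics(est)
  utils::write.csv(est, file.path(config$out_dir, "bucket_estimates.csv"),
                   row.names = FALSE)
  map_dir <- file.path(config$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  first_a <- est$bucket_id[est$bucket_type == "A"][1]
  if (!is.na(first_a)) {
    rows <- tile_pred[tile_pred$bucket_id == first_a, ]
    render_distribution_map(rows, w = ds$w,
                            path = file.path(map_dir,
                                             paste0(first_a, "_map.png")))
  }

  # ---- Grad-CAM examples from the first presence fold ----
  gc_dir <- file.path(config$out_dir, "gradcam")
  bal_p <- balanced$presence
  role1 <- sample_roles(plan, 1L, bal_p)
  te1 <- bal_p[role1 == "test", , drop = FALSE]
  n_ex <- min(config$gradcam$n_examples, nrow(te1))
  if (n_ex > 0L && !is.null(fold_models$presence1)) {
    model_p <- fold_models$presence1
    pick <- unique(round(seq(1L, nrow(te1), length.out = n_ex)))
    for (i in pick) {
      vox <- extract_voxel(volumes[[te1$bucket_id[i]]], te1$x0[i],
                           te1$y0[i], ds$w)
      pr <- predict_cnn(model_p, vox)
      pred_lab <- attr(pr, "class_ids")[1]
      att <- grad_cam(model_p, vox, target_class = pred_lab)
      render_explanation(vox, att, gc_dir, te1$bucket_id[i], te1$x0[i],
                         te1$y0[i], pred_lab, te1$label[i],
                         block = config$gradcam$block)
    }
  }

  # ---- summary + manifest ----
  summary <- list(
    config_hash = hash,
    presence_roc_auc = pooled$presence$roc_auc,
    presence_accuracy = pooled$presence$accuracy,
    presence_f1 = pooled$presence$f1,
    count_macro_roc_auc = pooled$count$macro_roc_auc,
    count_accuracy = pooled$count$accuracy,
    count_macro_f1 = pooled$count$macro_f1,
    bucket_mae_by_type = as.list(dist_metrics$mae_by_type),
    bucket_mre_by_type = as.list(dist_metrics$mre_by_type),
    count_correlation_overall = dist_metrics$correlation_overall,
    count_correlation_clam_types = dist_metrics$correlation_clam_types)
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA)
  history <- do.call(rbind, c(histories, make.row.names = FALSE))
  utils::write.csv(history,
                   file.path(config$out_dir, "training_history.csv"),
                   row.names = FALSE)
  manifest_info <- list(
    package_version = as.character(utils::packageVersion("asariscan")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    config_hash = hash,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list(summary = "summary.json",
                   ground_truth = "ground_truth.csv",
                   bucket_estimates = "bucket_estimates.csv",
                   training_history = "training_history.csv"))
  jsonlite::write_json(manifest_info,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(summary = summary,
                 presence_report = pooled$presence,
                 count_report = pooled$count,
                 bucket_estimates = est,
                 distribution = dist_metrics,
                 history = history,
                 fold_plan = plan,
                 paths = list(out_dir = config$out_dir,
                              summary = summary_path)))
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()]
#' @param path YAML file path
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the [run_config()] rebuilt through the defaults (so a partial
#'   YAML file overrides only the fields it names).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw_cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw_cfg), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw_cfg)
}

make_ds_cols <- function(volumes, rows, w) {
  cnn_dataset(function(i) extract_voxel(volumes[[rows$bucket_id[i]]],
                                        rows$x0[i], rows$y0[i], w),
              rep(NA_character_, nrow(rows)), n = nrow(rows))
}
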