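#' Pipeline configuration
#'
#' Assembles an end-to-end run: keyframe selection, an optional external
#' structure-from-motion (SfM) reconstruction adapter, passthrough filtering,
#' downsampling, stem/silique segmentation, sparse-to-dense mapping and
#' counting. Every stage can be toggled; a run may start from a supplied
#' cloud instead of video frames. The global seed feeds every stochastic
#' stage.
#'
#' @param stages Character vector of enabled stages, in pipeline order, from
#'   `c("keyframes", "sfm", "filter", "downsample", "segment", "map",
#'   "count")`.
#' @param frames Frame list (or a directory of PNGs) for the keyframe stage.
#' @param cloud A point cloud (or a cloud file path) to start from when the
#'   reconstruction stages are disabled.
#' @param keyframes A [keyframe_params()] or `NULL` for defaults.
#' @param sfm_backend A function `(keyframe_dir, out_ply)` invoking an
#'   external SfM tool; no reconstruction is performed in-package.
#' @param filter A `list(axis, lo, hi)` for [passthrough()].
#' @param downsample_n,downsample_method Downsampling target and method.
#' @param segmenter `"baseline"` or a trained `dgcnn_model` (or a checkpoint
#'   path).
#' @param baseline Arguments for [baseline_segment()].
#' @param mapping_radius Radius for [map_sparse_to_dense()].
#' @param counting A [counting_params()].
#' @param truth Optional generator `truth` tibble (scores recovered lines) or
#'   a single known true count; enables the closing count report.
#' @param run_dir Directory for stage artifacts; `NULL` disables persistence.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("filter", "downsample", "segment",
                                       "map", "count"),
                            frames = NULL, cloud = NULL, keyframes = NULL,
                            sfm_backend = NULL, filter = NULL,
                            downsample_n = 8192, downsample_method = "fps",
                            segmenter = "baseline",
                            baseline = list(height_quantile = 0.4),
                            mapping_radius = 0.01,
                            counting = counting_params(), truth = NULL,
                            run_dir = NULL, seed = 0) {
  known <- c("keyframes", "sfm", "filter", "downsample", "segment", "map",
             "count")
  if (length(stages) == 0) abort("no stage enabled")
  if (!all(stages %in% known)) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  structure(list(stages = known[known %in% stages], frames = frames,
                 cloud = cloud, keyframes = keyframes,
                 sfm_backend = sfm_backend, filter = filter,
                 downsample_n = downsample_n,
                 downsample_method = downsample_method, segmenter = segmenter,
                 baseline = baseline, mapping_radius = mapping_radius,
                 counting = counting, truth = truth, run_dir = run_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `counting` and `keyframes` blocks are passed to [counting_params()] and
#' [keyframe_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$counting)) args$counting <- do.call(counting_params, y$counting)
  if (!is.null(y$keyframes)) args$keyframes <- do.call(keyframe_params, y$keyframes)
  do.call(pipeline_config, args)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

persist_cloud <- function(cloud, config, file) {
  if (!is.null(config$run_dir)) {
    dir.create(config$run_dir, showWarnings = FALSE, recursive = TRUE)
    write_cloud(cloud, file.path(config$run_dir, file))
  }
  invisible(cloud)
}

#' Run the silique identification pipeline
#'
#' Executes the enabled stages in order, persisting each intermediate under
#' `run_dir` when set: keyframe manifest, reconstructed/filtered cloud, sparse
#' labels, dense canopy cloud, per-silique line models and (when truth is
#' available) the closing count report JSON. Re-running with the same config
#' and seed reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage artifacts: `keyframes`, `cloud`, `sparse`,
#'   `canopy`, `lines`, `count`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$stages) == 0) abort("no stage enabled")
  out <- list()
  cloud <- config$cloud
  if (is.character(cloud)) cloud <- read_cloud(cloud)

  if ("keyframes" %in% config$stages) {
    out$keyframes <- pipeline_stage("keyframes", {
      frames <- config$frames
      if (is.character(frames)) frames <- read_frames(frames)
      if (is.null(frames)) abort("no frames supplied")
      sel <- select_keyframes(frames, config$keyframes)
      if (!is.null(config$run_dir)) {
        write_keyframes(frames, sel, file.path(config$run_dir, "keyframes"))
      }
      sel
    })
  }
  if ("sfm" %in% config$stages) {
    cloud <- pipeline_stage("sfm", {
      if (is.null(config$sfm_backend)) {
        if (is.null(cloud)) {
          abort("no SfM backend configured and no cloud supplied")
        }
        warn("no SfM backend configured; starting from the supplied cloud")
        cloud
      } else {
        kf_dir <- file.path(config$run_dir %||% tempdir(), "keyframes")
        ply <- file.path(config$run_dir %||% tempdir(), "reconstruction.ply")
        config$sfm_backend(kf_dir, ply)
        read_cloud(ply)
      }
    })
  }
  if (is.null(cloud) && any(c("filter", "downsample", "segment", "map",
                              "count") %in% config$stages)) {
    abort("pipeline needs a point cloud for the geometry stages")
  }

  if ("filter" %in% config$stages && !is.null(config$filter)) {
    cloud <- pipeline_stage("filter", {
      f <- config$filter
      persist_cloud(passthrough(cloud, f$axis, f$lo, f$hi), config,
                    "filtered.txt")
    })
  }
  out$cloud <- cloud

  sparse <- cloud
  if ("downsample" %in% config$stages) {
    sparse <- pipeline_stage("downsample", {
      n <- min(config$downsample_n, nrow(cloud))
      downsample(cloud, n, method = config$downsample_method,
                 seed = config$seed)
    })
  }
  if ("segment" %in% config$stages) {
    sparse <- pipeline_stage("segment", {
      seg <- config$segmenter
      labeled <- if (identical(seg, "baseline")) {
        do.call(baseline_segment, c(list(sparse), config$baseline))
      } else {
        if (is.character(seg)) seg <- readRDS(seg)
        segment_cloud(sparse, seg)
      }
      persist_cloud(labeled, config, "sparse_labeled.txt")
    })
  }
  out$sparse <- sparse

  canopy <- sparse
  if ("map" %in% config$stages) {
    canopy <- pipeline_stage("map", {
      persist_cloud(map_sparse_to_dense(sparse, cloud,
                                        radius = config$mapping_radius),
                    config, "canopy_dense.txt")
    })
  } else if ("count" %in% config$stages && is_labeled(canopy)) {
    canopy <- canopy[canopy$label == 1L, , drop = FALSE]
  }
  out$canopy <- canopy

  if ("count" %in% config$stages) {
    out$lines <- pipeline_stage("count", {
      cp <- config$counting
      cp$seed <- cp$seed %||% config$seed
      count_siliques(canopy, cp)
    })
    out$count <- nrow(out$lines)
    if (!is.null(config$truth)) {
      if (is.data.frame(config$truth)) {
        ev <- evaluate_counting(out$lines, config$truth)
        out$report <- counting_metrics(ev$n_true, ev$n_recovered)
      } else {
        out$report <- counting_metrics(config$truth,
                                       min(out$count, config$truth))
      }
    }
    if (!is.null(config$run_dir)) {
      dir.create(config$run_dir, showWarnings = FALSE, recursive = TRUE)
      lines_out <- dplyr::select(as_tibble(out$lines), -dplyr::any_of("inliers"))
      jsonlite::write_json(
        list(count = out$count, lines = lines_out,
             report = if (is.null(out$report)) NULL else
               list(per_plant = out$report$per_plant,
                    totals = out$report$totals,
                    mape_percent = out$report$mape_percent,
                    r_squared = out$report$r_squared)),
        file.path(config$run_dir, "count_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}

#' Per-class segmentation metrics
#'
#' Standard precision, recall, F1 and intersection-over-union (as
#' percentages) per class from predicted and true 0/1 labels.
#'
#' @param predicted,truth Equal-length 0/1 label vectors (or labeled clouds).
#' @return A tibble with one row per class (`stem`, `silique`).
#' @export
segmentation_metrics <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$label
  if (is.data.frame(truth)) truth <- truth$label
  if (length(predicted) != length(truth)) {
    abort("predicted and true label vectors must have the same length")
  }
  per_class <- lapply(c(stem = 0L, silique = 1L), function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
    tibble(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
           iou = 100 * iou)
  })
  dplyr::bind_cols(tibble(class = names(per_class)),
                   dplyr::bind_rows(per_class))
}

#' Bundled per-plant silique counts for 12 rapeseed plants
#'
#' Reference counting results for 12 mature plants of the cultivars Huayouza
#' 62, Zhongshuang 6 and Dadi 55 (manually counted true siliques per plant
#' paired with the number correctly identified by the automated pipeline),
#' bundled as a plain-text table for the metric examples.
#'
#' @return A tibble with columns `variety`, `plant_id`, `true_count`,
#'   `correct_count`.
#' @export
example_plant_counts <- function() {
  path <- system.file("extdata", "rapeseed_counts.csv", package = "siliqueseg")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
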