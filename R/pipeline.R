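#' Full pipeline configuration
#'
#' Assembles the per-stage configurations of the frame-classification
#' pipeline: enhancement, saliency segmentation, backbone fine-tuning and
#' feature extraction, hybrid feature selection, and ELM classification.
#' Every stochastic stage derives its own RNG stream from the global `seed`,
#' so a config + seed pair fully determines the run.
#'
#' @param seed global seed.
#' @param frames in-memory dataset: a list with `images`, `labels` and
#'   optionally `masks` (as produced by [make_frames()]); alternatively set
#'   `recipe` or `data_dir`.
#' @param recipe a [frame_recipe()] used to generate frames when `frames`
#'   and `data_dir` are absent.
#' @param data_dir directory of `*.png` frames plus a `labels.csv`
#'   (`file,label`).
#' @param variant which prefix of the pipeline feeds the classifier:
#'   `"raw"` (original frames), `"enhanced"` (enhanced frames),
#'   `"segmented"` (localized crops), or `"full"` (crops + feature
#'   selection).
#' @param enhance_cfg an [enhancement_config()].
#' @param saliency_epochs,saliency_filters training epochs and filter counts
#'   of the saliency CNN.
#' @param top_k,min_area,morph_radius segmentation parameters (see
#'   [segment_frame()]).
#' @param backbone_arch,embed_dim,input_size backbone settings (see
#'   [backbone_spec()]).
#' @param hp a [hyper_params()] used when BO tuning is disabled.
#' @param finetune_epochs backbone training epochs.
#' @param tune enable Bayesian-optimization hyperparameter tuning.
#' @param tune_budget `c(n_init, n_iter)` BO budget.
#' @param select enable the hybrid whale/Harris-Hawks selector (only
#'   meaningful for the `"full"` variant, where it defaults to on).
#' @param selection_cfg a [selection_config()]; its seed is overridden by
#'   the derived stage seed.
#' @param split `"half"` (stratified 50:50 train/test) or `"tenfold"`
#'   (10-fold cross-validation for the classifier stage).
#' @param elm_hidden,elm_ridge final classifier settings.
#' @param out_dir optional directory for cached stage artifacts and the JSON
#'   report.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            frames = NULL, recipe = NULL, data_dir = NULL,
                            variant = c("full", "segmented", "enhanced",
                                        "raw"),
                            enhance_cfg = enhancement_config(),
                            saliency_epochs = 8, saliency_filters = c(16, 32, 64),
                            top_k = NULL, min_area = 32, morph_radius = 2,
                            backbone_arch = "tiny_cnn", embed_dim = 64,
                            input_size = 64,
                            hp = hyper_params(lr = 0.05, momentum = 0.7,
                                              l2 = 1e-6),
                            finetune_epochs = 15,
                            tune = FALSE, tune_budget = c(4, 4),
                            select = NULL,
                            selection_cfg = selection_config(pop = 10,
                                                             iters = 30,
                                                             hho_iters = 10),
                            split = c("half", "tenfold"),
                            elm_hidden = 200, elm_ridge = 1e-6,
                            out_dir = NULL) {
  variant <- match.arg(variant)
  split <- match.arg(split)
  if (is.null(select)) select <- variant == "full"
  structure(list(seed = seed, frames = frames, recipe = recipe,
                 data_dir = data_dir, variant = variant,
                 enhance_cfg = enhance_cfg,
                 saliency_epochs = saliency_epochs,
                 saliency_filters = saliency_filters,
                 top_k = top_k, min_area = min_area,
                 morph_radius = morph_radius,
                 backbone_arch = backbone_arch, embed_dim = embed_dim,
                 input_size = input_size, hp = hp,
                 finetune_epochs = finetune_epochs, tune = tune,
                 tune_budget = tune_budget, select = select,
                 selection_cfg = selection_cfg, split = split,
                 elm_hidden = elm_hidden, elm_ridge = elm_ridge,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# stage seeds derived from the global seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(data = 11L, saliency = 23L, tune = 37L, backbone = 41L,
            selection = 53L, split = 67L, elm = 79L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

load_pipeline_frames <- function(config) {
  if (!is.null(config$frames)) return(config$frames)
  if (!is.null(config$data_dir)) {
    lab <- utils::read.csv(file.path(config$data_dir, "labels.csv"),
                           stringsAsFactors = FALSE)
    images <- lapply(file.path(config$data_dir, lab$file), read_rgb_image)
    return(list(images = images, labels = as.integer(lab$label),
                masks = NULL))
  }
  if (!is.null(config$recipe)) return(make_frames(config$recipe))
  stop("no data source: set `frames`, `recipe` or `data_dir`",
       call. = FALSE)
}

# config-keyed stage cache: an .rds artifact is valid when its sidecar JSON
# equals the serialized stage key
cache_get <- function(out_dir, stage, key) {
  if (is.null(out_dir)) return(NULL)
  rds <- file.path(out_dir, paste0(stage, ".rds"))
  sc <- file.path(out_dir, paste0(stage, ".key.json"))
  if (!file.exists(rds) || !file.exists(sc)) return(NULL)
  if (!identical(readLines(sc, warn = FALSE), key)) return(NULL)
  readRDS(rds)
}

cache_put <- function(out_dir, stage, key, value) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, file.path(out_dir, paste0(stage, ".rds")))
  writeLines(key, file.path(out_dir, paste0(stage, ".key.json")))
  invisible(NULL)
}

stage_key <- function(config, fields) {
  sub <- config[fields]
  sub$frames <- NULL
  as.character(jsonlite::toJSON(sub, auto_unbox = TRUE, digits = NA,
                                force = TRUE))
}

#' Run the frame-classification pipeline
#'
#' Executes the stages selected by `config$variant` in order — enhancement,
#' saliency segmentation/localization, backbone fine-tuning and feature
#' extraction, hybrid feature selection, ELM classification — and returns a
#' run report. Stage outputs are cached under `config$out_dir` (keyed by the
#' relevant config subset plus the seed) and reused on reruns.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_report`: accuracy, confusion matrix,
#'   per-class recall, realized feature dimensions before and after
#'   selection, segmentation IoU (when ground-truth masks exist), per-stage
#'   timings, and a config echo sufficient to reproduce the run.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function() Sys.time()
  tock <- function(t0, nm) {
    timings[nm] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  t0 <- tick()
  data <- load_pipeline_frames(config)
  images <- data$images
  labels <- as.integer(data$labels)
  n <- length(images)
  stopifnot(n == length(labels), n >= 4)
  tock(t0, "data")

  split <- stratified_split(labels, 0.5, seed = stage_seed(config$seed,
                                                           "split"))

  # --- enhancement -------------------------------------------------------
  enhanced <- NULL
  if (config$variant != "raw") {
    t0 <- tick()
    key <- stage_key(config, c("seed", "enhance_cfg", "recipe", "data_dir"))
    enhanced <- cache_get(config$out_dir, "enhanced", key)
    if (is.null(enhanced)) {
      enhanced <- lapply(images, enhance, cfg = config$enhance_cfg)
      cache_put(config$out_dir, "enhanced", key, enhanced)
    }
    tock(t0, "enhance")
  }

  # --- saliency segmentation --------------------------------------------
  crops <- NULL
  seg_masks <- NULL
  saliency_acc <- NA_real_
  if (config$variant %in% c("segmented", "full")) {
    t0 <- tick()
    key <- stage_key(config, c("seed", "enhance_cfg", "recipe", "data_dir",
                               "saliency_epochs", "saliency_filters",
                               "top_k", "min_area", "morph_radius"))
    seg <- cache_get(config$out_dir, "segmentation", key)
    if (is.null(seg)) {
      scfg <- saliency_train_config(epochs = config$saliency_epochs,
                                    seed = stage_seed(config$seed,
                                                      "saliency"))
      spec <- saliency_cnn_spec(dim(enhanced[[1]]),
                                n_classes = max(labels),
                                filters = config$saliency_filters)
      model <- train_saliency_cnn(enhanced[split$train],
                                  labels[split$train], scfg, spec)
      seg_masks <- vector("list", n)
      crops <- vector("list", n)
      for (i in seq_len(n)) {
        sf <- segment_frame(model, images[[i]], enhanced[[i]],
                            top_k = config$top_k,
                            min_area = config$min_area,
                            morph_radius = config$morph_radius)
        seg_masks[[i]] <- sf$region_mask
        crops[[i]] <- if (length(sf$regions) > 0) sf$regions[[1]]$crop
                      else images[[i]]
      }
      seg <- list(masks = seg_masks, crops = crops,
                  saliency_acc = model$train_accuracy)
      cache_put(config$out_dir, "segmentation", key, seg)
    }
    seg_masks <- seg$masks
    crops <- seg$crops
    saliency_acc <- seg$saliency_acc
    tock(t0, "segment")
  } else {
    crops <- if (config$variant == "raw") images else enhanced
  }

  mean_iou <- NA_real_
  if (!is.null(seg_masks) && !is.null(data$masks)) {
    ious <- mapply(mask_iou, seg_masks, data$masks)
    mean_iou <- mean(ious)
  }

  # --- backbone ----------------------------------------------------------
  t0 <- tick()
  spec <- backbone_spec(config$backbone_arch, n_classes = max(labels),
                        embed_dim = if (config$backbone_arch == "tiny_cnn")
                          config$embed_dim else NULL,
                        input_size = config$input_size)
  hp <- config$hp
  tune_history <- NULL
  if (config$tune) {
    tr <- tune_hyperparams(crops[split$train], labels[split$train],
                           crops[split$test], labels[split$test],
                           spec = spec,
                           n_init = config$tune_budget[1],
                           n_iter = config$tune_budget[2],
                           seed = stage_seed(config$seed, "tune"))
    hp <- tr$hp
    tune_history <- tr$history
  }
  model <- build_backbone(spec, seed = stage_seed(config$seed, "backbone"))
  model <- finetune(model, crops[split$train], labels[split$train], hp,
                    epochs = config$finetune_epochs,
                    seed = stage_seed(config$seed, "backbone"))
  features <- extract_features(model, crops)
  tock(t0, "backbone")

  # --- feature selection -------------------------------------------------
  dim_before <- ncol(features)
  mask <- rep(1L, dim_before)
  sel_history <- NULL
  if (config$select) {
    t0 <- tick()
    scfg <- config$selection_cfg
    scfg$seed <- stage_seed(config$seed, "selection")
    sel <- hybrid_select(features[split$train, , drop = FALSE],
                         labels[split$train], scfg)
    mask <- sel$mask
    sel_history <- sel$history
    tock(t0, "select")
  }
  dim_after <- sum(mask)
  feats_sel <- features[, mask == 1, drop = FALSE]

  # --- classification ----------------------------------------------------
  t0 <- tick()
  elm_seed <- stage_seed(config$seed, "elm")
  if (config$split == "half") {
    m <- elm_train(feats_sel[split$train, , drop = FALSE],
                   labels[split$train], hidden_units = config$elm_hidden,
                   ridge = config$elm_ridge, seed = elm_seed)
    pred <- elm_predict(m, feats_sel[split$test, , drop = FALSE])
    metrics <- evaluate_predictions(labels[split$test], pred,
                                    classes = sort(unique(labels)))
  } else {
    folds <- with_seed(elm_seed, sample(rep(1:10, length.out = n)))
    preds <- integer(n)
    for (f in 1:10) {
      te <- which(folds == f)
      if (!length(te)) next
      m <- elm_train(feats_sel[-te, , drop = FALSE], labels[-te],
                     hidden_units = config$elm_hidden,
                     ridge = config$elm_ridge, seed = elm_seed)
      preds[te] <- elm_predict(m, feats_sel[te, , drop = FALSE])
    }
    metrics <- evaluate_predictions(labels, preds,
                                    classes = sort(unique(labels)))
  }
  tock(t0, "classify")

  report <- structure(list(
    accuracy = metrics$accuracy,
    confusion = metrics$confusion,
    recall = metrics$recall,
    dim_before = dim_before,
    dim_after = dim_after,
    mean_iou = mean_iou,
    saliency_train_accuracy = saliency_acc,
    variant = config$variant,
    split = config$split,
    n_train = length(split$train), n_test = length(split$test),
    train_idx = split$train, test_idx = split$test,
    seed = config$seed,
    hp = unclass(hp),
    tune_history = tune_history,
    selection_history = sel_history,
    timings = timings,
    config_echo = stage_key(config, setdiff(names(config),
                                            c("frames", "out_dir")))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir,
                                   paste0("report_", config$variant,
                                          ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# serializable view of a report
report_to_json <- function(report) {
  r <- unclass(report)
  r$confusion <- as.data.frame.matrix(r$confusion)
  r$timings <- as.list(r$timings)
  r
}

#' Strip volatile fields (timings) from a report for comparisons
#' @param report a `pipeline_report`.
#' @return the report without timing information.
#' @export
report_stable <- function(report) {
  report$timings <- NULL
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (variant=%s, split=%s, seed=%s)\n",
              x$variant, x$split, format(x$seed)))
  cat(sprintf("  accuracy: %.4f  (n_train=%d, n_test=%d)\n", x$accuracy,
              x$n_train, x$n_test))
  cat(sprintf("  features: %d -> %d\n", x$dim_before, x$dim_after))
  if (is.finite(x$mean_iou))
    cat(sprintf("  segmentation mean IoU: %.3f\n", x$mean_iou))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Run the four-experiment ablation over pipeline variants
#'
#' Runs the requested variants on the identical dataset, split and seed,
#' mirroring the original / enhanced / segmented / full experiment design.
#'
#' @param config a [pipeline_config()] (its `variant` is overridden).
#' @param variants subset of `c("raw", "enhanced", "segmented", "full")`.
#' @return list with `reports` (one `pipeline_report` per variant) and
#'   `summary` (data.frame: variant, accuracy, dim_after).
#' @export
run_ablation <- function(config, variants = c("raw", "full")) {
  bad <- setdiff(variants, c("raw", "enhanced", "segmented", "full"))
  if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  reports <- list()
  data <- load_pipeline_frames(config)
  for (v in variants) {
    cfg <- config
    cfg$variant <- v
    cfg$frames <- data
    cfg$recipe <- NULL
    cfg$select <- v == "full"
    reports[[v]] <- run_pipeline(cfg)
  }
  list(reports = reports,
       summary = data.frame(
         variant = variants,
         accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
         dim_after = vapply(reports, function(r) r$dim_after, numeric(1))))
}
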