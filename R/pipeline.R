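#' Full run configuration
#'
#' Bundles every stage configuration for one reproducible pipeline run.
#' Exactly one of `input_dir` (read spectra + labels.csv from disk) or
#' `synthetic = TRUE` (generate the cohort) must be chosen.
#'
#' @param synthetic Generate the cohort from `cohort` when TRUE.
#' @param input_dir Directory of spectrum files plus labels.csv.
#' @param cohort A [cohort_config()].
#' @param preprocessing A [preprocess_config()].
#' @param augment An [augment_config()].
#' @param k Number of peak features per sample.
#' @param layer_sizes Autoencoder hidden sizes.
#' @param sae Template [sae_hyper()] for pretraining.
#' @param softmax A [softmax_hyper()].
#' @param finetune_rate,finetune_epochs Fine-tuning settings.
#' @param split A [split_spec()].
#' @param seed Global seed; when supplied it overrides the seeds of all
#'   sub-configurations so one integer reproduces the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = TRUE, input_dir = NULL,
                       cohort = cohort_config(),
                       preprocessing = preprocess_config(),
                       augment = augment_config(),
                       k = 50, layer_sizes = c(100, 40),
                       sae = sae_hyper(layer_sizes[1]),
                       softmax = softmax_hyper(),
                       finetune_rate = 0.1, finetune_epochs = 1000,
                       split = split_spec(), seed = NULL) {
  if (isTRUE(synthetic) == !is.null(input_dir)) {
    stop("set exactly one of synthetic = TRUE or input_dir")
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    cohort$seed <- seed
    sae$seed <- seed
    softmax$seed <- seed
    split$seed <- seed
  }
  structure(list(synthetic = isTRUE(synthetic), input_dir = input_dir,
                 cohort = cohort, preprocessing = preprocessing,
                 augment = augment, k = as.integer(k),
                 layer_sizes = as.integer(layer_sizes), sae = sae,
                 softmax = softmax, finetune_rate = finetune_rate,
                 finetune_epochs = as.integer(finetune_epochs),
                 split = split, seed = seed),
            class = "run_config")
}

#' Run the complete pipeline
#'
#' simulate/ingest -> preprocess -> augment -> featurize -> split
#' (augmented copies stay with their source sample) -> min-max scale on
#' the training partition -> greedy pretraining + softmax + fine-tuning
#' -> per-partition evaluation. Everything is a pure function of
#' (config, seed).
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the model checkpoint,
#'   metrics, traces and resolved configuration are written there.
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `model`, `features` (scaled), `partitions`,
#'   `metrics` (per-partition reports), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (config$synthetic) generate_cohort(config$cohort)
            else read_cohort(config$input_dir)
  clean <- preprocess_set(cohort, config$preprocessing)
  aug <- augment_cohort(clean, config$augment)
  fm <- featurize(aug, k = config$k)
  parts <- split_data(fm$labels, config$split, groups = fm$groups)

  train_fm <- scale_features(subset_features(fm, parts$train))
  fm_scaled <- scale_features(fm, scaling = train_fm$scaling)

  model <- train_dssaenn(
    fm_scaled$values[parts$train, , drop = FALSE],
    fm_scaled$labels[parts$train],
    layer_sizes = config$layer_sizes,
    sae = config$sae, softmax = config$softmax,
    finetune_rate = config$finetune_rate,
    finetune_epochs = config$finetune_epochs,
    feature_scaling = train_fm$scaling)

  metrics <- evaluate_model(model, fm_scaled, parts)
  result <- list(model = model, features = fm_scaled, partitions = parts,
                 metrics = metrics, config = config)

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      stop("output directory ", out_dir, " is not empty (use force = TRUE)")
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(out_dir, "model.json"),
                    extra = list(k = config$k))
    for (nm in names(metrics)) {
      write_metrics(metrics[[nm]], file.path(out_dir, paste0("metrics_", nm)))
    }
    utils::write.csv(do.call(rbind, lapply(seq_along(model$pretrain_traces),
      function(i) cbind(layer = i, model$pretrain_traces[[i]]))),
      file.path(out_dir, "pretrain_trace.csv"), row.names = FALSE)
    utils::write.csv(data.frame(epoch = seq_along(model$trace),
                                cross_entropy = model$trace),
                     file.path(out_dir, "finetune_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(serialize_config(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Write a synthetic cohort to disk
#'
#' One CSV per spectrum plus a `labels.csv` table and the resolved
#' generator configuration.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, `out_dir`.
#' @export
simulate_cohort_files <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set <- generate_cohort(config)
  for (s in set$spectra) {
    write_spectrum(s, file.path(out_dir, paste0(s$sample_id, ".csv")))
  }
  write_label_table(set, file.path(out_dir, "labels.csv"))
  jsonlite::write_json(serialize_config(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

checkpoint_schema_version <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing JSON file holding the schema
#' version, layer sizes, all weight matrices and biases, the softmax
#' head, the feature-scaling statistics and the training seed.
#'
#' @param model An [ssae_model()].
#' @param path Checkpoint path (JSON).
#' @param extra Optional named list merged into the checkpoint.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "ssae_model"))
  payload <- c(list(
    schema_version = checkpoint_schema_version,
    layer_sizes = model$layer_sizes,
    input_size = model$input_size,
    seed = model$seed,
    layers = lapply(model$layers, function(p)
      list(W = p$W, b = p$b, W_dec = p$W_dec, b_dec = p$b_dec)),
    softmax = list(W = model$softmax$W, b = model$softmax$b),
    feature_scaling = model$feature_scaling
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(raw$schema_version) ||
      raw$schema_version != checkpoint_schema_version) {
    stop("unsupported checkpoint schema version: ",
         if (is.null(raw$schema_version)) "missing" else raw$schema_version)
  }
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  layers <- lapply(seq_along(raw$layer_sizes), function(i) {
    l <- raw$layers[[i]]
    structure(list(W = as_mat(l$W), b = as.numeric(unlist(l$b)),
                   W_dec = as_mat(l$W_dec),
                   b_dec = as.numeric(unlist(l$b_dec))),
              class = "sae_params")
  })
  softmax <- list(W = as_mat(raw$softmax$W),
                  b = as.numeric(unlist(raw$softmax$b)))
  scaling <- if (!is.null(raw$feature_scaling)) {
    list(min = as.numeric(unlist(raw$feature_scaling$min)),
         max = as.numeric(unlist(raw$feature_scaling$max)))
  } else NULL
  model <- ssae_model(layers, softmax, feature_scaling = scaling,
                      seed = if (is.null(raw$seed)) NA_integer_ else raw$seed)
  model$k <- raw$k
  model
}

#' Evaluate a saved checkpoint on a cohort directory
#'
#' Applies the stored preprocessing-independent feature pipeline
#' (peak features + the checkpoint's scaling statistics), predicts, and
#' returns the pooled metrics report.
#'
#' @param checkpoint_path Path to a [save_checkpoint()] file.
#' @param data_dir Directory of spectrum files plus labels.csv.
#' @param preprocessing A [preprocess_config()] applied to the spectra.
#' @param augment An [augment_config()] (cropping only by default at
#'   evaluation time: no shifted copies are added).
#' @return List with `report` (a `metrics_report`) and `predictions`.
#' @export
evaluate_checkpoint <- function(checkpoint_path, data_dir,
                                preprocessing = preprocess_config(),
                                augment = augment_config(directions = character(0))) {
  model <- load_checkpoint(checkpoint_path)
  set <- read_cohort(data_dir)
  clean <- preprocess_set(set, preprocessing)
  aug <- augment_cohort(clean, augment)
  k <- if (!is.null(model$k)) model$k else model$input_size
  fm <- featurize(aug, k = k)
  if (ncol(fm$values) != model$input_size) {
    stop("feature dimension mismatch: expected ", model$input_size,
         ", got ", ncol(fm$values))
  }
  fm <- scale_features(fm, scaling = model$feature_scaling)
  pred <- predict(model, fm$values)
  list(report = metrics_report(fm$labels, pred$labels, pred$prob),
       predictions = data.frame(sample_id = fm$sample_ids,
                                truth = as.character(fm$labels),
                                predicted = as.character(pred$labels)))
}
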