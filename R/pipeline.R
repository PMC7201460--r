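#' Pipeline configuration
#'
#' One nested configuration drives the whole workflow: dataset generation,
#' preprocessing, network, training, evaluation and counting. The global
#' `seed` propagates to every stochastic stage (scene generation, the
#' train/test split, weight initialization, shuffling).
#'
#' @param out_dir Run directory for all artifacts.
#' @param dataset_dir Where the generated dataset lives (default
#'   `out_dir/dataset`).
#' @param smear List of [smear_config()] arguments.
#' @param input_size Network input `c(h, w)`.
#' @param network List of [network_spec()] arguments (minus `input_size`).
#' @param train List of [train_config()] arguments (minus `seed`).
#' @param split List with `n_train`, `n_test`; `NULL` reserves ~5% (at
#'   least 1 image) for testing.
#' @param metrics List: `bf_tolerance`, `include_background`,
#'   `bf_aggregation`.
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "hemaseg_run",
                            dataset_dir = NULL,
                            smear = list(),
                            input_size = c(64L, 64L),
                            network = list(widths = c(8L, 16L)),
                            train = list(epochs = 5L),
                            split = NULL,
                            metrics = list(),
                            seed = 1L) {
  structure(list(
    out_dir = out_dir,
    dataset_dir = dataset_dir %||% file.path(out_dir, "dataset"),
    smear = smear,
    input_size = as.integer(input_size),
    network = network,
    train = train,
    split = split,
    metrics = metrics,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_hemaseg("hemaseg_invalid_config",
                 "unknown config keys: %s", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = unique(c("hemaseg_stage_error", class(e))),
      list(message = sprintf("[%s] %s", name, conditionMessage(e)),
           call = conditionCall(e), stage = name)
    ))
  })
}

log_stage <- function(name, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), name,
                  sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' generate -> preprocess -> train -> evaluate -> count, writing every
#' artifact (dataset index, split, checkpoint, training log and plots,
#' evaluation report, count report, resolved config, manifest) into the run
#' directory. Rerunning with the same config and seed reproduces the
#' reports.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return The run directory path, invisibly.
#' @export
run_end_to_end <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("setup", "seed = %d, out = %s", config$seed, config$out_dir)
  yaml::write_yaml(unclass(config), file.path(config$out_dir,
                                              "config_resolved.yaml"))

  index <- stage("generate", {
    smear <- do.call(smear_config, config$smear)
    scenes <- generate_scenes(smear, config$seed)
    log_stage("generate", "%d scenes on %dx%d canvas", length(scenes),
              smear$canvas[1], smear$canvas[2])
    write_dataset(scenes, config$dataset_dir)
  })

  split_index <- stage("preprocess", {
    if (nrow(index) == 0L) {
      stop_hemaseg("hemaseg_no_data", "dataset contains no images")
    }
    n <- nrow(index)
    n_test <- config$split$n_test %||% max(1L, round(0.05 * n))
    n_train <- config$split$n_train %||% (n - n_test)
    si <- split_datastore(index, n_train, n_test, config$seed)
    utils::write.csv(si, file.path(config$out_dir, "split.csv"),
                     row.names = FALSE)
    log_stage("preprocess", "%d train / %d test at %dx%d", n_train, n_test,
              config$input_size[1], config$input_size[2])
    si
  })

  trained <- stage("train", {
    net_args <- config$network
    net_args$input_size <- config$input_size
    spec <- do.call(network_spec, net_args)
    model <- build_network(spec, seed = config$seed)
    tr_args <- config$train
    tr_args$seed <- config$seed
    tcfg <- do.call(train_config, tr_args)
    res <- train_model(model, split_index, tcfg, out_dir = config$out_dir)
    save_checkpoint(res$model, file.path(config$out_dir, "checkpoint.rds"))
    write_train_log(res, file.path(config$out_dir, "train_log.csv"))
    plot_training(res, file.path(config$out_dir, "training_epochs.png"))
    plot_training(res, file.path(config$out_dir, "training_iterations.png"),
                  by = "iteration")
    log_stage("train", "%d iterations, final loss %.4f", nrow(res$log),
              res$log$loss[nrow(res$log)])
    res
  })

  evaluation <- stage("evaluate", {
    ev <- do.call(evaluate_model, c(list(model = trained$model,
                                         datastore = split_index),
                                    config$metrics))
    write_evaluation_report(ev, file.path(config$out_dir, "evaluation"))
    log_stage("evaluate", "global accuracy %.4f", ev$summary$GlobalAccuracy)
    ev
  })

  stage("count", {
    pairs <- load_split(split_index, "test", config$input_size)
    preds <- lapply(pairs, function(p) {
      predict_image(trained$model, p$image)$label
    })
    rep_pred <- pixel_counts(preds)
    write_count_report(rep_pred, file.path(config$out_dir, "counts"),
                       plot = TRUE)
    rep_truth <- pixel_counts(lapply(pairs, `[[`, "label"))
    write_count_report(rep_truth, file.path(config$out_dir, "counts_truth"))
    log_stage("count", "predicted foreground pixels: %d",
              as.integer(sum(rep_pred$counts)))
  })

  manifest <- c("config_resolved.yaml", "dataset/index.csv", "split.csv",
                "checkpoint.rds", "train_log.csv", "training_epochs.png",
                "training_iterations.png", "evaluation/evaluation_classwise.csv",
                "evaluation/evaluation_summary.csv",
                "evaluation/evaluation_summary.json", "counts/counts.csv",
                "counts/counts.json", "counts_truth/counts.csv")
  jsonlite::write_json(list(artifacts = manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(config$out_dir)
}
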