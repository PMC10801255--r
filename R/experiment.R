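#' Default experiment configuration
#'
#' Mirrors the small-dataset protocol: batch size 32, hidden width 64, 10
#' communication rounds, 5 local epochs (converted to minibatch iterations),
#' checkpoints every 5 rounds, radius 1e-4, beta 0.5.
#'
#' @return a nested configuration list accepted by [run_experiment()].
#' @export
default_config <- function() {
  list(
    data = list(n = 2000L, d = 20L, K = 2L, n_clients = 4L, alpha = 0.1,
                class_separation = 2, attribute_shift = 1,
                label_noise = 0.05, test_fraction = 0.2,
                attributes = list(list(name = "sex", n_values = 2L,
                                       probs = c(0.5, 0.5)))),
    train = list(method = "fedufo", level = "client", rho = 1e-4,
                 beta = 0.5, gamma = 1, eta = 0.01, rounds = 10L,
                 local_epochs = 5L, batch_size = 32L, optimizer = "adam",
                 hidden_width = 64L, checkpoint_every = 5L),
    seed = 1L
  )
}

config_to_spec <- function(cfg) {
  synthetic_spec(
    n = cfg$data$n, d = cfg$data$d, K = cfg$data$K,
    n_clients = cfg$data$n_clients, alpha = cfg$data$alpha,
    attribute_spec = lapply(cfg$data$attributes, function(a) {
      list(name = a$name, n_values = as.integer(a$n_values),
           probs = as.numeric(unlist(a$probs)))
    }),
    class_separation = cfg$data$class_separation,
    attribute_shift = cfg$data$attribute_shift,
    label_noise = cfg$data$label_noise,
    seed = as.integer(cfg$seed)
  )
}

# local epochs -> minibatch iterations: epochs * ceiling(mean client train
# size / batch size)
epochs_to_iters <- function(epochs, benchmark, batch_size) {
  mean_n <- mean(vapply(benchmark$train$client_rows, length, 1L))
  as.integer(max(1, epochs * ceiling(mean_n / batch_size)))
}

validate_config <- function(cfg) {
  need <- function(path, ok) {
    if (!ok) stop("config error at ", path, call. = FALSE)
  }
  need("data", is.list(cfg$data))
  need("train", is.list(cfg$train))
  need("seed", is.numeric(cfg$seed))
  need("data.n", is.numeric(cfg$data$n) && cfg$data$n >= 1)
  need("train.method",
       cfg$train$method %in% c("fedufo", "fedavg", "local", "centralized"))
  need("train.level",
       cfg$train$level %in% c("client", "attribute", "multilevel", "agnostic"))
  need("train.rho", is.numeric(cfg$train$rho) && cfg$train$rho >= 0)
  need("train.beta", is.numeric(cfg$train$beta) &&
         cfg$train$beta >= 0 && cfg$train$beta <= 1)
  invisible(cfg)
}

#' Run a complete experiment from a configuration
#'
#' Executes synthesize -> partition -> train -> checkpoint-select ->
#' evaluate and writes all artifacts (metrics JSON, trace CSV, manifest
#' JSON, config echo) into `out_dir`. The configuration may be a nested
#' list (see [default_config()]) or a path to a YAML file with the same
#' structure.
#'
#' @param config configuration list or YAML path.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return list with `metrics` (a `metrics_report`), `result` (the run),
#'   `benchmark`, and `config`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  validate_config(cfg)
  benchmark <- make_benchmark(config_to_spec(cfg),
                              test_fraction = cfg$data$test_fraction)
  E <- if (!is.null(cfg$train$local_iters)) {
    as.integer(cfg$train$local_iters)
  } else {
    epochs_to_iters(cfg$train$local_epochs, benchmark, cfg$train$batch_size)
  }
  schedule <- training_schedule(
    R = cfg$train$rounds, E = E, eta = cfg$train$eta,
    gamma = cfg$train$gamma, batch_size = cfg$train$batch_size,
    optimizer = cfg$train$optimizer, hidden_width = cfg$train$hidden_width,
    checkpoint_every = cfg$train$checkpoint_every)
  uspec <- uncertainty_set_spec(cfg$train$level, rho = cfg$train$rho,
                                beta = cfg$train$beta)
  seed <- as.integer(cfg$seed)
  result <- switch(cfg$train$method,
    fedufo = run_fedufo(benchmark, uspec, schedule, seed),
    fedavg = run_fedavg(benchmark, schedule, seed),
    centralized = run_centralized(benchmark, schedule, seed),
    local = run_local(benchmark, schedule, seed)
  )
  metrics <- if (cfg$train$method == "local") {
    # evaluate each local model on its own client's held-out rows is the
    # convention; here we report the per-client models' pooled metrics via
    # each client's own model
    accs <- vapply(seq_along(result), function(i) {
      rows <- benchmark$test$client_rows[[i]]
      mean(predict_class(result[[i]]$final_state,
                         benchmark$dataset$features[rows, , drop = FALSE]) ==
             benchmark$dataset$labels[rows])
    }, 0)
    list(client_accuracy = accs, disparity_client = disparity(accs),
         overall_acc = sum(accs * vapply(benchmark$test$client_rows,
                                         length, 1L)) /
           sum(vapply(benchmark$test$client_rows, length, 1L)))
  } else {
    selected <- select_checkpoint(result, benchmark)
    evaluate_model(selected, benchmark$dataset, benchmark$test,
                   benchmark$attribute_columns)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(benchmark$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(result$trace)) {
      utils::write.csv(result$trace, file.path(out_dir, "trace.csv"),
                       row.names = FALSE)
    }
  }
  list(metrics = metrics, result = result, benchmark = benchmark,
       config = cfg)
}

#' Sweep the uncertainty-ball radius
#'
#' Reruns the configured experiment for each radius in `rhos` and collects
#' the accuracy/fairness trade-off, one row per radius (the protocol used to
#' trace the fairness-accuracy frontier as the radius shrinks from 1e-1
#' toward 1e-8).
#'
#' @param config base configuration (list or YAML path).
#' @param rhos numeric vector of radii.
#' @param out_dir optional directory for the sweep CSV.
#' @return data frame: rho, disparity_client, disparity_attribute,
#'   overall_acc.
#' @export
sweep_rho <- function(config = default_config(),
                      rhos = 10^seq(-8, -1), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rows <- lapply(rhos, function(rho) {
    cfg <- utils::modifyList(default_config(), config)
    cfg$train$rho <- rho
    res <- run_experiment(cfg)
    data.frame(rho = rho,
               disparity_client = res$metrics$disparity_client,
               disparity_attribute = res$metrics$disparity_attribute,
               overall_acc = res$metrics$overall_acc)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }
  out
}
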