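ARCHIVE_FORMAT <- "adsnet-model"
ARCHIVE_VERSION <- 1L

#' Content hash of a model's numeric payload
#'
#' MD5 over the serialised parameter arrays; changes iff any array
#' changes.
#'
#' @param model a `rate_network` or `ads_network`.
#' @export
model_hash <- function(model) {
  payload <- model[vapply(model, is.numeric, TRUE)]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(payload, con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Save / load a model archive
#'
#' Archives hold the parameter arrays together with a format version, an
#' optional configuration snapshot, training provenance (seeds, epochs)
#' and a content hash.  Loading is a bit-exact round trip and is
#' version-checked; truncated or corrupt files fail cleanly.
#'
#' @param model a `rate_network` or `ads_network`.
#' @param path file path for the archive.
#' @param config optional configuration list to snapshot.
#' @param provenance optional named list (seeds, epochs, ...).
#' @rdname model_archive
#' @export
save_model <- function(model, path, config = NULL, provenance = NULL) {
  archive <- list(format = ARCHIVE_FORMAT, version = ARCHIVE_VERSION,
                  class = class(model)[1], model = model, config = config,
                  provenance = provenance, hash = model_hash(model))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname model_archive
#' @export
load_model <- function(path) {
  archive <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupt model archive: ",
                                               conditionMessage(e)))
  if (!is.list(archive) || !identical(archive$format, ARCHIVE_FORMAT)) {
    stop("not an adsnet model archive")
  }
  if (!identical(archive$version, ARCHIVE_VERSION)) {
    stop(sprintf("archive version %s not supported (expected %d)",
                 archive$version, ARCHIVE_VERSION))
  }
  if (!identical(archive$hash, model_hash(archive$model))) {
    stop("corrupt model archive: content hash mismatch")
  }
  archive
}

config_defaults <- function() {
  list(
    task = list(name = "xor"),
    teacher = list(n_units = 64, n_in = 1, n_out = 1, dt = 0.001,
                   epochs = 20, samples_per_epoch = 500, batch_size = 25,
                   lr = 1e-3),
    ads = list(n_neurons = 320, schedule = "xor", n_samples = NULL),
    evaluation = list(n_test = 200),
    robustness = NULL,
    seed = 1L
  )
}

#' Read and validate an experiment configuration
#'
#' A single human-readable YAML file with sections `task`, `teacher`,
#' `ads`, `evaluation`, `robustness` and `seed`.  All defaults are
#' explicit (see the returned object); unknown keys anywhere are rejected
#' by name, and missing required fields error by name.
#'
#' @param path YAML file path, or a list already in config form.
#' @return a validated config list with defaults filled in.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$task) || is.null(cfg$task$name)) {
    stop("missing required config field: task$name")
  }
  for (sec in c("teacher", "ads", "evaluation")) {
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      stop(sprintf("unknown config field(s) in %s: %s", sec,
                   paste(bad, collapse = ", ")))
    }
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  defaults$task <- cfg$task
  if (!is.null(cfg$seed)) defaults$seed <- cfg$seed
  if (!is.null(cfg$robustness)) defaults$robustness <- cfg$robustness
  defaults
}

#' Built-in experiment presets
#'
#' `"xor"` is the full study configuration; `"xor-small"` is a reduced
#' smoke-test configuration (80 spiking neurons, 100 distillation
#' samples) that completes end-to-end in a few minutes.
#'
#' @param name preset name.
#' @export
experiment_preset <- function(name = c("xor", "xor-small")) {
  name <- match.arg(name)
  cfg <- config_defaults()
  if (name == "xor-small") {
    cfg$teacher$n_units <- 32
    cfg$teacher$epochs <- 3
    cfg$teacher$samples_per_epoch <- 100
    cfg$ads$n_neurons <- 80
    cfg$ads$n_samples <- 100
    cfg$evaluation$n_test <- 25
  }
  cfg
}

#' Run a full experiment from a configuration
#'
#' Executes the pipeline train-teacher -> train-ads -> evaluate, writing
#' model archives, the training records as CSV, the evaluation summary and
#' a structured JSON log of every hyperparameter and seed into `out_dir`.
#' Each stage draws from its own derived seed (see [derive_seed()]), so
#' runs with identical config and seed produce identical artifacts.
#'
#' @param config a config list (see [read_experiment_config()] /
#'   [experiment_preset()]) or a path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the trained models and the evaluation
#'   summaries.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- read_experiment_config(config)
  if (!identical(cfg$task$name, "xor")) {
    stop(sprintf("unsupported task: %s", cfg$task$name))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  sampler <- xor_task_sampler()

  set.seed(derive_seed(cfg$seed, "teacher-init"))
  teacher <- rate_network(cfg$teacher$n_units, cfg$teacher$n_in,
                          cfg$teacher$n_out, cfg$teacher$dt)
  set.seed(derive_seed(cfg$seed, "teacher-data"))
  fit <- stage("train-teacher", train_rnn(
    sampler, teacher, epochs = cfg$teacher$epochs,
    samples_per_epoch = cfg$teacher$samples_per_epoch,
    batch_size = cfg$teacher$batch_size, lr = cfg$teacher$lr))
  teacher <- fit$params
  save_model(teacher, file.path(out_dir, "teacher.rds"), config = cfg,
             provenance = list(seed = cfg$seed, stage = "teacher"))
  write.csv(fit$loss_trace, file.path(out_dir, "teacher_loss.csv"),
            row.names = FALSE)

  set.seed(derive_seed(cfg$seed, "ads-init"))
  net <- ads_network(teacher, n_neurons = cfg$ads$n_neurons)
  schedule <- schedule_preset(cfg$ads$schedule, n_samples = cfg$ads$n_samples)
  set.seed(derive_seed(cfg$seed, "ads-data"))
  dist <- stage("train-ads", train_ads(teacher, net, sampler, schedule))
  net <- dist$net
  save_model(net, file.path(out_dir, "ads.rds"), config = cfg,
             provenance = list(seed = cfg$seed, stage = "ads"))
  write.csv(dist$record, file.path(out_dir, "ads_training.csv"),
            row.names = FALSE)

  set.seed(derive_seed(cfg$seed, "evaluate"))
  ev_teacher <- evaluate_ads(teacher, sampler, cfg$evaluation$n_test)
  set.seed(derive_seed(cfg$seed, "evaluate"))
  ev_ads <- evaluate_ads(net, sampler, cfg$evaluation$n_test,
                         teacher = teacher)
  summary <- list(
    teacher_accuracy = ev_teacher$accuracy,
    ads_accuracy = ev_ads$accuracy,
    ads_output_mse = ev_ads$mse,
    seed = cfg$seed,
    config = cfg,
    stage_seeds = list(
      teacher_init = derive_seed(cfg$seed, "teacher-init"),
      teacher_data = derive_seed(cfg$seed, "teacher-data"),
      ads_init = derive_seed(cfg$seed, "ads-init"),
      ads_data = derive_seed(cfg$seed, "ads-data"),
      evaluate = derive_seed(cfg$seed, "evaluate")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(ev_ads$trials, file.path(out_dir, "evaluation.csv"),
            row.names = FALSE)
  invisible(list(teacher = teacher, net = net, teacher_eval = ev_teacher,
                 ads_eval = ev_ads))
}
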