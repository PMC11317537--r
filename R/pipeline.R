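#' @name pipeline
#' @title End-to-end orchestration
#' @description
#' A single validated configuration drives the whole run: simulate (or
#' read) raw records, curate, split, featurize, train, predict, evaluate.
#' Every artifact is a new file carrying the configuration hash and seed
#' in a JSON sidecar, so identical configurations reproduce identical
#' reports.
NULL

pipeline_schema <- list(
  seed = NULL, out_dir = NULL,
  simulate = c("n_entries", "seq_length_range", "missing_props", "rho",
               "noise_sd", "n_organisms", "mutant_fraction",
               "duplicate_rate", "planted_violations", "enzyme_dim",
               "substrate_dim", "aux_dim"),
  input = c("records", "fasta"),
  split = c("ratios"),
  featurize = c("enzyme_dim", "substrate_dim", "aux_dim", "gamma", "stride"),
  model = c("n_shared_experts", "n_specific_experts", "expert_layers",
            "expert_dim", "expert_dropout", "tower_dims", "n_cgc_layers",
            "learning_rate", "batch_size", "epochs", "tasks")
)

#' Validate a pipeline configuration
#'
#' Every documented key is checked; unknown keys are rejected with their
#' location so config typos fail before any stage runs.
#'
#' @param config named list (parsed YAML/JSON).
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  for (key in names(config)) {
    if (!key %in% names(pipeline_schema)) {
      stopf("unknown config key '%s'", key)
    }
    allowed <- pipeline_schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]])) {
      bad <- setdiff(names(config[[key]]), allowed)
      if (length(bad)) {
        stopf("unknown config key '%s.%s'", key, bad[1])
      }
    }
  }
  if (!is.null(config$simulate) && !is.null(config$input)) {
    stopf("config must give either 'simulate' or 'input', not both")
  }
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' YAML and JSON are both accepted (JSON is a YAML subset; files ending
#' in `.json` are parsed with jsonlite).
#'
#' @param path config file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
  cfg
}

write_sidecar <- function(obj, path, config_hash, seed) {
  jsonlite::write_json(
    c(list(config_hash = config_hash, seed = seed), obj),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages run in dependency order: simulate (or load) raw records,
#' curate, stratified split, featurize, train the multitask model,
#' predict on the held-out test split, and evaluate over the subtest
#' partitions. All artifacts are written under `out_dir`.
#'
#' @param config config list (see [validate_config()]) or path to a
#'   YAML/JSON file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param verbose print stage progress.
#' @return invisibly, a list with the curated entries, splits, fit,
#'   predictions and metric report.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "pipeline_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  hash <- object_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))

  # stage 1: raw records
  if (!is.null(config$input)) {
    say("reading records from %s", config$input$records)
    records <- read_kinetic_records(config$input$records,
                                    fasta = config$input$fasta)
    truth <- NULL
  } else {
    sim <- config$simulate %||% list()
    sim <- lapply(sim, function(x) {
      if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) unlist(x)
      else x
    })
    sim$seed <- seed
    spec <- do.call(synth_spec, sim)
    say("simulating %d entries (seed %d)", spec$n_entries, seed)
    gen <- gen_dataset(spec)
    records <- gen$records
    truth <- gen$truth
    write_kinetic_records(records, file.path(out_dir, "records.csv"))
    write_sidecar(list(n_records = nrow(records),
                       rho = spec$rho, noise_sd = spec$noise_sd),
                  file.path(out_dir, "records.json"), hash, seed)
  }

  # stage 2: curation
  cur <- curate_pipeline(records)
  say("curated: %d records -> %d joint entries", nrow(records),
      nrow(cur$entries))
  write_curated_entries(cur$entries, file.path(out_dir, "curated.csv"))
  rep_list <- unclass(cur$report)
  rep_list$reasons <- NULL
  acc <- accounting(cur$entries)
  write_sidecar(list(report = rep_list, accounting = unclass(acc)),
                file.path(out_dir, "curation_report.json"), hash, seed)

  # stage 3: split
  ratios <- unlist(config$split$ratios %||% c(0.8, 0.1, 0.1))
  splits <- stratified_split(cur$entries, ratios = ratios, seed = seed)
  say("split: %d train / %d val / %d test", nrow(splits$train),
      nrow(splits$val), nrow(splits$test))
  split_df <- rbind(
    data.frame(splits$train[key_cols], split = "train"),
    data.frame(splits$val[key_cols], split = "val"),
    data.frame(splits$test[key_cols], split = "test"))
  utils::write.csv(split_df, file.path(out_dir, "splits.csv"),
                   row.names = FALSE)

  # stage 4: featurize
  fz <- config$featurize %||% list()
  spec_f <- feature_spec(
    splits$train,
    enzyme_embedder = hash_embedder(fz$enzyme_dim %||% 16L, salt = 1L),
    substrate_embedder = hash_embedder(fz$substrate_dim %||% 8L, salt = 2L),
    aux_dim = fz$aux_dim %||% 8L,
    gamma = fz$gamma %||% 10,
    stride = fz$stride %||% 0.1)
  fs_train <- featurize_entries(splits$train, spec_f)
  fs_val <- featurize_entries(splits$val, spec_f)

  # stage 5: train
  mc <- config$model %||% list()
  mc$input_dim <- input_dim(spec_f)
  mc$seed <- seed
  cfg_model <- do.call(cgc_config, mc)
  say("training CGC model (%d epochs)", cfg_model$epochs)
  fit <- cgc_train(fs_train, fs_val, cfg_model)
  save_cgc(fit, file.path(out_dir, "model"), config_hash = hash)

  # stage 6: predict + evaluate
  preds <- predict_entries(fit, splits$test)
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  metrics <- evaluate_subtests(fit, splits$test, train = splits$train)
  write_sidecar(list(metrics = metrics, best_epoch = fit$best_epoch),
                file.path(out_dir, "metrics.json"), hash, seed)
  say("done: artifacts in %s", out_dir)

  invisible(list(entries = cur$entries, report = cur$report,
                 accounting = acc, splits = splits, fit = fit,
                 predictions = preds, metrics = metrics, truth = truth))
}

#' Save a trained model as a directory artifact
#'
#' JSON metadata (architecture, dimensions, centers, vocabulary, seed)
#' next to a binary parameter archive.
#'
#' @param fit `cgc_fit`.
#' @param dir target directory.
#' @param config_hash optional provenance hash.
#' @export
save_cgc <- function(fit, dir, config_hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- fit$model$spec
  meta <- list(
    config = unclass(fit$config),
    config_hash = config_hash,
    best_epoch = fit$best_epoch,
    feature_spec = if (!is.null(spec)) list(
      d_enzyme = spec$d_enzyme, d_substrate = spec$d_substrate,
      aux_dim = spec$aux_dim, gamma = spec$gamma, stride = spec$stride,
      ph_centers = spec$ph_centers, temp_centers = spec$temp_centers,
      organism_vocab = spec$organism_vocab,
      enzyme_embedder = spec$enzyme_embedder$name,
      substrate_embedder = spec$substrate_embedder$name))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(fit, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a saved model directory
#' @param dir directory written by [save_cgc()].
#' @return the `cgc_fit`.
#' @export
load_cgc <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
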