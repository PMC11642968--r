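# End-to-end pipeline: generation -> extraction -> training -> evaluation ->
# explanation, with one config object, per-stage output directories, derived
# seeds, and a JSON run manifest.

#' Default pipeline configuration
#'
#' A nested list with per-stage sections. Every stochastic component receives
#' a seed derived deterministically from the global `seed`, so a whole run is
#' reproducible from one integer. Override any field via the `...` of
#' [perio_run()], a YAML file ([load_run_config()]), or by editing the list.
#'
#' @param n Cohort size.
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(n = 100, seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      n = n, stage_counts = NULL, grade_counts = NULL,
      omission_rate = 0.1, case_jitter = TRUE
    ),
    extraction = list(
      schema = NULL, pocket_threshold_mm = 4, cal_threshold_mm = 3,
      extent_fraction = 0.30
    ),
    mlp = list(
      train_fraction = 0.70, stratify = TRUE,
      grid = FALSE, hidden1 = 4:20, hidden2 = 4:20,
      hidden_stage = c(15, 13), hidden_grade = c(4, 4),
      epochs = 30, batch_size = 16, learning_rate = 1e-2
    ),
    text = list(
      encoder_dim = 32, encoder_vocab = 1024,
      window_length = 100, lstm_units = 32, dense_units = 64,
      dropout_rate = 0.2, decay_rate = 0.97, learning_rate = 0.01,
      epochs = 40, batch_size = 20, train_fraction = 0.80,
      val_fraction = 0.2, patience = 5, class_weighting = "balanced",
      fine_tune = TRUE
    ),
    explain = list(n_samples = 200, kernel_width = 0.25)
  )
}

#' Load a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   fields.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_cfg(cfg, user)
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

run_stage_generate <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "data")
  cohort <- generate_cohort(cfg$cohort$n, cfg$cohort$stage_counts,
                            cfg$cohort$grade_counts,
                            seed = derive_seed(cfg$seed, "cohort"))
  notes <- render_notes(cohort, omission_rate = cfg$cohort$omission_rate,
                        case_jitter = cfg$cohort$case_jitter,
                        seed = derive_seed(cfg$seed, "notes"))
  paths <- write_cohort(cohort, notes, d)
  inform(glue::glue("generate: {nrow(cohort)} records -> {d}"))
  unlist(paths, use.names = FALSE)
}

run_stage_extract <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "features")
  data <- read_cohort(file.path(out_dir, "data"))
  schema <- load_extraction_schema(cfg$extraction$schema)
  rows <- extract_notes(data$notes, schema)
  summaries <- summarize_charts(
    data$charts,
    pocket_threshold_mm = cfg$extraction$pocket_threshold_mm,
    cal_threshold_mm = cfg$extraction$cal_threshold_mm,
    extent_fraction = cfg$extraction$extent_fraction
  )
  table <- merge_to_table(rows, summaries)
  path <- file.path(d, "features.csv")
  write_feature_table(table, path)
  inform(glue::glue("extract: {nrow(table)} rows -> {path}"))
  path
}

# Labels come from the cohort labels file, not from the note-extracted
# stage/grade columns (which are this track's inputs-by-construction).
mlp_training_table <- function(out_dir) {
  feats <- read_feature_table(file.path(out_dir, "features", "features.csv"))
  labels <- readr::read_csv(file.path(out_dir, "data", "labels.csv"),
                            show_col_types = FALSE, col_types = "icii")
  feats |>
    dplyr::select(-dplyr::any_of(c("stage", "grade", "date"))) |>
    dplyr::inner_join(labels[, c("chart_number", "stage", "grade")],
                      by = "chart_number")
}

run_stage_train_mlp <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "mlp")
  tbl <- mlp_training_table(out_dir)
  m <- cfg$mlp
  out <- character(0)
  for (target in c("stage", "grade")) {
    sp <- split_data(tbl, m$train_fraction, stratify = m$stratify,
                     label_col = target,
                     seed = derive_seed(cfg$seed, paste0("mlp-split-", target)))
    seed_fit <- derive_seed(cfg$seed, paste0("mlp-fit-", target))
    hidden <- if (target == "stage") m$hidden_stage else m$hidden_grade
    if (isTRUE(m$grid)) {
      gs <- grid_search(sp$train, label_col = target, hidden1 = m$hidden1,
                        hidden2 = m$hidden2, epochs = m$epochs,
                        batch_size = m$batch_size,
                        learning_rate = m$learning_rate, seed = seed_fit)
      readr::write_csv(gs$grid, file.path(d, paste0("grid_", target, ".csv")))
      fit <- gs$model
      out <- c(out, file.path(d, paste0("grid_", target, ".csv")))
    } else {
      fit <- train_mlp(sp$train, label_col = target, hidden = hidden,
                       epochs = m$epochs, batch_size = m$batch_size,
                       learning_rate = m$learning_rate, seed = seed_fit)
    }
    pred <- predict(fit, sp$test)
    pred_tbl <- dplyr::bind_cols(
      tibble::tibble(chart_number = sp$test$chart_number,
                     true = sp$test[[target]]),
      pred
    )
    p_pred <- file.path(d, paste0("predictions_", target, ".csv"))
    readr::write_csv(pred_tbl, p_pred)
    p_model <- file.path(d, paste0("model_", target, ".rds"))
    saveRDS(fit, p_model)
    out <- c(out, p_pred, p_model)
    inform(glue::glue("train-mlp [{target}]: test accuracy {round(mean(pred_tbl$true == pred_tbl$pred), 3)}"))
  }
  out
}

run_stage_train_text <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "text")
  data <- read_cohort(file.path(out_dir, "data"))
  notes <- dplyr::inner_join(data$notes, data$labels, by = "chart_number")
  tx <- cfg$text
  out <- character(0)
  for (target in c("stage", "grade")) {
    K <- if (target == "stage") 4L else 3L
    config <- text_train_config(
      window_length = tx$window_length, lstm_units = tx$lstm_units,
      decay_rate = tx$decay_rate, dropout_rate = tx$dropout_rate,
      dense_units = tx$dense_units, learning_rate = tx$learning_rate,
      epochs = tx$epochs, batch_size = tx$batch_size,
      train_fraction = tx$train_fraction, val_fraction = tx$val_fraction,
      patience = tx$patience, class_weighting = tx$class_weighting,
      fine_tune = tx$fine_tune,
      seed = derive_seed(cfg$seed, paste0("text-", target))
    )
    sp <- split_data(notes, tx$train_fraction, stratify = TRUE,
                     label_col = target,
                     seed = derive_seed(cfg$seed, paste0("text-split-", target)))
    enc <- fixture_encoder(tx$encoder_dim, tx$encoder_vocab,
                           seed = derive_seed(cfg$seed, "encoder"))
    model <- build_text_model(enc, K, config)
    model <- train_text_model(model, sp$train, sp$train[[target]])
    pred <- predict_text(model, sp$test)
    pred_tbl <- dplyr::bind_cols(
      tibble::tibble(true = sp$test[[target]]), pred
    )[, c("chart_number", "true", "pred",
          paste0("p_", seq_len(K)))]
    p_pred <- file.path(d, paste0("predictions_", target, ".csv"))
    readr::write_csv(pred_tbl, p_pred)
    p_hist <- file.path(d, paste0("history_", target, ".csv"))
    readr::write_csv(model$history, p_hist)
    p_model <- file.path(d, paste0("model_", target, ".rds"))
    saveRDS(model, p_model)
    out <- c(out, p_pred, p_hist, p_model)
    inform(glue::glue("train-text [{target}]: test accuracy {round(mean(pred_tbl$true == pred_tbl$pred), 3)}"))
  }
  out
}

run_stage_evaluate <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "metrics")
  out <- character(0)
  reports <- list()
  for (track in c("mlp", "text")) {
    for (target in c("stage", "grade")) {
      p <- file.path(out_dir, track, paste0("predictions_", target, ".csv"))
      if (!file.exists(p)) next
      pred <- readr::read_csv(p, show_col_types = FALSE)
      K <- if (target == "stage") 4L else 3L
      rep <- metrics(confusion(pred$true, pred$pred, K))
      reports[[paste(track, target, sep = "_")]] <- rep
      pm <- file.path(d, paste0("metrics_", track, "_", target, ".csv"))
      pc <- file.path(d, paste0("confusion_", track, "_", target, ".csv"))
      write_metrics(rep, pm, pc)
      out <- c(out, pm, pc)
    }
  }
  for (target in c("stage", "grade")) {
    a <- reports[[paste0("text_", target)]]
    b <- reports[[paste0("mlp_", target)]]
    if (is.null(a) || is.null(b)) next
    comp <- compare_models(a, b, names = c("text", "mlp"))
    pcmp <- file.path(d, paste0("comparison_", target, ".csv"))
    readr::write_csv(comp$table, pcmp)
    writeLines(utils::capture.output(print(comp)),
               file.path(d, paste0("comparison_", target, ".txt")))
    out <- c(out, pcmp, file.path(d, paste0("comparison_", target, ".txt")))
  }
  inform(glue::glue("evaluate: reports -> {d}"))
  out
}

run_stage_explain <- function(cfg, out_dir) {
  d <- stage_dir(out_dir, "explain")
  model <- readRDS(file.path(out_dir, "text", "model_stage.rds"))
  pred <- readr::read_csv(file.path(out_dir, "text", "predictions_stage.csv"),
                          show_col_types = FALSE)
  data <- read_cohort(file.path(out_dir, "data"))
  note <- data$notes$text[data$notes$chart_number == pred$chart_number[1]]
  predict_fn <- function(texts) {
    as.matrix(predict_text(model, tibble::tibble(
      chart_number = seq_along(texts), text = texts
    ))[, paste0("p_", seq_len(model$K))])
  }
  attr_tbl <- token_importance(predict_fn, note,
                               target_class = pred$pred[1],
                               n_samples = cfg$explain$n_samples,
                               kernel_width = cfg$explain$kernel_width,
                               seed = derive_seed(cfg$seed, "explain"))
  path <- file.path(d, "attribution_stage.csv")
  write_attribution(attr_tbl, path)
  inform(glue::glue("explain: chart {pred$chart_number[1]}, class {pred$pred[1]} -> {path}"))
  path
}

#' Run pipeline stages
#'
#' Executes the requested stage (or all of them in order) under `out_dir`,
#' with each stage writing to its own subdirectory, then writes a JSON run
#' manifest (config hash, derived seeds, versions, every output path).
#'
#' @param stages One of `"generate"`, `"extract"`, `"train-mlp"`,
#'   `"train-text"`, `"evaluate"`, `"explain"`, `"run-all"`.
#' @param config Configuration list (see [default_run_config()] /
#'   [load_run_config()]).
#' @param out_dir Run directory.
#' @param seed Optional override of `config$seed`.
#' @return The manifest list, invisibly.
#' @export
perio_run <- function(stages = "run-all", config = default_run_config(),
                      out_dir = "perio_run", seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  all_stages <- c("generate", "extract", "train-mlp", "train-text",
                  "evaluate", "explain")
  todo <- if (identical(stages, "run-all")) all_stages else stages
  if (!all(todo %in% all_stages)) {
    abort(glue::glue("unknown stage(s): {paste(setdiff(todo, all_stages), collapse = ', ')}"),
          class = "periodx_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(
    "generate" = run_stage_generate, "extract" = run_stage_extract,
    "train-mlp" = run_stage_train_mlp, "train-text" = run_stage_train_text,
    "evaluate" = run_stage_evaluate, "explain" = run_stage_explain
  )
  outputs <- purrr::map(todo, function(s) runners[[s]](config, out_dir))
  names(outputs) <- todo
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    derived_seeds = list(
      cohort = derive_seed(config$seed, "cohort"),
      notes = derive_seed(config$seed, "notes"),
      encoder = derive_seed(config$seed, "encoder"),
      explain = derive_seed(config$seed, "explain")
    ),
    versions = list(
      r = R.version.string,
      periodx = as.character(utils::packageVersion("periodx"))
    ),
    stages = todo,
    outputs = purrr::map(outputs, ~ as.character(.x))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
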