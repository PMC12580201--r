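#' Pipeline run configuration
#'
#' A nested configuration for the staged pipeline: synthesize (or point at)
#' a dataset, split it patient-wise, run the whale search per model family,
#' train the tuned models, predict, soft-vote and report.  Every stage
#' writes plain-file artifacts under `out_dir` and can be re-run
#' independently; all randomness derives from `seed`.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed master integer seed.
#' @param models named character vector or list of model names: the name
#'   `"lvm"` selects the from-scratch CNN family; any other entry is
#'   treated as a registered backbone id for the transfer family (defaults
#'   to the three-member ensemble `lvm`, `tinynet_a`, `tinynet_b`).
#' @param dataset list describing the data source: either
#'   `list(type = "synthetic", patients_per_class =, image_side =,
#'   separation =, noise_sd =, preset = NULL)` (preset `"kauh_like"`
#'   selects the full reference-sized cohort) or
#'   `list(type = "directory", path = "<dir>", image_side =)`.
#' @param split named fractions `c(train=, val=, test=)`.
#' @param woa list with `n_whales`, `max_iterations`, `patience`.
#' @param partial_epochs epochs per fitness evaluation.
#' @param final_epochs epochs for final training of the best
#'   configuration.
#' @param augment list: `enabled`, `shear`, `zoom`, `horizontal_flip`.
#' @param balance_before_split balance classes by augmentation before
#'   splitting (compatibility mode reproducing equal per-class test
#'   counts) instead of the default leakage-safe train-only augmentation.
#' @return a `whalenet_config` list.
#' @export
run_config <- function(out_dir = tempfile("whalenet_run_"), seed = 1,
                       models = c("lvm", "tinynet_a", "tinynet_b"),
                       dataset = list(type = "synthetic",
                                      patients_per_class = 10,
                                      image_side = 64, separation = 0.9,
                                      noise_sd = 0.04, preset = NULL),
                       split = c(train = 0.8, val = 0.1, test = 0.1),
                       woa = list(n_whales = 2, max_iterations = 3,
                                  patience = 3),
                       partial_epochs = 10, final_epochs = 30,
                       augment = list(enabled = TRUE, shear = 0.2,
                                      zoom = 0.2, horizontal_flip = TRUE),
                       balance_before_split = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              models = unlist(models), dataset = dataset, split = split,
              woa = woa, partial_epochs = as.integer(partial_epochs),
              final_epochs = as.integer(final_epochs), augment = augment,
              balance_before_split = isTRUE(balance_before_split))
  for (m in cfg$models) {
    if (m != "lvm") backbone_info(m) # fail fast on unknown backbones
  }
  structure(cfg, class = "whalenet_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys mirror the [run_config()] arguments.
#' @param seed optional seed override.
#' @return a `whalenet_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("out_dir", "seed", "models", "dataset", "woa",
              "partial_epochs", "final_epochs", "augment",
              "balance_before_split")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$split)) args$split <- unlist(y$split)
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

family_of <- function(model_name) if (model_name == "lvm") "lvm" else "transfer"

data_dir_of <- function(config) {
  if (identical(config$dataset$type, "directory")) config$dataset$path
  else file.path(config$out_dir, "data")
}

#' Synthesize the dataset stage
#'
#' Generates the synthetic cohort configured in `config$dataset` and
#' writes the PNG tree and `manifest.csv` under `<out_dir>/data`.  A no-op
#' for directory-backed datasets.
#'
#' @param config a [run_config()].
#' @return the dataset directory, invisibly.
#' @export
run_synth <- function(config) {
  stopifnot(inherits(config, "whalenet_config"))
  if (identical(config$dataset$type, "directory")) {
    return(invisible(config$dataset$path))
  }
  ds <- config$dataset
  spec <- if (identical(ds$preset, "kauh_like")) {
    kauh_like_spec(image_side = ds$image_side %||% 64,
                   separation = ds$separation %||% 0.7,
                   noise_sd = ds$noise_sd %||% 0.05,
                   seed = derive_seed(config$seed, "data"))
  } else {
    synthetic_cohort_spec(
      patients_per_class = ds$patients_per_class %||% 10,
      image_side = ds$image_side %||% 64,
      separation = ds$separation %||% 0.9,
      noise_sd = ds$noise_sd %||% 0.04,
      seed = derive_seed(config$seed, "data"))
  }
  dir <- data_dir_of(config)
  generate_cohort(spec, dir = dir)
  message("synthetic dataset written to ", dir)
  invisible(dir)
}

# Load the dataset, assign patient-level splits and augment.  Deterministic
# in the config, so every stage can recompute identical splits; the split
# assignment is also written once as an artifact.
prepare_splits <- function(config) {
  side <- config$dataset$image_side %||% 64
  dataset <- read_image_dataset(data_dir_of(config), side = side)
  split_seed <- derive_seed(config$seed, "split")
  aug_seed <- derive_seed(config$seed, "augment")
  pol <- augmentation_policy(shear = config$augment$shear %||% 0.2,
                             zoom = config$augment$zoom %||% 0.2,
                             horizontal_flip =
                               config$augment$horizontal_flip %||% TRUE)
  if (config$balance_before_split && isTRUE(config$augment$enabled)) {
    dataset <- augment_to_balance(dataset, pol, seed = aug_seed)
    dataset$manifest <- patient_stratified_split(dataset$manifest,
                                                 config$split, split_seed)
    splits <- split_dataset(dataset)
  } else {
    dataset$manifest <- patient_stratified_split(dataset$manifest,
                                                 config$split, split_seed)
    splits <- split_dataset(dataset)
    if (isTRUE(config$augment$enabled)) {
      tr <- augment_to_balance(list(images = splits$train$x,
                                    manifest = splits$train$manifest),
                               pol, seed = aug_seed)
      splits$train <- list(x = tr$images,
                           y = encode_label(tr$manifest$class),
                           manifest = tr$manifest)
    }
  }
  split_path <- file.path(config$out_dir, "splits.csv")
  if (!file.exists(split_path)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      do.call(rbind, lapply(names(splits), function(s) {
        m <- splits[[s]]$manifest
        data.frame(image_id = m$image_id, class = m$class,
                   patient_id = m$patient_id,
                   split = rep(s, nrow(m)),
                   augmented = if (is.null(m$augmented))
                     rep(FALSE, nrow(m)) else m$augmented)
      })), split_path, row.names = FALSE)
  }
  splits
}

#' Whale-search stage for one model
#'
#' Builds the partial-training objective for the model's family and runs
#' the whale optimizer, writing the convergence curve, the fitness ledger
#' and the best decoded configuration.
#'
#' @param config a [run_config()].
#' @param model model name from `config$models`.
#' @return list with `run` (the `woa_run`) and `best` (decoded
#'   hyperparameters), invisibly.
#' @export
run_optimize <- function(config, model) {
  stopifnot(inherits(config, "whalenet_config"), model %in% config$models)
  splits <- prepare_splits(config)
  family <- family_of(model)
  space <- search_space(family)
  objective <- make_objective(
    family, splits, partial_epochs = config$partial_epochs,
    base_seed = derive_seed(config$seed, paste0("fitness_", model)),
    backbone_id = if (family == "transfer") model else NULL,
    input_side = config$dataset$image_side %||% 64, space = space)
  wcfg <- woa_config(n_whales = config$woa$n_whales %||% 2,
                     max_iterations = config$woa$max_iterations %||% 3,
                     early_stop_patience = config$woa$patience %||% 3,
                     seed = derive_seed(config$seed, paste0("woa_", model)))
  run <- woa_optimize(objective, d = space_dim(space), config = wcfg)
  best <- decode_hyperparameters(run$best_position, space)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_convergence_csv(run, file.path(config$out_dir,
                                       sprintf("convergence_%s.csv", model)))
  utils::write.csv(fitness_ledger(objective),
                   file.path(config$out_dir,
                             sprintf("fitness_ledger_%s.csv", model)),
                   row.names = FALSE)
  yaml::write_yaml(
    c(list(model = model, family = family,
           best_fitness = run$best_fitness),
      unclass(best)[!vapply(unclass(best), is.null, TRUE)]),
    file.path(config$out_dir, sprintf("best_config_%s.yaml", model)))
  message(sprintf("[%s] best fitness %.4f after %d evaluations",
                  model, run$best_fitness, run$n_evaluations))
  invisible(list(run = run, best = best))
}

read_best_config <- function(config, model) {
  path <- file.path(config$out_dir, sprintf("best_config_%s.yaml", model))
  require_artifact(path, sprintf("whalenet optimize --model %s", model))
  y <- yaml::read_yaml(path)
  h <- list(learning_rate = y$learning_rate,
            batch_size = as.integer(y$batch_size),
            dropout_rate = y$dropout_rate,
            dense_units = as.integer(y$dense_units),
            optimizer = y$optimizer, activation = y$activation,
            weight_decay = y$weight_decay, momentum = y$momentum,
            conv_filters = if (!is.null(y$conv_filters))
              as.integer(unlist(y$conv_filters)) else NULL)
  structure(h, class = "whale_hyperparameters", model_family = y$family)
}

#' Final-training stage for one model
#'
#' Trains the model's best configuration (from the optimize stage, or an
#' explicit `hyperparameters` argument) for `config$final_epochs` epochs
#' and writes the model checkpoint and training history.
#'
#' @param config a [run_config()].
#' @param model model name.
#' @param hyperparameters optional decoded `whale_hyperparameters`
#'   overriding the optimize-stage artifact.
#' @return the trained `whale_model`, invisibly.
#' @export
run_train <- function(config, model, hyperparameters = NULL) {
  stopifnot(inherits(config, "whalenet_config"), model %in% config$models)
  h <- hyperparameters %||% read_best_config(config, model)
  splits <- prepare_splits(config)
  family <- family_of(model)
  arch <- architecture_from_hyperparameters(
    h, input_side = config$dataset$image_side %||% 64,
    backbone_id = if (family == "transfer") model else NULL)
  handle <- if (family == "lvm") build_lvm(arch) else
    build_transfer_model(arch)
  policy <- policy_from_hyperparameters(
    h, epochs = config$final_epochs,
    seed = derive_seed(config$seed, paste0("train_", model)))
  trained <- train_model(handle, splits, policy)
  dir.create(file.path(config$out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  saveRDS(trained, file.path(config$out_dir, "models",
                             paste0(model, ".rds")))
  utils::write.csv(trained$history,
                   file.path(config$out_dir,
                             sprintf("history_%s.csv", model)),
                   row.names = FALSE)
  message(sprintf("[%s] final val loss %.4f, val accuracy %.3f", model,
                  utils::tail(trained$history$val_loss, 1),
                  utils::tail(trained$history$val_accuracy, 1)))
  invisible(trained)
}

#' Prediction stage for one model
#'
#' @param config a [run_config()].
#' @param model model name.
#' @param split `"test"`, `"val"` or `"train"`.
#' @return the `probability_matrix`, invisibly; also written to
#'   `proba_<model>_<split>.csv`.
#' @export
run_predict <- function(config, model, split = "test") {
  stopifnot(inherits(config, "whalenet_config"))
  model_path <- file.path(config$out_dir, "models", paste0(model, ".rds"))
  require_artifact(model_path, sprintf("whalenet train --model %s", model))
  trained <- readRDS(model_path)
  splits <- prepare_splits(config)
  part <- splits[[split]]
  pm <- predict_proba(trained, part$x, image_ids = part$manifest$image_id)
  write_probability_csv(pm, file.path(config$out_dir,
                                      sprintf("proba_%s_%s.csv", model,
                                              split)))
  invisible(pm)
}

#' Soft-voting stage
#'
#' Averages the per-model probability CSVs for `split` and writes the
#' ensemble probabilities with predicted labels and tie flags.
#'
#' @param config a [run_config()].
#' @param split evaluated split.
#' @return the [soft_vote()] result, invisibly.
#' @export
run_ensemble <- function(config, split = "test") {
  stopifnot(inherits(config, "whalenet_config"))
  members <- lapply(config$models, function(m) {
    p <- file.path(config$out_dir, sprintf("proba_%s_%s.csv", m, split))
    require_artifact(p, sprintf("whalenet predict --model %s", m))
    read_probability_csv(p)
  })
  vote <- soft_vote(members)
  write_probability_csv(vote, file.path(config$out_dir,
                                        sprintf("ensemble_%s.csv", split)))
  invisible(vote)
}

#' Reporting stage
#'
#' Computes, for every individual model and the soft-voting ensemble on
#' `split`: the confusion matrix, the per-class + overall metric table and
#' the accuracy confidence-interval table (accuracy, difference from the
#' ensemble, 95% Wald CI).  All tables are written as CSV.
#'
#' @param config a [run_config()].
#' @param split evaluated split.
#' @return list with `metrics` (named list of `metrics_table`),
#'   `confusions`, `ci_table` (data.frame) and `accuracy` (named vector,
#'   percent).
#' @export
run_report <- function(config, split = "test") {
  stopifnot(inherits(config, "whalenet_config"))
  splits <- prepare_splits(config)
  truth <- stats::setNames(splits[[split]]$manifest$class,
                           splits[[split]]$manifest$image_id)
  sources <- c(stats::setNames(as.list(config$models), config$models),
               list(ensemble = "ensemble"))
  metrics <- list(); confusions <- list(); correct <- integer(0)
  for (name in names(sources)) {
    path <- if (name == "ensemble") {
      file.path(config$out_dir, sprintf("ensemble_%s.csv", split))
    } else {
      file.path(config$out_dir, sprintf("proba_%s_%s.csv", name, split))
    }
    require_artifact(path, if (name == "ensemble") "whalenet ensemble" else
      sprintf("whalenet predict --model %s", name))
    pm <- read_probability_csv(path)
    pred <- colnames(pm$probs)[max.col(pm$probs, ties.method = "first")]
    ids <- rownames(pm$probs)
    cm <- confusion_matrix(truth[ids], pred, class_labels = colnames(pm$probs))
    mt <- per_class_metrics(cm)
    metrics[[name]] <- mt
    confusions[[name]] <- cm
    correct[name] <- sum(diag(cm))
    write_metrics_csv(mt, file.path(config$out_dir,
                                    sprintf("metrics_%s_%s.csv", name, split)))
    write_confusion_csv(cm, file.path(config$out_dir,
                                      sprintf("confusion_%s_%s.csv", name,
                                              split)))
  }
  n <- length(truth)
  acc <- vapply(metrics, function(m) m$accuracy, 0)
  ci_rows <- lapply(names(metrics), function(name) {
    ci <- accuracy_ci(correct[[name]], n)
    data.frame(model = name, accuracy = ci$accuracy,
               difference_from_ensemble =
                 round_half_up(acc[["ensemble"]] - ci$accuracy, 2),
               ci_lower = ci$lower, ci_upper = ci$upper, n = n)
  })
  ci_table <- do.call(rbind, ci_rows)
  ci_table <- ci_table[order(-ci_table$accuracy), ]
  utils::write.csv(ci_table,
                   file.path(config$out_dir,
                             sprintf("ci_table_%s.csv", split)),
                   row.names = FALSE)
  list(metrics = metrics, confusions = confusions, ci_table = ci_table,
       accuracy = acc)
}

#' Run the whole pipeline
#'
#' Chains synth, optimize + train + predict per model, ensemble and
#' report.
#'
#' @param config a [run_config()].
#' @param split evaluated split for the report.
#' @return the [run_report()] result.
#' @export
run_all <- function(config, split = "test") {
  stopifnot(inherits(config, "whalenet_config"))
  run_synth(config)
  for (m in config$models) {
    run_optimize(config, m)
    run_train(config, m)
    run_predict(config, m, split = split)
  }
  run_ensemble(config, split = split)
  run_report(config, split = split)
}
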