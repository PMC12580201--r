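#' A partial-training fitness request
#'
#' Bundles everything one whale-fitness evaluation needs: the model family,
#' the normalized candidate vector, the dataset splits, the partial-training
#' epoch budget and the base seed.
#'
#' @param model_family `"lvm"` or `"transfer"`.
#' @param vector normalized hyperparameter vector in `[0,1]^d`.
#' @param splits dataset splits as produced by [split_dataset()] (`train`
#'   and `val` are used).
#' @param partial_epochs epochs of partial training (default 10).
#' @param seed base seed; the candidate's own training seed is derived
#'   from it and the decoded configuration.
#' @param backbone_id backbone for the transfer family.
#' @param input_side image side of the splits (needed by the LVM).
#' @param space optional pre-built [search_space()]; defaults to the
#'   family's standard space.
#' @return a `fitness_request`.
#' @export
fitness_request <- function(model_family, vector, splits,
                            partial_epochs = 10, seed = 1,
                            backbone_id = NULL, input_side = 64,
                            space = NULL) {
  stopifnot(model_family %in% c("lvm", "transfer"), partial_epochs >= 1)
  structure(list(model_family = model_family, vector = vector,
                 splits = splits, partial_epochs = as.integer(partial_epochs),
                 seed = as.integer(seed), backbone_id = backbone_id,
                 input_side = as.integer(input_side),
                 space = space %||% search_space(model_family)),
            class = "fitness_request")
}

#' Create a fitness cache
#'
#' Keys are canonical decoded-configuration strings, so two normalized
#' vectors that decode to the same physical configuration share one
#' training run.
#'
#' @return an environment usable as `cache` in [evaluate_fitness()].
#' @export
new_fitness_cache <- function() new.env(parent = emptyenv())

#' Evaluate the whale-fitness of a candidate vector
#'
#' Decodes the vector, builds and partially trains the corresponding model
#' and returns the validation loss of the final partial epoch (or the
#' minimum over epochs with `min_over_epochs = TRUE`).  Failed or diverged
#' trainings return `+Inf`.  Deterministic for a fixed request.
#'
#' @param req a [fitness_request()].
#' @param cache optional [new_fitness_cache()] for cross-call reuse.
#' @param min_over_epochs use the minimum validation loss over the partial
#'   epochs instead of the final-epoch value.
#' @return a single fitness value (validation loss; `+Inf` on failure),
#'   with attributes `decoded` (the configuration) and `cached` (logical).
#' @export
evaluate_fitness <- function(req, cache = NULL, min_over_epochs = FALSE) {
  stopifnot(inherits(req, "fitness_request"))
  h <- decode_hyperparameters(req$vector, req$space)
  key <- paste0(hp_canonical_string(h), " ep=", req$partial_epochs,
                " seed=", req$seed, " min=", min_over_epochs)
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
    fit <- get(key, envir = cache, inherits = FALSE)
    attr(fit, "decoded") <- h
    attr(fit, "cached") <- TRUE
    return(fit)
  }
  model_seed <- derive_seed(req$seed, hp_canonical_string(h))
  fit <- tryCatch({
    arch <- architecture_from_hyperparameters(
      h, input_side = req$input_side, backbone_id = req$backbone_id)
    handle <- if (req$model_family == "lvm") build_lvm(arch) else
      build_transfer_model(arch)
    policy <- policy_from_hyperparameters(h, epochs = req$partial_epochs,
                                          seed = model_seed)
    trained <- train_model(handle, req$splits, policy)
    v <- if (min_over_epochs) min(trained$history$val_loss) else
      trained$history$val_loss[nrow(trained$history)]
    if (!is.finite(v)) Inf else v
  }, error = function(e) {
    message("fitness evaluation failed (+Inf): ", conditionMessage(e))
    Inf
  })
  if (!is.null(cache)) assign(key, fit, envir = cache)
  attr(fit, "decoded") <- h
  attr(fit, "cached") <- FALSE
  fit
}

#' Build a WOA objective from dataset splits
#'
#' Wraps [evaluate_fitness()] into the fitness-function contract
#' [woa_optimize()] expects, with a shared cache and a ledger recording
#' every (vector, decoded configuration, fitness) evaluation.
#'
#' @param model_family `"lvm"` or `"transfer"`.
#' @param splits dataset splits ([split_dataset()]).
#' @param partial_epochs partial-training epoch budget.
#' @param base_seed base seed for per-candidate seeds.
#' @param backbone_id backbone for the transfer family.
#' @param input_side image side of the splits.
#' @param space optional [search_space()] override.
#' @param min_over_epochs see [evaluate_fitness()].
#' @return a function `v -> fitness`; retrieve the evaluation history with
#'   [fitness_ledger()].
#' @export
make_objective <- function(model_family, splits, partial_epochs = 10,
                           base_seed = 1, backbone_id = NULL,
                           input_side = 64, space = NULL,
                           min_over_epochs = FALSE) {
  space <- space %||% search_space(model_family)
  cache <- new_fitness_cache()
  ledger <- new.env(parent = emptyenv())
  ledger$rows <- list()
  objective <- function(v) {
    req <- fitness_request(model_family, v, splits, partial_epochs,
                           base_seed, backbone_id, input_side, space)
    fit <- evaluate_fitness(req, cache = cache,
                            min_over_epochs = min_over_epochs)
    h <- attr(fit, "decoded")
    ledger$rows[[length(ledger$rows) + 1L]] <- data.frame(
      evaluation = length(ledger$rows) + 1L,
      fitness = as.numeric(fit),
      cached = isTRUE(attr(fit, "cached")),
      config = hp_canonical_string(h),
      t(stats::setNames(v, paste0("x", seq_along(v) - 1L))))
    as.numeric(fit)
  }
  attr(objective, "ledger") <- ledger
  attr(objective, "cache") <- cache
  objective
}

#' Evaluation ledger of a [make_objective()] objective
#'
#' @param objective the objective function.
#' @return data.frame with one row per objective call: evaluation index,
#'   fitness, cache-hit flag, canonical decoded configuration and the
#'   normalized coordinates `x0..x(d-1)`.
#' @export
fitness_ledger <- function(objective) {
  ledger <- attr(objective, "ledger")
  if (is.null(ledger)) stop("not a make_objective() function", call. = FALSE)
  if (!length(ledger$rows)) return(NULL)
  do.call(rbind, ledger$rows)
}
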