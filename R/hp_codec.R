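#' Hyperparameter search spaces over the normalized unit cube
#'
#' The whale optimizer works on `[0,1]^d`; every coordinate is decoded to a
#' physical training setting at evaluation time.  Two model families are
#' supported: `"transfer"` (frozen-backbone classification heads, 8
#' dimensions) and `"lvm"` (the from-scratch lightweight vision model, 11
#' dimensions — the extra three are the per-block convolution filter counts).
#'
#' Dimension order is fixed: learning rate, batch size, dropout rate, dense
#' units, optimizer, activation, weight decay, momentum, then (LVM only)
#' conv1/conv2/conv3 filters.
#'
#' Scales:
#' \describe{
#'   \item{log10}{`x -> 10^(lo + (hi - lo) x)` on the exponent, e.g. the
#'     learning rate `10^(-5 + 3x)` spanning `1e-5 .. 1e-2`.}
#'   \item{linear}{affine map `lo + (hi - lo) x`.}
#'   \item{integer-linear}{affine map truncated toward zero,
#'     e.g. batch size `int(16 + 112 x)`.}
#'   \item{categorical-index}{`round(2x)` (half-up) indexes an ordered label
#'     list, so `x = 0, 0.5, 1` hit indices 0, 1, 2 exactly.}
#' }
#'
#' The LVM filter counts follow `int(base * (0.5 + 1.5 x))` with bases
#' 32/64/128, i.e. maxima 64/128/256.  `extended_filter_range = TRUE`
#' substitutes coefficient 2.5, widening the maxima to 96/192/384.
#'
#' @param model_family `"transfer"` or `"lvm"`.
#' @param extended_filter_range widen LVM filter maxima to 96/192/384.
#' @return A `whale_search_space` object: ordered list of dimension specs
#'   plus the family tag.
#' @seealso [decode_hyperparameters()], [encode_hyperparameters()]
#' @export
search_space <- function(model_family = c("transfer", "lvm"),
                         extended_filter_range = FALSE) {
  model_family <- match.arg(model_family)
  dim_spec <- function(name, scale, lower, upper, categories = NULL) {
    if (scale != "categorical-index" && lower >= upper) {
      stop("dimension '", name, "': lower must be < upper", call. = FALSE)
    }
    if (scale == "categorical-index" && length(categories) < 2) {
      stop("dimension '", name, "': needs >= 2 categories", call. = FALSE)
    }
    list(name = name, scale = scale, lower = lower, upper = upper,
         categories = categories)
  }
  dims <- list(
    dim_spec("learning_rate", "log10", -5, -2),
    dim_spec("batch_size", "integer-linear", 16, 128),
    dim_spec("dropout_rate", "linear", 0.1, 0.5),
    dim_spec("dense_units", "integer-linear", 64, 512),
    dim_spec("optimizer", "categorical-index", 0, 2,
             categories = c("Adam", "SGD", "RMSprop")),
    dim_spec("activation", "categorical-index", 0, 2,
             categories = c("ReLU", "LeakyReLU", "ELU")),
    dim_spec("weight_decay", "log10", -6, -3),
    dim_spec("momentum", "linear", 0.5, 0.95)
  )
  if (model_family == "lvm") {
    coef <- if (extended_filter_range) 2.5 else 1.5
    bases <- c(32, 64, 128)
    for (i in 1:3) {
      dims[[length(dims) + 1L]] <- dim_spec(
        paste0("conv", i, "_filters"), "integer-linear",
        bases[i] * 0.5, bases[i] * (0.5 + coef))
    }
  }
  structure(list(dimensions = dims, model_family = model_family,
                 extended_filter_range = extended_filter_range),
            class = "whale_search_space")
}

#' @export
print.whale_search_space <- function(x, ...) {
  cat(sprintf("<whale_search_space> family=%s, %d dimensions\n",
              x$model_family, length(x$dimensions)))
  for (d in x$dimensions) {
    rng <- if (d$scale == "categorical-index") {
      paste(d$categories, collapse = "/")
    } else if (d$scale == "log10") {
      sprintf("1e%g .. 1e%g", d$lower, d$upper)
    } else {
      sprintf("%g .. %g", d$lower, d$upper)
    }
    cat(sprintf("  %-16s %-18s %s\n", d$name, d$scale, rng))
  }
  invisible(x)
}

#' Number of dimensions of a search space
#' @param space a `whale_search_space`.
#' @return integer dimensionality (8 for transfer, 11 for LVM).
#' @export
space_dim <- function(space) length(space$dimensions)

decode_one <- function(x, d) {
  switch(d$scale,
    "log10" = 10^(d$lower + (d$upper - d$lower) * x),
    "linear" = d$lower + (d$upper - d$lower) * x,
    # truncation toward zero, as in the published encodings int(16 + 112x)
    "integer-linear" = trunc(d$lower + (d$upper - d$lower) * x),
    "categorical-index" = {
      idx <- floor(2 * x + 0.5) # round half-up: 0.25 -> 1, 0.75 -> 2
      d$categories[[clamp(idx, 0, length(d$categories) - 1L) + 1L]]
    },
    stop("unknown scale: ", d$scale))
}

encode_one <- function(v, d) {
  switch(d$scale,
    "log10" = (log10(v) - d$lower) / (d$upper - d$lower),
    "linear" = (v - d$lower) / (d$upper - d$lower),
    "integer-linear" = (v - d$lower) / (d$upper - d$lower),
    "categorical-index" = (match(v, d$categories) - 1L) / 2,
    stop("unknown scale: ", d$scale))
}

#' Decode a normalized vector into physical hyperparameters
#'
#' @param v numeric vector in `[0,1]^d` (coordinates outside `[0,1]` are
#'   clamped with a warning).
#' @param space a [search_space()].
#' @return A `whale_hyperparameters` list: `learning_rate`, `batch_size`,
#'   `dropout_rate`, `dense_units`, `optimizer`, `activation`,
#'   `weight_decay`, `momentum`, and for the LVM family `conv_filters`
#'   (length-3 integer vector).  `momentum` is always decoded but is only
#'   consumed when `optimizer == "SGD"`.
#' @export
#' @examples
#' sp <- search_space("lvm")
#' decode_hyperparameters(rep(0, 11), sp) # every range's lower endpoint
decode_hyperparameters <- function(v, space) {
  stopifnot(inherits(space, "whale_search_space"))
  d <- space_dim(space)
  if (length(v) != d) {
    stop(sprintf("expected %d coordinates for family '%s', got %d",
                 d, space$model_family, length(v)), call. = FALSE)
  }
  if (any(v < 0 | v > 1)) {
    warning("coordinates outside [0,1] clamped before decoding")
    v <- clamp(v)
  }
  vals <- lapply(seq_len(d), function(i) decode_one(v[i], space$dimensions[[i]]))
  names(vals) <- vapply(space$dimensions, `[[`, "", "name")
  h <- list(
    learning_rate = vals$learning_rate,
    batch_size = as.integer(vals$batch_size),
    dropout_rate = vals$dropout_rate,
    dense_units = as.integer(vals$dense_units),
    optimizer = vals$optimizer,
    activation = vals$activation,
    weight_decay = vals$weight_decay,
    momentum = vals$momentum,
    conv_filters = NULL
  )
  if (space$model_family == "lvm") {
    h$conv_filters <- as.integer(c(vals$conv1_filters, vals$conv2_filters,
                                   vals$conv3_filters))
  }
  structure(h, class = "whale_hyperparameters",
            model_family = space$model_family)
}

#' Encode physical hyperparameters back into the unit cube
#'
#' Inverse of [decode_hyperparameters()] (up to integer truncation):
#' continuous dimensions round-trip exactly, integer dimensions round-trip
#' to within one truncation step, categorical dimensions map to the exact
#' representative coordinates 0, 0.5, 1.
#'
#' @param h a `whale_hyperparameters` list (fields as returned by
#'   [decode_hyperparameters()]).
#' @param space a [search_space()] of the matching family.
#' @return numeric vector in `[0,1]^d`.
#' @export
encode_hyperparameters <- function(h, space) {
  stopifnot(inherits(space, "whale_search_space"))
  field_of <- c(learning_rate = "learning_rate", batch_size = "batch_size",
                dropout_rate = "dropout_rate", dense_units = "dense_units",
                optimizer = "optimizer", activation = "activation",
                weight_decay = "weight_decay", momentum = "momentum",
                conv1_filters = 1, conv2_filters = 2, conv3_filters = 3)
  v <- vapply(space$dimensions, function(d) {
    val <- if (grepl("^conv", d$name)) {
      h$conv_filters[[as.integer(field_of[[d$name]])]]
    } else {
      h[[field_of[[d$name]]]]
    }
    if (is.null(val) || (is.numeric(val) && is.na(val))) {
      stop("missing hyperparameter field for dimension '", d$name, "'",
           call. = FALSE)
    }
    if (d$scale == "categorical-index") {
      if (!val %in% d$categories) {
        stop(sprintf("field '%s': value '%s' not in {%s}", d$name, val,
                     paste(d$categories, collapse = ", ")), call. = FALSE)
      }
    } else {
      lo <- if (d$scale == "log10") 10^d$lower else d$lower
      hi <- if (d$scale == "log10") 10^d$upper else d$upper
      if (val < lo * (1 - 1e-12) - 1e-300 || val > hi * (1 + 1e-12)) {
        stop(sprintf("field '%s': value %s outside range [%s, %s]",
                     d$name, format_num(val), format_num(lo), format_num(hi)),
             call. = FALSE)
      }
    }
    x <- encode_one(val, d)
    clamp(x)
  }, numeric(1))
  v
}

#' @export
print.whale_hyperparameters <- function(x, ...) {
  cat("<whale_hyperparameters> family:", attr(x, "model_family"), "\n")
  df <- hyperparameters_to_table(x)
  cat(paste(sprintf("  %-14s %s", df$hyperparameter, df$value),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Flatten a decoded configuration into a two-column report table
#'
#' Mirrors the layout of published per-model configuration tables
#' (hyperparameter name, value); momentum prints only for SGD, filter
#' counts only for the LVM family.
#'
#' @param h a `whale_hyperparameters` object.
#' @return data.frame with columns `hyperparameter`, `value`.
#' @export
hyperparameters_to_table <- function(h) {
  rows <- list(
    c("learning_rate", format_num(signif(h$learning_rate, 6))),
    c("batch_size", as.character(h$batch_size)),
    c("dropout_rate", format_num(signif(h$dropout_rate, 6))),
    c("dense_units", as.character(h$dense_units)),
    c("optimizer", h$optimizer),
    c("activation", h$activation),
    c("weight_decay", format_num(signif(h$weight_decay, 6))),
    c("momentum", if (identical(h$optimizer, "SGD"))
        format_num(signif(h$momentum, 6)) else "-")
  )
  if (!is.null(h$conv_filters)) {
    for (i in 1:3) {
      rows[[length(rows) + 1L]] <-
        c(paste0("conv", i, "_filters"), as.character(h$conv_filters[i]))
    }
  }
  data.frame(hyperparameter = vapply(rows, `[[`, "", 1),
             value = vapply(rows, `[[`, "", 2))
}

# Canonical single-line rendering of a decoded config; the fitness cache and
# the per-candidate seed derivation key on this string, so two normalized
# vectors that decode to the same physical configuration are one evaluation.
hp_canonical_string <- function(h) {
  paste(
    attr(h, "model_family"),
    sprintf("lr=%.12g", h$learning_rate),
    sprintf("bs=%d", h$batch_size),
    sprintf("dr=%.12g", h$dropout_rate),
    sprintf("du=%d", h$dense_units),
    sprintf("opt=%s", h$optimizer),
    sprintf("act=%s", h$activation),
    sprintf("wd=%.12g", h$weight_decay),
    # momentum participates only when it is consumed
    if (identical(h$optimizer, "SGD")) sprintf("mom=%.12g", h$momentum) else "mom=-",
    if (!is.null(h$conv_filters))
      sprintf("conv=%s", paste(h$conv_filters, collapse = ",")) else "conv=-",
    sep = " ")
}
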