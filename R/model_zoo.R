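#' Lightweight vision model architecture
#'
#' A compact from-scratch CNN for three-class image classification: three
#' (3x3 same-convolution, activation, 2x2 max-pool) blocks in series with
#' filter counts `conv_filters = (F1, F2, F3)`, then flatten, a dense layer
#' of `dense_units` with the same activation, dropout, and a softmax output
#' over `n_classes`.  Each block halves the spatial side, so the input side
#' must be divisible by 8 (224 -> 112/56/28; 64 -> 32/16/8).
#'
#' @param input_side input image side in pixels (square, divisible by 8).
#' @param conv_filters integer triple (F1, F2, F3), each >= 1.
#' @param dense_units dense layer width.
#' @param dropout_rate dropout rate in [0.1, 0.5].
#' @param activation "ReLU", "LeakyReLU" (slope 0.3) or "ELU" (alpha 1).
#' @param n_classes number of classes K.
#' @return an `lvm_architecture` list.
#' @export
lvm_architecture <- function(input_side = 224, conv_filters = c(16, 32, 64),
                             dense_units = 128, dropout_rate = 0.3,
                             activation = c("ReLU", "LeakyReLU", "ELU"),
                             n_classes = 3) {
  activation <- match.arg(activation)
  if (input_side %% 8 != 0) {
    stop("input_side must be divisible by 8 (three 2x2 poolings), got ",
         input_side, call. = FALSE)
  }
  stopifnot(length(conv_filters) == 3, all(conv_filters >= 1),
            dense_units >= 1, n_classes >= 2)
  structure(list(kind = "lvm", input_side = as.integer(input_side),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, activation = activation,
                 n_classes = as.integer(n_classes)),
            class = "lvm_architecture")
}

#' Transfer-learning head architecture over a frozen backbone
#'
#' The backbone (looked up in the registry by `backbone_id`) is a frozen
#' feature extractor; its output map is reduced by global average pooling
#' to one value per channel, then passed through dense(`dense_units`) +
#' activation, dropout, and a softmax output layer.  Only the head is
#' trainable; the L2 penalty `l2_lambda * ||W1||^2` applies to the head's
#' first dense weight matrix.
#'
#' @param backbone_id a registered backbone id (see [list_backbones()]).
#' @param dense_units head width in [64, 512].
#' @param dropout_rate dropout rate in [0.1, 0.5].
#' @param activation "ReLU", "LeakyReLU" or "ELU".
#' @param l2_lambda L2 weight-decay coefficient for the head dense weights.
#' @param n_classes number of classes K.
#' @return a `transfer_architecture` list.
#' @export
transfer_architecture <- function(backbone_id, dense_units = 128,
                                  dropout_rate = 0.3,
                                  activation = c("ReLU", "LeakyReLU", "ELU"),
                                  l2_lambda = 1e-5, n_classes = 3) {
  activation <- match.arg(activation)
  info <- backbone_info(backbone_id) # errors early on unknown id
  stopifnot(dense_units >= 1, n_classes >= 2, l2_lambda >= 0)
  structure(list(kind = "transfer", backbone_id = backbone_id,
                 backbone_channels = info$n_channels,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, activation = activation,
                 l2_lambda = l2_lambda, n_classes = as.integer(n_classes)),
            class = "transfer_architecture")
}

#' Spatial sides of the LVM feature maps
#'
#' @param input_side input image side (divisible by 8).
#' @return integer vector of the three post-pooling sides
#'   (`input_side / c(2, 4, 8)`), e.g. 224 -> 112, 56, 28.
#' @export
feature_map_sides <- function(input_side) {
  stopifnot(input_side %% 8 == 0)
  as.integer(input_side / c(2L, 4L, 8L))
}

#' Build an architecture from decoded hyperparameters
#'
#' @param h decoded `whale_hyperparameters`.
#' @param input_side image side.
#' @param backbone_id backbone for the transfer family (ignored for LVM).
#' @param n_classes number of classes.
#' @return an architecture object of the matching family.
#' @export
architecture_from_hyperparameters <- function(h, input_side = 64,
                                              backbone_id = NULL,
                                              n_classes = 3) {
  family <- attr(h, "model_family")
  if (identical(family, "lvm")) {
    lvm_architecture(input_side = input_side, conv_filters = h$conv_filters,
                     dense_units = h$dense_units,
                     dropout_rate = h$dropout_rate,
                     activation = h$activation, n_classes = n_classes)
  } else {
    transfer_architecture(backbone_id = backbone_id,
                          dense_units = h$dense_units,
                          dropout_rate = h$dropout_rate,
                          activation = h$activation,
                          l2_lambda = h$weight_decay, n_classes = n_classes)
  }
}

#' Build an untrained LVM model handle
#' @param arch an [lvm_architecture()].
#' @return a `whale_model` handle (parameters are initialized at training
#'   time from the training seed).
#' @export
build_lvm <- function(arch) {
  stopifnot(inherits(arch, "lvm_architecture"))
  structure(list(arch = arch, params = NULL, trained = FALSE,
                 history = NULL), class = "whale_model")
}

#' Build an untrained transfer model handle
#' @param arch a [transfer_architecture()].
#' @return a `whale_model` handle.
#' @export
build_transfer_model <- function(arch) {
  stopifnot(inherits(arch, "transfer_architecture"))
  structure(list(arch = arch, params = NULL, trained = FALSE,
                 history = NULL), class = "whale_model")
}

#' @export
print.whale_model <- function(x, ...) {
  a <- x$arch
  if (a$kind == "lvm") {
    cat(sprintf("<whale_model> LVM %dx%d, filters (%s), dense %d, %s\n",
                a$input_side, a$input_side,
                paste(a$conv_filters, collapse = ", "), a$dense_units,
                a$activation))
  } else {
    cat(sprintf("<whale_model> transfer head over '%s' (%d ch), dense %d, %s\n",
                a$backbone_id, a$backbone_channels, a$dense_units,
                a$activation))
  }
  cat(if (x$trained) "  trained" else "  untrained", "\n")
  invisible(x)
}

#' Count trainable parameters of an architecture
#'
#' For transfer heads this is dense(C -> u) + output(u -> K) weights and
#' biases; the frozen backbone contributes nothing.  For the LVM every
#' layer is trainable.
#'
#' @param arch an architecture (or a `whale_model` handle).
#' @return integer parameter count.
#' @export
count_trainable_params <- function(arch) {
  if (inherits(arch, "whale_model")) arch <- arch$arch
  if (arch$kind == "transfer") {
    C <- arch$backbone_channels; u <- arch$dense_units; K <- arch$n_classes
    C * u + u + u * K + K
  } else {
    f <- arch$conv_filters
    side3 <- arch$input_side / 8L
    flat <- side3 * side3 * f[3]
    conv <- 9 * 3 * f[1] + f[1] + 9 * f[1] * f[2] + f[2] +
      9 * f[2] * f[3] + f[3]
    conv + flat * arch$dense_units + arch$dense_units +
      arch$dense_units * arch$n_classes + arch$n_classes
  }
}

#' Training policy
#'
#' The optimizer and its scalar settings, all within the search-space
#' ranges of the hyperparameter codec.  `momentum` is consumed only by SGD.
#'
#' @param optimizer "Adam", "SGD" or "RMSprop".
#' @param learning_rate step size in [1e-5, 1e-2].
#' @param batch_size minibatch size in [16, 128] (capped at the training-set
#'   size at run time).
#' @param epochs number of passes over the training set.
#' @param weight_decay L2 coefficient in [1e-6, 1e-3].
#' @param momentum SGD momentum in [0.5, 0.95].
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `training_policy` list.
#' @export
training_policy <- function(optimizer = c("Adam", "SGD", "RMSprop"),
                            learning_rate = 1e-3, batch_size = 32,
                            epochs = 10, weight_decay = 1e-5,
                            momentum = 0.9, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            weight_decay >= 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 momentum = momentum, seed = as.integer(seed)),
            class = "training_policy")
}

#' Build a training policy from decoded hyperparameters
#' @param h decoded `whale_hyperparameters`.
#' @param epochs number of epochs to train.
#' @param seed training seed.
#' @return a [training_policy()].
#' @export
policy_from_hyperparameters <- function(h, epochs, seed) {
  training_policy(optimizer = h$optimizer, learning_rate = h$learning_rate,
                  batch_size = h$batch_size, epochs = epochs,
                  weight_decay = h$weight_decay, momentum = h$momentum,
                  seed = seed)
}

# ---- parameter initialization ---------------------------------------------

lvm_init_params <- function(arch) {
  f <- arch$conv_filters
  s3 <- arch$input_side / 8L
  flat <- s3 * s3 * f[3]
  u <- arch$dense_units
  K <- arch$n_classes
  list(
    W1 = glorot_uniform(c(3, 3, 3, f[1]), 27, f[1]), b1 = numeric(f[1]),
    W2 = glorot_uniform(c(3, 3, f[1], f[2]), 9 * f[1], f[2]), b2 = numeric(f[2]),
    W3 = glorot_uniform(c(3, 3, f[2], f[3]), 9 * f[2], f[3]), b3 = numeric(f[3]),
    Wd = glorot_uniform(c(flat, u), flat, u), bd = numeric(u),
    Wo = glorot_uniform(c(u, K), u, K), bo = numeric(K)
  )
}

head_init_params <- function(C, u, K) {
  list(W1 = glorot_uniform(c(C, u), C, u), b1 = numeric(u),
       Wo = glorot_uniform(c(u, K), u, K), bo = numeric(K))
}

# Names of weight arrays the L2 penalty covers: all weights for the LVM
# (every trainable layer), only the first head dense matrix for transfer.
l2_names_for <- function(arch) {
  if (arch$kind == "lvm") c("W1", "W2", "W3", "Wd", "Wo") else "W1"
}

# ---- forward / backward ----------------------------------------------------

# images (S, S, 3, N) -> batch tensor (S, S, n, 3)
batch_images <- function(images, idx) {
  aperm(images[, , , idx, drop = FALSE], c(1, 2, 4, 3))
}

lvm_forward <- function(params, x, arch, training = FALSE, drop_mask = NULL) {
  act <- arch$activation
  c1 <- conv3_forward(x, params$W1, params$b1)
  z1 <- c1$out; a1 <- act_forward(z1, act)
  p1 <- maxpool2_forward(a1)
  c2 <- conv3_forward(p1$out, params$W2, params$b2)
  z2 <- c2$out; a2 <- act_forward(z2, act)
  p2 <- maxpool2_forward(a2)
  c3 <- conv3_forward(p2$out, params$W3, params$b3)
  z3 <- c3$out; a3 <- act_forward(z3, act)
  p3 <- maxpool2_forward(a3)
  d <- dim(p3$out) # (s, s, n, F3)
  flat <- t(matrix(aperm(p3$out, c(1, 2, 4, 3)), nrow = d[1] * d[2] * d[4]))
  zd <- dense_forward(flat, params$Wd, params$bd)
  ad <- act_forward(zd, act)
  hd <- if (training && !is.null(drop_mask)) ad * drop_mask else ad
  logits <- dense_forward(hd, params$Wo, params$bo)
  list(logits = logits,
       cache = list(c1 = c1, z1 = z1, p1 = p1, c2 = c2, z2 = z2, p2 = p2,
                    c3 = c3, z3 = z3, p3 = p3, flat = flat, zd = zd,
                    hd = hd, drop_mask = drop_mask, pool_dim = d))
}

lvm_backward <- function(params, cache, dlogits, arch) {
  act <- arch$activation
  g <- list()
  bo <- dense_backward(cache$hd, params$Wo, dlogits)
  g$Wo <- bo$dW; g$bo <- bo$db
  dhd <- bo$dx
  if (!is.null(cache$drop_mask)) dhd <- dhd * cache$drop_mask
  dzd <- act_backward(cache$zd, act, dhd)
  bd <- dense_backward(cache$flat, params$Wd, dzd)
  g$Wd <- bd$dW; g$bd <- bd$db
  d <- cache$pool_dim
  dp3 <- aperm(array(t(bd$dx), dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  da3 <- maxpool2_backward(cache$p3, dp3)
  dz3 <- act_backward(cache$z3, act, da3)
  b3 <- conv3_backward(cache$c3, params$W3, dz3)
  g$W3 <- b3$dW; g$b3 <- b3$db
  da2 <- maxpool2_backward(cache$p2, b3$dx)
  dz2 <- act_backward(cache$z2, act, da2)
  b2 <- conv3_backward(cache$c2, params$W2, dz2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- maxpool2_backward(cache$p1, b2$dx)
  dz1 <- act_backward(cache$z1, act, da1)
  b1 <- conv3_backward(cache$c1, params$W1, dz1, want_dx = FALSE)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

head_forward <- function(params, feats, arch, training = FALSE,
                         drop_mask = NULL) {
  z1 <- dense_forward(feats, params$W1, params$b1)
  a1 <- act_forward(z1, arch$activation)
  h1 <- if (training && !is.null(drop_mask)) a1 * drop_mask else a1
  logits <- dense_forward(h1, params$Wo, params$bo)
  list(logits = logits,
       cache = list(feats = feats, z1 = z1, h1 = h1, drop_mask = drop_mask))
}

head_backward <- function(params, cache, dlogits, arch) {
  g <- list()
  bo <- dense_backward(cache$h1, params$Wo, dlogits)
  g$Wo <- bo$dW; g$bo <- bo$db
  dh1 <- bo$dx
  if (!is.null(cache$drop_mask)) dh1 <- dh1 * cache$drop_mask
  dz1 <- act_backward(cache$z1, arch$activation, dh1)
  b1 <- dense_backward(cache$feats, params$W1, dz1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

# Backbone features with global average pooling, computed in chunks to
# bound peak memory; frozen, so results are cacheable per dataset.
backbone_features <- function(backbone_id, images, chunk = 128L) {
  info <- backbone_info(backbone_id)
  N <- dim(images)[4]
  out <- matrix(0, nrow = N, ncol = info$n_channels)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    out[idx, ] <- global_average_pool(info$fn(batch_images(images, idx)))
  }
  out
}

# ---- training --------------------------------------------------------------

#' Train a model on dataset splits
#'
#' Minimizes integer-label (sparse categorical) cross-entropy plus the L2
#' weight penalty with the policy's optimizer, recording per-epoch training
#' loss, validation loss and validation accuracy.  Transfer models compute
#' their frozen-backbone features once per split and train only the head.
#' Training is fully reproducible from `policy$seed` (initialization,
#' shuffling, dropout).
#'
#' @param handle an untrained (or trained) `whale_model`.
#' @param splits list with `train` and `val` elements, each a list of
#'   `x` (images array (S, S, 3, N)) and `y` (integer labels 0..K-1).
#' @param policy a [training_policy()].
#' @return the trained `whale_model`; `$history` is a data.frame with
#'   columns `epoch`, `loss`, `val_loss`, `val_accuracy`.
#' @export
train_model <- function(handle, splits, policy) {
  stopifnot(inherits(handle, "whale_model"), inherits(policy, "training_policy"))
  for (s in c("train", "val")) {
    if (is.null(splits[[s]]) || length(splits[[s]]$y) == 0) {
      stop("empty '", s, "' split", call. = FALSE)
    }
  }
  arch <- handle$arch
  K <- arch$n_classes
  if (any(splits$train$y < 0 | splits$train$y >= K)) {
    stop("training labels must lie in 0..K-1", call. = FALSE)
  }
  # L2 coverage: every trainable layer for the LVM, the head dense weights
  # for transfer models (the backbone is frozen either way)
  lambda <- if (arch$kind == "lvm") policy$weight_decay else arch$l2_lambda
  withr::with_seed(policy$seed, {
    if (arch$kind == "transfer") {
      xtr <- backbone_features(arch$backbone_id, splits$train$x)
      # standardize the pooled features on the training set; the statistics
      # are frozen into the handle and re-applied at prediction time
      fnorm <- list(mu = colMeans(xtr),
                    sd = pmax(apply(xtr, 2, stats::sd), 1e-8))
      xtr <- sweep(sweep(xtr, 2, fnorm$mu, `-`), 2, fnorm$sd, `/`)
      xva <- backbone_features(arch$backbone_id, splits$val$x)
      xva <- sweep(sweep(xva, 2, fnorm$mu, `-`), 2, fnorm$sd, `/`)
      handle$feature_norm <- fnorm
      params <- head_init_params(arch$backbone_channels, arch$dense_units, K)
      fwd <- function(p, xb, training, mask) head_forward(p, xb, arch, training, mask)
      bwd <- function(p, cache, dl) head_backward(p, cache, dl, arch)
      take <- function(x, idx) x[idx, , drop = FALSE]
      mask_cols <- arch$dense_units
    } else {
      xtr <- splits$train$x
      xva <- splits$val$x
      params <- lvm_init_params(arch)
      fwd <- function(p, xb, training, mask) lvm_forward(p, xb, arch, training, mask)
      bwd <- function(p, cache, dl) lvm_backward(p, cache, dl, arch)
      take <- function(x, idx) batch_images(x, idx)
      mask_cols <- arch$dense_units
    }
    ytr <- as.integer(splits$train$y)
    yva <- as.integer(splits$val$y)
    n_tr <- length(ytr)
    l2n <- l2_names_for(arch)
    opt <- opt_init(params, policy)
    bs <- min(policy$batch_size, n_tr)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_loss = numeric(0), val_accuracy = numeric(0))
    eval_split <- function(x_all, y_all, n_all) {
      tot <- 0; correct <- 0L
      for (start in seq(1L, n_all, by = 64L)) {
        idx <- start:min(start + 63L, n_all)
        fl <- fwd(params, take(x_all, idx), FALSE, NULL)
        cl <- ce_from_logits(fl$logits, y_all[idx])
        tot <- tot + cl$loss * length(idx)
        correct <- correct + sum(max.col(fl$logits) - 1L == y_all[idx])
      }
      list(loss = tot / n_all + l2_penalty_value(params, l2n, lambda),
           acc = correct / n_all)
    }
    for (epoch in seq_len(policy$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      for (start in seq(1L, n_tr, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n_tr)]
        xb <- take(xtr, idx)
        mask <- if (arch$dropout_rate > 0) {
          matrix(dropout_mask(length(idx) * mask_cols, arch$dropout_rate),
                 nrow = length(idx))
        } else NULL
        f <- fwd(params, xb, TRUE, mask)
        cl <- ce_from_logits(f$logits, ytr[idx])
        if (!is.finite(cl$loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d (lr=%g, optimizer=%s); aborting",
            epoch, policy$learning_rate, policy$optimizer), call. = FALSE)
        }
        grads <- bwd(params, f$cache, cl$dlogits)
        l2 <- apply_l2(params, grads, l2n, lambda)
        step <- opt_step(opt, params, l2$grads)
        opt <- step$state
        params <- step$params
        ep_loss <- ep_loss + (cl$loss + l2$penalty) * length(idx)
      }
      val <- eval_split(xva, yva, length(yva))
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / n_tr, val_loss = val$loss,
        val_accuracy = val$acc))
    }
    handle$params <- params
    handle$trained <- TRUE
    handle$history <- history
    handle$l2_lambda <- lambda
    handle
  })
}

#' Predict class probabilities
#'
#' Runs the trained model on preprocessed images and returns the softmax
#' class probabilities as a [probability_matrix()] (rows sum to 1).
#'
#' @param handle a trained `whale_model`.
#' @param images array (S, S, 3, N) of preprocessed images in [0,1].
#' @param image_ids optional row identifiers (default `img_1..N`).
#' @param class_labels optional K class names (default the package's
#'   standard label order).
#' @return a `probability_matrix`.
#' @export
predict_proba <- function(handle, images, image_ids = NULL,
                          class_labels = NULL) {
  stopifnot(inherits(handle, "whale_model"))
  if (!handle$trained) stop("model has not been trained", call. = FALSE)
  arch <- handle$arch
  d <- dim(images)
  if (length(d) != 4L || d[3] != 3L) {
    stop("images must be an (S, S, 3, N) array", call. = FALSE)
  }
  if (arch$kind == "lvm" && (d[1] != arch$input_side || d[2] != arch$input_side)) {
    stop(sprintf("LVM expects %dx%d input, got %dx%d",
                 arch$input_side, arch$input_side, d[1], d[2]), call. = FALSE)
  }
  N <- d[4]
  K <- arch$n_classes
  probs <- matrix(0, N, K)
  if (arch$kind == "transfer") {
    feats <- backbone_features(arch$backbone_id, images)
    if (!is.null(handle$feature_norm)) {
      feats <- sweep(sweep(feats, 2, handle$feature_norm$mu, `-`), 2,
                     handle$feature_norm$sd, `/`)
    }
    for (start in seq(1L, N, by = 256L)) {
      idx <- start:min(start + 255L, N)
      f <- head_forward(handle$params, feats[idx, , drop = FALSE], arch, FALSE, NULL)
      probs[idx, ] <- softmax_rows(f$logits)
    }
  } else {
    for (start in seq(1L, N, by = 64L)) {
      idx <- start:min(start + 63L, N)
      f <- lvm_forward(handle$params, batch_images(images, idx), arch, FALSE, NULL)
      probs[idx, ] <- softmax_rows(f$logits)
    }
  }
  if (is.null(class_labels)) {
    class_labels <- if (K == 3) class_levels() else paste0("class_", seq_len(K) - 1L)
  }
  probability_matrix(probs,
                     image_ids = image_ids %||% paste0("img_", seq_len(N)),
                     class_labels = class_labels)
}
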