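# Frozen feature-extractor registry.
#
# Transfer models consume a backbone through a narrow contract: a function
# that maps an image batch (H, W, N, 3) with values in [0,1] to a
# channel-last feature map (H', W', N, C).  The backbone owns no trainable
# parameters as far as the head is concerned: its weights are fixed at
# registration and never touched by training.  Large pretrained extractors
# can be plugged in through the same contract; the two bundled "tiny"
# backbones keep everything self-contained and fast.

.backbone_registry <- new.env(parent = emptyenv())

#' Register a frozen feature-extractor backbone
#'
#' @param id backbone identifier.
#' @param fn function `(images (H,W,N,3)) -> feature map (H',W',N,C)`.
#' @param n_channels number of output channels C (needed to size the head).
#' @param params optional list of the backbone's fixed weights (exposed so
#'   the freezing contract is checkable).
#' @param description one-line description.
#' @return `id`, invisibly.
#' @export
register_backbone <- function(id, fn, n_channels, params = NULL,
                              description = "") {
  stopifnot(is.character(id), is.function(fn), n_channels >= 1)
  assign(id, list(id = id, fn = fn, n_channels = as.integer(n_channels),
                  params = params, description = description),
         envir = .backbone_registry)
  invisible(id)
}

#' Look up a registered backbone
#' @param id backbone identifier.
#' @return the registry entry (`id`, `fn`, `n_channels`, `params`,
#'   `description`).
#' @export
backbone_info <- function(id) {
  if (!exists(id, envir = .backbone_registry, inherits = FALSE)) {
    stop(sprintf("unknown backbone '%s'; registered: %s", id,
                 paste(list_backbones(), collapse = ", ")), call. = FALSE)
  }
  get(id, envir = .backbone_registry, inherits = FALSE)
}

#' List registered backbone ids
#' @return character vector of ids.
#' @export
list_backbones <- function() sort(ls(envir = .backbone_registry))

# A small fixed two-stage convolutional extractor.  Weights are drawn once
# from a pinned seed at registration, so the extractor is deterministic,
# frozen, and identical across sessions.  Stage 1: 3x3 conv (3 -> c1), ReLU,
# two 2x2 max pools (spatial /4).  Stage 2: 3x3 conv (c1 -> c2), ReLU, one
# 2x2 max pool (spatial /8 overall), then a frozen per-channel affine
# normalization (the analogue of a pretrained network's frozen batch-norm
# statistics), calibrated once at registration on a fixed batch of smooth
# synthetic noise so downstream heads see features with O(1) spread.
make_tiny_backbone <- function(c1, c2, seed) {
  params <- withr::with_seed(seed, list(
    W1 = glorot_uniform(c(3, 3, 3, c1), 27, c1),
    b1 = numeric(c1),
    W2 = glorot_uniform(c(3, 3, c1, c2), 9 * c1, c2),
    b2 = numeric(c2)
  ))
  raw_fn <- function(images) {
    stopifnot(length(dim(images)) == 4L, dim(images)[4] == 3L)
    z <- act_forward(conv3_forward(images, params$W1, params$b1)$out, "ReLU")
    z <- maxpool2_forward(z)$out
    z <- maxpool2_forward(z)$out
    z <- act_forward(conv3_forward(z, params$W2, params$b2)$out, "ReLU")
    maxpool2_forward(z)$out
  }
  calib <- withr::with_seed(seed + 1L, {
    # 16 smooth random fields at 64x64: low-frequency sinusoid mixtures
    # plus noise, spanning the intensity range typical of [0,1] images
    side <- 64L
    imgs <- array(0, c(side, side, 16L, 3L))
    ax <- seq(-1, 1, length.out = side)
    for (n in 1:16) {
      f1 <- stats::runif(1, 0.5, 6); f2 <- stats::runif(1, 0.5, 6)
      ph <- stats::runif(2, 0, 2 * pi)
      base <- 0.5 + 0.35 * outer(sin(f1 * pi * ax + ph[1]),
                                 cos(f2 * pi * ax + ph[2]))
      for (ch in 1:3) {
        imgs[, , n, ch] <- clamp(base +
          matrix(stats::rnorm(side^2, 0, 0.05), side, side), 0, 1)
      }
    }
    fm <- raw_fn(imgs)
    d <- dim(fm)
    flat <- matrix(fm, ncol = d[4])
    list(mu = colMeans(flat),
         sd = pmax(apply(flat, 2, stats::sd), 1e-3))
  })
  params$norm_mu <- calib$mu
  params$norm_sd <- calib$sd
  fn <- function(images) {
    fm <- raw_fn(images)
    d <- dim(fm)
    flat <- matrix(fm, ncol = d[4])
    flat <- sweep(sweep(flat, 2, params$norm_mu, `-`), 2, params$norm_sd, `/`)
    array(flat, dim = d)
  }
  list(fn = fn, params = params, n_channels = c2)
}

register_builtin_backbones <- function() {
  a <- make_tiny_backbone(16L, 32L, seed = 76001L)
  register_backbone("tinynet_a", a$fn, a$n_channels, a$params,
                    "bundled tiny reference extractor A (3->16->32 channels, /8)")
  b <- make_tiny_backbone(24L, 40L, seed = 76002L)
  register_backbone("tinynet_b", b$fn, b$n_channels, b$params,
                    "bundled tiny reference extractor B (3->24->40 channels, /8)")
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backbones()
}

#' Global average pooling
#'
#' Reduces each channel of a feature map to its spatial mean, turning an
#' (H, W, N, C) map into an (N, C) feature matrix.
#'
#' @param fm feature map array (H, W, N, C).
#' @return N x C matrix of pooled features.
#' @export
global_average_pool <- function(fm) {
  stopifnot(length(dim(fm)) == 4L)
  d <- dim(fm)
  m <- colMeans(matrix(fm, nrow = d[1] * d[2], ncol = d[3] * d[4]))
  matrix(m, nrow = d[3], ncol = d[4])
}
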