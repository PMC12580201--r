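# Internal neural-network engine.
#
# Feature maps are stored as 4-d arrays (H, W, N, C): collapsing the first
# three margins of a column-major array gives the (H*W*N) x C matrix a GEMM
# needs, so a 3x3 same-padding convolution is nine shifted matrix products
# against the (C x F) kernel slices and stays BLAS-bound.  Dense activations
# are plain (N x units) matrices.  Everything is double precision.

# ---- convolution -----------------------------------------------------------
#
# im2col layout: with feature maps collapsed to an (H*W) x (N*C) matrix,
# zero padding is a row scatter, each of the nine kernel offsets is a row
# gather, and the whole convolution is one GEMM against the (9C x F)
# kernel matrix.  Row gathers on matrices hit R's fast indexing path,
# unlike 4-d array slices.

conv3_offsets <- function(H, W) {
  Hp <- H + 2L
  interior <- as.vector(outer(2:(H + 1L), (2:(W + 1L) - 1L) * Hp, `+`))
  offs <- vector("list", 9L)
  kk <- 0L
  for (dj in 1:3) {
    for (di in 1:3) {
      kk <- kk + 1L
      offs[[kk]] <- as.vector(outer(di:(di + H - 1L),
                                    (dj:(dj + W - 1L) - 1L) * Hp, `+`))
    }
  }
  list(interior = interior, offsets = offs, padded_rows = Hp * (W + 2L))
}

# x: (H, W, N, C) -> column matrix (H*W*N, 9C); offset blocks ordered
# (c fastest, then di, then dj), matching aperm(W, c(3,1,2,4)).
conv3_im2col <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  geo <- conv3_offsets(H, W)
  P <- matrix(0, geo$padded_rows, N * C)
  P[geo$interior, ] <- x
  xcol <- matrix(0, H * W * N, 9L * C)
  for (kk in 1:9) {
    S <- P[geo$offsets[[kk]], , drop = FALSE]
    dim(S) <- c(H * W * N, C)
    xcol[, ((kk - 1L) * C + 1L):(kk * C)] <- S
  }
  xcol
}

kernel_matrix <- function(W) {
  d <- dim(W) # (3, 3, C, F)
  matrix(aperm(W, c(3, 1, 2, 4)), nrow = 9L * d[3], ncol = d[4])
}

# 'Same' zero padding.  Returns the output map plus the column matrix and
# input geometry, which the backward pass reuses.
conv3_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]
  F <- dim(W)[4]
  xcol <- conv3_im2col(x)
  out <- xcol %*% kernel_matrix(W)
  out <- out + rep(b, each = H * Wd * N)
  dim(out) <- c(H, Wd, N, F)
  list(out = out, xcol = xcol, in_dim = d)
}

conv3_backward <- function(fwd, W, dout, want_dx = TRUE) {
  d <- fwd$in_dim; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  F <- dim(W)[4]
  dim(dout) <- c(H * Wd * N, F)
  db <- colSums(dout)
  dW2 <- crossprod(fwd$xcol, dout) # (9C, F)
  dW <- aperm(array(dW2, c(C, 3L, 3L, F)), c(2, 3, 1, 4))
  dx <- NULL
  if (want_dx) {
    dxcol <- tcrossprod(dout, kernel_matrix(W)) # (HWN, 9C)
    geo <- conv3_offsets(H, Wd)
    dP <- matrix(0, geo$padded_rows, N * C)
    for (kk in 1:9) {
      dS <- dxcol[, ((kk - 1L) * C + 1L):(kk * C), drop = FALSE]
      dim(dS) <- c(H * Wd, N * C)
      dP[geo$offsets[[kk]], ] <- dP[geo$offsets[[kk]], ] + dS
    }
    dx <- dP[geo$interior, , drop = FALSE]
    dim(dx) <- c(H, Wd, N, C)
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  i1 <- seq(1L, H, 2L); j1 <- seq(1L, W, 2L)
  s1 <- x[i1, j1, , , drop = FALSE]
  s2 <- x[i1 + 1L, j1, , , drop = FALSE]
  s3 <- x[i1, j1 + 1L, , , drop = FALSE]
  s4 <- x[i1 + 1L, j1 + 1L, , , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  # ties resolved in slice order (top-left wins), matching the forward max
  m1 <- s1 == m
  m2 <- (s2 == m) & !m1
  m3 <- (s3 == m) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = m, masks = list(m1, m2, m3, m4), in_dim = d)
}

maxpool2_backward <- function(pool, dout) {
  d <- pool$in_dim; H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); j1 <- seq(1L, W, 2L)
  dx <- array(0, d)
  dx[i1, j1, , ] <- dout * pool$masks[[1]]
  dx[i1 + 1L, j1, , ] <- dout * pool$masks[[2]]
  dx[i1, j1 + 1L, , ] <- dout * pool$masks[[3]]
  dx[i1 + 1L, j1 + 1L, , ] <- dout * pool$masks[[4]]
  dx
}

# ---- activations -----------------------------------------------------------

# LeakyReLU negative slope 0.3, ELU alpha = 1.
act_forward <- function(x, kind) {
  switch(kind,
    ReLU = pmax(x, 0),
    LeakyReLU = {
      y <- x
      neg <- x < 0
      y[neg] <- 0.3 * x[neg]
      y
    },
    ELU = {
      y <- x
      neg <- x < 0
      y[neg] <- exp(x[neg]) - 1
      y
    },
    stop("unknown activation: ", kind))
}

act_backward <- function(x, kind, dout) {
  switch(kind,
    ReLU = dout * (x > 0),
    LeakyReLU = dout * ifelse(x > 0, 1, 0.3),
    ELU = {
      g <- array(1, dim(x) %||% length(x))
      neg <- x < 0
      g[neg] <- exp(x[neg])
      dout * g
    },
    stop("unknown activation: ", kind))
}

# ---- dense / dropout / loss ------------------------------------------------

dense_forward <- function(X, W, b) sweep(X %*% W, 2, b, `+`)

dense_backward <- function(X, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(X, dout), db = colSums(dout))
}

# Inverted dropout: scale kept units by 1/(1-rate) at train time so
# inference needs no rescaling.
dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Sparse categorical cross-entropy from logits; y holds integer labels in
# 0..K-1.  Returns mean loss and the gradient wrt logits.
ce_from_logits <- function(logits, y) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_len(n), y + 1L)]
  loss <- mean(lse - picked)
  p <- softmax_rows(logits)
  p[cbind(seq_len(n), y + 1L)] <- p[cbind(seq_len(n), y + 1L)] - 1
  list(loss = loss, dlogits = p / n)
}

# ---- initialization --------------------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- optimizers ------------------------------------------------------------

# params/grads are flat named lists of arrays.  State is kept per parameter.
opt_init <- function(params, policy) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  state <- switch(policy$optimizer,
    SGD = list(v = zeros),
    RMSprop = list(s = zeros),
    Adam = list(m = zeros, v = zeros, t = 0L),
    stop("unknown optimizer: ", policy$optimizer))
  state$kind <- policy$optimizer
  state$lr <- policy$learning_rate
  state$momentum <- policy$momentum %||% 0
  state
}

opt_step <- function(state, params, grads) {
  lr <- state$lr
  nm <- names(params)
  if (state$kind == "SGD") {
    for (k in nm) {
      state$v[[k]] <- state$momentum * state$v[[k]] - lr * grads[[k]]
      params[[k]] <- params[[k]] + state$v[[k]]
    }
  } else if (state$kind == "RMSprop") {
    rho <- 0.9; eps <- 1e-7
    for (k in nm) {
      state$s[[k]] <- rho * state$s[[k]] + (1 - rho) * grads[[k]]^2
      params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(state$s[[k]]) + eps)
    }
  } else { # Adam
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
    state$t <- state$t + 1L
    corr1 <- 1 - b1^state$t
    corr2 <- 1 - b2^state$t
    for (k in nm) {
      state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
      state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
      mhat <- state$m[[k]] / corr1
      vhat <- state$v[[k]] / corr2
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, params = params)
}

# L2 penalty lambda * sum(W^2) over the named weight arrays; adds 2*lambda*W
# to the matching gradients.  Returns the penalty value.
apply_l2 <- function(params, grads, l2_names, lambda) {
  pen <- 0
  if (lambda > 0) {
    for (k in l2_names) {
      pen <- pen + lambda * sum(params[[k]]^2)
      grads[[k]] <- grads[[k]] + 2 * lambda * params[[k]]
    }
  }
  list(penalty = pen, grads = grads)
}

l2_penalty_value <- function(params, l2_names, lambda) {
  if (lambda <= 0) return(0)
  sum(vapply(l2_names, function(k) sum(params[[k]]^2), 0)) * lambda
}
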