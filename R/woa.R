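#' Configuration for the whale optimization algorithm
#'
#' @param n_whales population size (>= 2).  Small populations (2-5) paired
#'   with few iterations (5-10) are typical when each objective evaluation
#'   is a partial model training.
#' @param max_iterations iteration budget T (>= 1).
#' @param spiral_b logarithmic-spiral shape constant b (> 0, default 1).
#' @param early_stop_patience stop after this many consecutive iterations
#'   without improvement of the best fitness.
#' @param seed integer seed; the whole run (initialization and every random
#'   draw of the update rules) is reproducible from it.
#' @return a `woa_config` list.
#' @export
woa_config <- function(n_whales = 3, max_iterations = 8, spiral_b = 1,
                       early_stop_patience = 3, seed = 1) {
  stopifnot(n_whales >= 2, max_iterations >= 1, spiral_b > 0,
            early_stop_patience >= 1)
  structure(list(n_whales = as.integer(n_whales),
                 max_iterations = as.integer(max_iterations),
                 spiral_b = spiral_b,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "woa_config")
}

#' Linear coefficient schedule
#'
#' The encircling coefficient magnitude `a` decreases linearly from 2 at the
#' start of the search to 0 at the end; it controls the exploration to
#' exploitation transition (components of A are drawn from `[-a, a]`).
#'
#' @param t iteration index, `0 <= t <= T`.
#' @param T total number of iterations, `T >= 1`.
#' @return `2 * (1 - t / T)`.
#' @export
#' @examples
#' woa_a_schedule(0, 10)  # 2
#' woa_a_schedule(10, 10) # 0
woa_a_schedule <- function(t, T) {
  stopifnot(T >= 1)
  if (t < 0 || t > T) stop("iteration t must satisfy 0 <= t <= T", call. = FALSE)
  2 * (1 - t / T)
}

#' One whale position update
#'
#' Applies the branch structure of the algorithm: with probability p < 0.5
#' either encircling of the best position (|A| < 1, intensification) or
#' exploration toward a random whale (|A| >= 1); otherwise the logarithmic
#' spiral move around the best position.  The result is clamped into the
#' unit cube.
#'
#' @param whale current position.
#' @param best best-so-far position (the "prey").
#' @param rand_whale a randomly selected other whale's position.
#' @param coeff list with elements `A`, `C` (vectors of the position's
#'   dimension), `l` in `[-1,1]`, `p` in `[0,1]`.
#' @param b spiral shape constant.
#' @return updated position in `[0,1]^d`.
#' @export
woa_update_position <- function(whale, best, rand_whale, coeff, b = 1) {
  d <- length(whale)
  if (length(best) != d || length(rand_whale) != d ||
      length(coeff$A) != d || length(coeff$C) != d) {
    stop("position/coefficient dimension mismatch", call. = FALSE)
  }
  new_pos <- if (coeff$p < 0.5) {
    if (sqrt(sum(coeff$A^2)) < 1) {
      D <- abs(coeff$C * best - whale)        # encircle the best solution
      best - coeff$A * D
    } else {
      D <- abs(coeff$C * rand_whale - whale)  # explore toward a random whale
      rand_whale - coeff$A * D
    }
  } else {
    Dp <- abs(best - whale)                   # spiral around the best
    Dp * exp(b * coeff$l) * cos(2 * pi * coeff$l) + best
  }
  clamp(new_pos)
}

# Evaluate the objective defensively: errors and non-finite values become
# +Inf so a single diverged training cannot kill the search.
safe_eval <- function(objective, x) {
  f <- tryCatch(objective(x), error = function(e) {
    message("objective evaluation failed (treated as +Inf): ",
            conditionMessage(e))
    Inf
  })
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) Inf else as.numeric(f)
}

#' Whale optimization over the unit cube
#'
#' Population-based minimization of `objective` on `[0,1]^d`.  The
#' population is initialized uniformly at random, every whale is updated
#' per iteration by [woa_update_position()] with per-whale, per-component
#' fresh random coefficients, and the best-so-far position is kept
#' elitistically (replaced only on strict improvement).  The search stops
#' at `max_iterations` or when the best fitness has not improved for
#' `early_stop_patience` consecutive iterations.
#'
#' @param objective function mapping a numeric vector in `[0,1]^d` to a
#'   single finite number (errors / non-finite values count as `+Inf`).
#' @param d dimensionality of the search cube.
#' @param config a [woa_config()].
#' @return a `woa_run` list: `positions` (final population), `fitness`
#'   (their objective values), `best_position`, `best_fitness`,
#'   `iterations` completed, `convergence_curve` (best-so-far per
#'   iteration, non-increasing), `n_evaluations`
#'   (`n_whales * (iterations + 1)`), `stopped_early`.
#' @export
#' @examples
#' sphere <- function(x) sum((x - 0.5)^2)
#' run <- woa_optimize(sphere, d = 5, woa_config(n_whales = 5,
#'                     max_iterations = 10, seed = 7))
#' run$best_fitness
woa_optimize <- function(objective, d, config = woa_config()) {
  stopifnot(inherits(config, "woa_config"), d >= 1)
  n <- config$n_whales
  T <- config$max_iterations
  withr::with_seed(config$seed, {
    X <- matrix(stats::runif(n * d), nrow = n, ncol = d)
    fit <- vapply(seq_len(n), function(i) safe_eval(objective, X[i, ]), 0)
    best_i <- which.min(fit)
    best_x <- X[best_i, ]
    best_f <- fit[best_i]
    curve <- numeric(0)
    no_improve <- 0L
    completed <- 0L
    for (t in seq_len(T)) {
      a <- woa_a_schedule(t - 1, T)
      X_prev <- X
      for (i in seq_len(n)) {
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
        coeff <- list(A = 2 * a * r1 - a, C = 2 * r2,
                      l = stats::runif(1, -1, 1), p = stats::runif(1))
        j <- if (n > 2) sample(setdiff(seq_len(n), i), 1L) else setdiff(seq_len(n), i)
        X[i, ] <- woa_update_position(X_prev[i, ], best_x, X_prev[j, ],
                                      coeff, config$spiral_b)
      }
      fit <- vapply(seq_len(n), function(i) safe_eval(objective, X[i, ]), 0)
      improved <- min(fit) < best_f
      if (improved) {
        best_i <- which.min(fit)
        best_x <- X[best_i, ]
        best_f <- fit[best_i]
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
      }
      completed <- t
      curve <- c(curve, best_f)
      if (no_improve >= config$early_stop_patience && t < T) {
        completed <- t
        break
      }
    }
    structure(list(positions = X, fitness = fit,
                   best_position = best_x, best_fitness = best_f,
                   iterations = completed, convergence_curve = curve,
                   n_evaluations = n * (completed + 1L),
                   stopped_early = completed < T,
                   config = config),
              class = "woa_run")
  })
}

#' @export
print.woa_run <- function(x, ...) {
  cat(sprintf(
    "<woa_run> %d whales, %d iteration(s)%s, %d evaluations\n  best fitness: %g\n",
    x$config$n_whales, x$iterations,
    if (x$stopped_early) " (early stop)" else "", x$n_evaluations,
    x$best_fitness))
  invisible(x)
}

#' Write a convergence curve to CSV
#'
#' Two columns: `iteration` (1-based) and `best_fitness` (best-so-far
#' objective value at the end of that iteration).
#'
#' @param run a `woa_run`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_convergence_csv <- function(run, path) {
  df <- data.frame(iteration = seq_along(run$convergence_curve),
                   best_fitness = run$convergence_curve)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
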