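sphere <- function(x) sum((x - 0.5)^2)

test_that("the coefficient schedule is linear with exact endpoints", {
  expect_equal(woa_a_schedule(0, 10), 2)
  expect_equal(woa_a_schedule(10, 10), 0)
  expect_equal(woa_a_schedule(5, 10), 1)
  expect_error(woa_a_schedule(11, 10), "0 <= t <= T")
})

test_that("position update branches collapse to their closed forms", {
  d <- 4
  whale <- rep(0.2, d); best <- rep(0.6, d); rnd <- rep(0.9, d)
  # encircling with A = 0 lands exactly on the best position
  co <- list(A = rep(0, d), C = rep(1.3, d), l = 0, p = 0.2)
  expect_equal(woa_update_position(whale, best, rnd, co), best)
  # exploration branch (|A| = 1): components with A_i = 0 land on the
  # random whale, the driven component moves away by A_1 * D_1
  co2 <- list(A = c(1, rep(0, d - 1)), C = rep(1, d), l = 0, p = 0.2)
  got <- woa_update_position(whale, best, rnd, co2)
  expect_equal(got[-1], rnd[-1])
  expect_equal(got[1], rnd[1] - abs(rnd[1] - whale[1]))
  # spiral with l = 0, b = 1: |best - whale| + best, clamped to [0,1]
  co3 <- list(A = rep(0, d), C = rep(1, d), l = 0, p = 0.9)
  expect_equal(woa_update_position(whale, best, rnd, co3),
               pmin(abs(best - whale) + best, 1))
  expect_error(woa_update_position(whale[-1], best, rnd, co3),
               "dimension mismatch")
})

test_that("optimization improves on the initial population and is elitist", {
  res <- vapply(1:100, function(seed) {
    cfg <- woa_config(n_whales = 5, max_iterations = 10,
                      early_stop_patience = 10, seed = seed)
    # recompute the initial population minimum independently
    init_best <- withr::with_seed(seed, {
      X <- matrix(stats::runif(5 * 5), 5, 5)
      min(apply(X, 1, sphere))
    })
    run <- woa_optimize(sphere, 5, cfg)
    c(no_worse = run$best_fitness <= init_best,
      monotone = all(diff(run$convergence_curve) <= 0),
      improved = run$best_fitness < init_best)
  }, c(no_worse = FALSE, monotone = FALSE, improved = FALSE))
  expect_true(all(res["no_worse", ]))
  expect_true(all(res["monotone", ]))
  expect_gte(sum(res["improved", ]), 95)
})

test_that("a constant objective terminates by patience", {
  run <- woa_optimize(function(x) 1.0, 3,
                      woa_config(n_whales = 3, max_iterations = 10,
                                 early_stop_patience = 3, seed = 4))
  expect_true(run$stopped_early)
  expect_equal(run$convergence_curve, rep(1.0, 3))
  expect_equal(run$iterations, 3)
})

test_that("identical seeds give bit-identical runs; positions stay in the cube", {
  seen <- new.env(); seen$ok <- TRUE
  watched <- function(x) {
    if (any(x < 0 | x > 1)) seen$ok <- FALSE
    sphere(x)
  }
  cfg <- woa_config(n_whales = 4, max_iterations = 8, seed = 123)
  r1 <- woa_optimize(watched, 6, cfg)
  r2 <- woa_optimize(sphere, 6, cfg)
  expect_identical(r1$convergence_curve, r2$convergence_curve)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(seen$ok)
  expect_true(all(r1$positions >= 0 & r1$positions <= 1))
})

test_that("objective evaluations follow the budget accounting", {
  calls <- new.env(); calls$n <- 0L
  counting <- function(x) { calls$n <- calls$n + 1L; sphere(x) }
  run <- woa_optimize(counting, 3,
                      woa_config(n_whales = 4, max_iterations = 5,
                                 early_stop_patience = 5, seed = 2))
  expect_equal(calls$n, 4L * (run$iterations + 1L))
  expect_equal(run$n_evaluations, calls$n)
})

test_that("errors and non-finite objective values count as +Inf, run continues", {
  flaky <- function(x) {
    if (x[1] < 0.3) stop("synthetic failure")
    if (x[1] > 0.9) NaN else sum(x)
  }
  expect_message(
    run <- woa_optimize(flaky, 2,
                        woa_config(n_whales = 3, max_iterations = 4,
                                   early_stop_patience = 4, seed = 5)),
    "treated as \\+Inf")
  expect_true(is.finite(run$best_fitness))
})

test_that("the search beats a random-search oracle at equal budget", {
  woa_best <- numeric(100); rand_best <- numeric(100); onedim <- numeric(100)
  for (seed in 1:100) {
    cfg <- woa_config(n_whales = 5, max_iterations = 10,
                      early_stop_patience = 10, seed = seed)
    run <- woa_optimize(sphere, 5, cfg)
    woa_best[seed] <- run$best_fitness
    rand_best[seed] <- withr::with_seed(seed + 10000, {
      X <- matrix(stats::runif(run$n_evaluations * 5), ncol = 5)
      min(apply(X, 1, sphere))
    })
    one <- woa_optimize(function(x) x[1], 1,
                        woa_config(n_whales = 5, max_iterations = 10,
                                   early_stop_patience = 10, seed = seed))
    onedim[seed] <- one$best_fitness
  }
  expect_lt(mean(woa_best), mean(rand_best))
  expect_gte(mean(onedim < 0.1), 0.90)
})

test_that("convergence curves export as two-column CSV", {
  run <- woa_optimize(sphere, 3, woa_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_convergence_csv(run, path)
  df <- read.csv(path)
  expect_equal(names(df), c("iteration", "best_fitness"))
  expect_equal(df$best_fitness, run$convergence_curve)
})
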