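test_that("search spaces have the documented shape and order", {
  tr <- search_space("transfer")
  lv <- search_space("lvm")
  expect_equal(space_dim(tr), 8)
  expect_equal(space_dim(lv), 11)
  expect_equal(vapply(lv$dimensions, `[[`, "", "name"),
               c("learning_rate", "batch_size", "dropout_rate",
                 "dense_units", "optimizer", "activation", "weight_decay",
                 "momentum", "conv1_filters", "conv2_filters",
                 "conv3_filters"))
})

test_that("all-ones and all-zeros vectors decode to the range endpoints", {
  sp <- search_space("lvm")
  h1 <- decode_hyperparameters(rep(1, 11), sp)
  expect_equal(h1$learning_rate, 1e-2)
  expect_equal(h1$batch_size, 128L)
  expect_equal(h1$dropout_rate, 0.5)
  expect_equal(h1$dense_units, 512L)
  expect_equal(h1$optimizer, "RMSprop")
  expect_equal(h1$activation, "ELU")
  expect_equal(h1$weight_decay, 1e-3)
  expect_equal(h1$momentum, 0.95)
  # the printed per-block formulas f = int(base * (0.5 + 1.5 x)) imply
  # maxima of twice the base, not the wider printed ranges
  expect_equal(h1$conv_filters, c(64L, 128L, 256L))

  h0 <- decode_hyperparameters(rep(0, 11), sp)
  expect_equal(h0$learning_rate, 1e-5)
  expect_equal(h0$batch_size, 16L)
  expect_equal(h0$dropout_rate, 0.1)
  expect_equal(h0$dense_units, 64L)
  expect_equal(h0$optimizer, "Adam")
  expect_equal(h0$activation, "ReLU")
  expect_equal(h0$weight_decay, 1e-6)
  expect_equal(h0$momentum, 0.5)
  expect_equal(h0$conv_filters, c(16L, 32L, 64L))

  wide <- decode_hyperparameters(rep(1, 11),
                                 search_space("lvm", extended_filter_range = TRUE))
  expect_equal(wide$conv_filters, c(96L, 192L, 384L))
})

test_that("decoding validates dimension count and clamps stray coordinates", {
  sp <- search_space("transfer")
  expect_error(decode_hyperparameters(rep(0.5, 11), sp), "expected 8")
  expect_warning(h <- decode_hyperparameters(c(rep(0.5, 7), 1.2), sp),
                 "clamped")
  expect_equal(h$momentum, 0.95)
})

test_that("encode inverts decode", {
  sp <- search_space("lvm")
  # continuous dimensions round-trip exactly through coordinates
  v <- c(0.3, 0.25, 0.6, 0.5, 0.5, 1, 0.8, 0.1, 0.2, 0.9, 0.4)
  h <- decode_hyperparameters(v, sp)
  v2 <- encode_hyperparameters(h, sp)
  h2 <- decode_hyperparameters(v2, sp)
  for (f in c("learning_rate", "dropout_rate", "momentum", "weight_decay")) {
    expect_equal(h2[[f]], h[[f]], tolerance = 1e-12)
  }
  # integer and categorical dimensions reproduce the decoded values exactly
  expect_identical(h2$batch_size, h$batch_size)
  expect_identical(h2$dense_units, h$dense_units)
  expect_identical(h2$conv_filters, h$conv_filters)
  expect_identical(h2$optimizer, h$optimizer)
  expect_identical(h2$activation, h$activation)

  # worked inverses
  h$dense_units <- 288L
  expect_equal(encode_hyperparameters(h, sp)[4], 0.5)
  h$optimizer <- "SGD"
  expect_equal(encode_hyperparameters(h, sp)[5], 0.5)
  h$learning_rate <- 2
  expect_error(encode_hyperparameters(h, sp), "learning_rate")
})

test_that("sampled decodes stay in range and are monotone per coordinate", {
  for (family in c("transfer", "lvm")) {
    sp <- search_space(family)
    d <- space_dim(sp)
    in_range <- withr::with_seed(99, {
      V <- matrix(stats::runif(10000 * d), ncol = d)
      vapply(seq_len(nrow(V)), function(i) {
        h <- decode_hyperparameters(V[i, ], sp)
        ok <- h$learning_rate >= 1e-5 && h$learning_rate <= 1e-2 &&
          h$batch_size >= 16L && h$batch_size <= 128L &&
          h$dropout_rate >= 0.1 && h$dropout_rate <= 0.5 &&
          h$dense_units >= 64L && h$dense_units <= 512L &&
          h$weight_decay >= 1e-6 && h$weight_decay <= 1e-3 &&
          h$momentum >= 0.5 && h$momentum <= 0.95
        if (family == "lvm") {
          ok <- ok && all(h$conv_filters >= c(16L, 32L, 64L)) &&
            all(h$conv_filters <= c(64L, 128L, 256L))
        }
        ok
      }, logical(1))
    })
    expect_true(all(in_range))
    # monotone continuous fields along each own coordinate
    base <- rep(0.4, d)
    for (j in which(vapply(sp$dimensions, `[[`, "", "scale") != "categorical-index")) {
      vals <- vapply(seq(0, 1, by = 0.05), function(x) {
        v <- base; v[j] <- x
        h <- decode_hyperparameters(v, sp)
        nm <- sp$dimensions[[j]]$name
        if (grepl("^conv", nm)) {
          h$conv_filters[as.integer(substr(nm, 5, 5))]
        } else {
          as.numeric(h[[nm]])
        }
      }, 0)
      expect_true(all(diff(vals) >= 0))
    }
  }
})

test_that("categorical boundaries land on exact indices", {
  sp <- search_space("transfer")
  v <- rep(0.5, 8)
  for (x in c(0, 0.5, 1)) {
    v[5] <- x
    expect_equal(decode_hyperparameters(v, sp)$optimizer,
                 c("Adam", "SGD", "RMSprop")[2 * x + 1])
  }
  # half-up rounding makes the 0.25 / 0.75 boundaries deterministic
  v[5] <- 0.25
  expect_equal(decode_hyperparameters(v, sp)$optimizer, "SGD")
  v[5] <- 0.75
  expect_equal(decode_hyperparameters(v, sp)$optimizer, "RMSprop")
})

test_that("configuration report table gates momentum on SGD", {
  sp <- search_space("transfer")
  h <- decode_hyperparameters(rep(0.5, 8), sp) # optimizer SGD at 0.5
  tab <- hyperparameters_to_table(h)
  expect_equal(tab$value[tab$hyperparameter == "momentum"], "0.725")
  h2 <- decode_hyperparameters(c(rep(0.5, 4), 0, 0.5, 0.5, 0.5), sp)
  tab2 <- hyperparameters_to_table(h2)
  expect_equal(tab2$value[tab2$hyperparameter == "momentum"], "-")
})
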