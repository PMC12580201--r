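ns <- asNamespace("whalenet")

test_that("LVM shape contract: sides halve through the three blocks", {
  expect_equal(feature_map_sides(224), c(112L, 56L, 28L))
  expect_equal(feature_map_sides(64), c(32L, 16L, 8L))
  expect_error(lvm_architecture(input_side = 100), "divisible by 8")
  # flatten length for a 64-pixel input with F3 = 16 is 8 * 8 * 16
  arch <- lvm_architecture(64, c(2, 3, 16), dense_units = 8,
                           dropout_rate = 0, activation = "ReLU")
  params <- withr::with_seed(5, ns$lvm_init_params(arch))
  x <- array(stats::runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  fwd <- ns$lvm_forward(params, x, arch, FALSE, NULL)
  expect_equal(dim(fwd$cache$p1$out)[1:2], c(32L, 32L))
  expect_equal(dim(fwd$cache$p2$out)[1:2], c(16L, 16L))
  expect_equal(dim(fwd$cache$p3$out)[1:2], c(8L, 8L))
  expect_equal(ncol(fwd$cache$flat), 1024L)
})

test_that("trainable-parameter counts follow dense-layer arithmetic", {
  # a frozen 1024-channel extractor with a 170-unit head over 3 classes
  register_backbone("wide_ref_synthetic", function(images) stop("unused"),
                    n_channels = 1024)
  arch <- transfer_architecture("wide_ref_synthetic", dense_units = 170)
  expect_equal(count_trainable_params(arch), 1024 * 170 + 170 + 170 * 3 + 3)
  small <- transfer_architecture("tinynet_a", dense_units = 64)
  large <- transfer_architecture("tinynet_a", dense_units = 512)
  expect_lt(count_trainable_params(small), count_trainable_params(large))
  expect_error(transfer_architecture("no_such_backbone"), "unknown backbone")
})

test_that("an untrained 3-class model scores about ln 3 on balanced data", {
  splits <- fixture_splits()
  # one epoch at a vanishing learning rate leaves the model untrained
  pol <- training_policy("SGD", learning_rate = 1e-8, batch_size = 32,
                         epochs = 1, weight_decay = 0, momentum = 0.5,
                         seed = 7)
  m <- train_model(build_transfer_model(
    transfer_architecture("tinynet_a", 64, 0.1, "ReLU", 0)), splits, pol)
  expect_equal(m$history$val_loss[1], log(3), tolerance = 0.15)
  expect_equal(nrow(m$history), 1L)
})

test_that("training learns separable synthetic data and records history", {
  splits <- fixture_splits()
  pol <- training_policy("Adam", 1e-3, 32, 20, 1e-5, seed = 5)
  m <- train_model(build_transfer_model(
    transfer_architecture("tinynet_a", 128, 0.2, "ReLU", 1e-5)), splits, pol)
  expect_equal(nrow(m$history), 20L)
  expect_gt(utils::tail(m$history$val_accuracy, 1), 0.8)
  # probability contract on the test split
  pm <- predict_proba(m, splits$test$x)
  expect_true(all(abs(rowSums(pm$probs) - 1) < 1e-6))
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
})

test_that("seeded training is exactly repeatable", {
  splits <- fixture_splits()
  pol <- training_policy("RMSprop", 5e-4, 32, 5, 1e-5, seed = 21)
  arch <- transfer_architecture("tinynet_b", 96, 0.3, "ELU", 1e-5)
  m1 <- train_model(build_transfer_model(arch), splits, pol)
  m2 <- train_model(build_transfer_model(arch), splits, pol)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("the frozen backbone is untouched by training", {
  before <- backbone_info("tinynet_a")$params
  splits <- fixture_splits()
  pol <- training_policy("Adam", 1e-3, 32, 3, 1e-5, seed = 8)
  train_model(build_transfer_model(
    transfer_architecture("tinynet_a", 64, 0.2, "ReLU", 1e-5)), splits, pol)
  after <- backbone_info("tinynet_a")$params
  expect_identical(before, after)
})

test_that("LVM training aborts informatively on divergence and empty splits", {
  splits <- fixture_splits()
  expect_error(train_model(build_lvm(lvm_architecture(64)),
                           list(train = splits$train, val = NULL),
                           training_policy("Adam", 1e-3)),
               "empty 'val' split")
  bad <- splits
  bad$train$y[1] <- 7L
  expect_error(train_model(build_lvm(lvm_architecture(64)), bad,
                           training_policy("Adam", 1e-3)),
               "labels")
})

test_that("prediction validates input shape", {
  splits <- fixture_splits()
  pol <- training_policy("Adam", 1e-3, 32, 2, 1e-5, seed = 9)
  m <- train_model(build_lvm(lvm_architecture(64, c(4, 6, 8), 16, 0.1,
                                              "ReLU")), splits, pol)
  expect_error(predict_proba(m, array(0, c(32, 32, 3, 2))), "expects 64x64")
  expect_error(predict_proba(m, splits$test$x[, , 1:2, , drop = FALSE]),
               "\\(S, S, 3, N\\)")
})
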