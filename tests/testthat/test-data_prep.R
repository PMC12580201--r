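test_that("label encoding follows the fixed three-class order", {
  expect_equal(encode_label(c("Normal", "Benign", "Malignant")), c(0L, 1L, 2L))
  expect_equal(decode_label(encode_label(class_levels())), class_levels())
  expect_error(encode_label("Cystic"), "unknown class")
  expect_error(decode_label(3), "outside")
})

test_that("preprocessing resizes and rescales to [0,1]", {
  expect_equal(preprocess_image(array(255, c(10, 10, 3)), side = 16),
               array(1, c(16, 16, 3)))
  expect_equal(preprocess_image(array(0, c(10, 10, 3)), side = 16),
               array(0, c(16, 16, 3)))
  # grayscale input is replicated across channels
  g <- preprocess_image(matrix(128, 8, 8), side = 8)
  expect_equal(dim(g), c(8, 8, 3))
  expect_equal(g[1, 1, 1], 128 / 255)
  # interpolation approximately preserves the mean of a checkerboard
  withr::with_seed(41, {
    board <- 255 * (outer(seq_len(720), seq_len(720), function(i, j)
      (i %/% 24 + j %/% 24) %% 2))
    board <- array(rep(board, 3), c(720, 720, 3))
  })
  small <- preprocess_image(board, side = 224)
  expect_true(all(small >= 0 & small <= 1))
  expect_equal(mean(small), mean(board / 255), tolerance = 0.05)
  expect_error(preprocess_image("nonexistent.png"), "cannot read")
})

test_that("single-image patients split exactly 80/10/10 and are patient-disjoint", {
  man <- single_image_manifest(100)
  split <- patient_stratified_split(man, seed = 5)
  for (cl in class_levels()) {
    tab <- table(split$split[split$class == cl])
    expect_equal(as.integer(tab[c("train", "val", "test")]), c(80L, 10L, 10L))
  }
  # disjointness holds for any seed, with multi-image patients too
  spec <- synthetic_cohort_spec(patients_per_class = 17, image_side = 16,
                                seed = 2)
  man3 <- cohort_manifest(spec)
  for (seed in c(1, 9, 104)) {
    sp <- patient_stratified_split(man3, seed = seed)
    overlap <- tapply(sp$split, sp$patient_id,
                      function(s) length(unique(s)))
    expect_true(all(overlap == 1))
  }
})

test_that("the greedy allocation lands within one patient of the targets", {
  spec <- synthetic_cohort_spec(patients_per_class = 150, image_side = 16,
                                seed = 3)
  man <- cohort_manifest(spec) # 450 patients, 3 images each
  sp <- patient_stratified_split(man, seed = 8)
  for (cl in class_levels()) {
    n_cl <- sum(sp$class == cl)
    frac <- table(sp$split[sp$class == cl]) / n_cl
    expect_true(all(abs(frac[c("train", "val", "test")] -
                          c(0.8, 0.1, 0.1)) <= 3 / n_cl))
  }
  # deterministic in (records, fractions, seed)
  expect_identical(sp, patient_stratified_split(man, seed = 8))
})

test_that("patients spanning two classes are an integrity error", {
  man <- single_image_manifest(5)
  man$patient_id[1] <- man$patient_id[6] # Normal patient also in Benign
  expect_error(patient_stratified_split(man), "more than one class")
})

test_that("augmentation tops up to the target, tags provenance, never removes", {
  spec <- synthetic_cohort_spec(patients_per_class = 6, image_side = 32,
                                separation = 0.8, seed = 14)
  ds <- generate_cohort(spec)
  keep <- ds$manifest$class != "Normal" | seq_len(nrow(ds$manifest)) %% 2 == 0
  ds <- list(images = ds$images[, , , keep, drop = FALSE],
             manifest = ds$manifest[keep, ])
  before <- table(ds$manifest$class)
  aug <- augment_to_balance(ds, augmentation_policy(), seed = 4)
  after <- table(aug$manifest$class)
  expect_true(all(after == max(before)))
  expect_equal(dim(aug$images)[4], nrow(aug$manifest))
  added <- aug$manifest[aug$manifest$augmented, ]
  expect_gt(nrow(added), 0)
  # provenance resolves and every augmented image differs from its source
  for (i in seq_len(nrow(added))) {
    src_idx <- match(added$source_image_id[i], aug$manifest$image_id)
    expect_false(is.na(src_idx))
    ai <- match(added$image_id[i], aug$manifest$image_id)
    expect_gt(mean(abs(aug$images[, , , ai] - aug$images[, , , src_idx])), 0)
  }
  # originals retained
  expect_true(all(ds$manifest$image_id %in% aug$manifest$image_id))
  # already balanced -> no-op
  again <- augment_to_balance(aug, augmentation_policy(), seed = 4)
  expect_equal(nrow(again$manifest), nrow(aug$manifest))
  # target below a current count warns
  expect_warning(
    augment_to_balance(ds, augmentation_policy(target_per_class = 2),
                       seed = 4),
    "below current count")
})

test_that("train-only augmentation keeps synthetic copies out of val/test", {
  spec <- synthetic_cohort_spec(patients_per_class = 8, image_side = 32,
                                separation = 0.8, seed = 15)
  ds <- generate_cohort(spec)
  ds$manifest <- patient_stratified_split(ds$manifest, seed = 2)
  splits <- split_dataset(ds)
  tr <- augment_to_balance(list(images = splits$train$x,
                                manifest = splits$train$manifest),
                           augmentation_policy(target_per_class = 30),
                           seed = 6)
  expect_true(any(tr$manifest$augmented))
  expect_false(any(splits$val$manifest$augmented))
  expect_false(any(splits$test$manifest$augmented))
  # leakage guard: every augmentation source lives in the train subset
  src <- tr$manifest$source_image_id[tr$manifest$augmented]
  expect_true(all(src %in% splits$train$manifest$image_id))
})

test_that("datasets round-trip through the PNG tree and manifest", {
  spec <- synthetic_cohort_spec(patients_per_class = 2, image_side = 32,
                                seed = 21)
  dir <- withr::local_tempdir()
  ds <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_image_dataset(dir, side = 32)
  expect_equal(back$manifest$image_id, ds$manifest$image_id)
  # 8-bit PNG quantization bounds the round-trip error
  expect_lt(max(abs(back$images - ds$images)), 1 / 255)
  expect_error(read_image_dataset(withr::local_tempdir()), "missing artifact")
})
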