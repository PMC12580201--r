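# Shared fixtures, built in code.

# A small, moderately separable synthetic cohort with patient-level splits,
# memoized per (patients, separation, seed) so several tests can share it.
.fixture_env <- new.env()

fixture_splits <- function(patients = 20, separation = 0.9, seed = 11,
                           split_seed = 3, side = 64) {
  key <- paste(patients, separation, seed, split_seed, side, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    spec <- synthetic_cohort_spec(patients_per_class = patients,
                                  image_side = side,
                                  separation = separation,
                                  noise_sd = 0.04, seed = seed)
    ds <- generate_cohort(spec)
    ds$manifest <- patient_stratified_split(ds$manifest, seed = split_seed)
    .fixture_env[[key]] <- split_dataset(ds)
  }
  .fixture_env[[key]]
}

# Plain manifest of single-image patients, for split arithmetic tests.
single_image_manifest <- function(per_class = 100) {
  do.call(rbind, lapply(class_levels(), function(cl) {
    data.frame(
      image_id = sprintf("%s_img%03d", tolower(cl), seq_len(per_class)),
      patient_id = sprintf("%s_p%03d", tolower(cl), seq_len(per_class)),
      plane = "axial", class = cl)
  }))
}

ref_extdata <- function(name) {
  path <- system.file("extdata", name, package = "whalenet")
  expect_true(nzchar(path))
  utils::read.csv(path, check.names = FALSE)
}

# Test-set accuracy of a probability matrix against integer labels.
proba_accuracy <- function(pm, y) mean(max.col(pm$probs) - 1L == y)
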