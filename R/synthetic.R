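#' Specification of a synthetic three-class imaging cohort
#'
#' Emulates the structure of a patient-grouped gynecological MRI dataset:
#' three diagnostic classes (Normal / Benign / Malignant), one class per
#' patient, and up to three acquisition planes (sagittal, coronal, axial)
#' per patient.  Images are grayscale-like RGB squares showing a smooth
#' elliptical "organ" on a dark background; the Benign class adds a
#' well-circumscribed bright blob, the Malignant class an irregular
#' high-frequency textured region, and the Normal class neither.  Lesion
#' contrast scales linearly with `separation`, so `separation = 0` makes
#' the three class-conditional distributions identical (chance-level
#' problem) and larger values make the classes progressively easier.
#' Each patient carries a random intensity offset shared by its planes, so
#' patient-level splitting is consequential.
#'
#' @param patients_per_class patients per class (>= 1).
#' @param planes subset of `c("sagittal", "coronal", "axial")`.
#' @param image_side image side in pixels (default 64; use 224 for
#'   full-scale runs).
#' @param separation class-separation strength in [0, 1].
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param seed integer seed; generation is bit-identical for identical
#'   specs.
#' @param images_per_class optional named/ordered triple of exact per-class
#'   image totals (overrides `patients_per_class`; patients then hold 3
#'   planes each, with one smaller remainder patient per class if needed).
#' @return a `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(patients_per_class = 10,
                                  planes = c("sagittal", "coronal", "axial"),
                                  image_side = 64, separation = 0.7,
                                  noise_sd = 0.05, seed = 1,
                                  images_per_class = NULL) {
  planes <- match.arg(planes, several.ok = TRUE)
  stopifnot(patients_per_class >= 1, image_side >= 16,
            image_side %% 8 == 0, separation >= 0, separation <= 1,
            noise_sd >= 0)
  if (!is.null(images_per_class)) stopifnot(length(images_per_class) == 3)
  structure(list(patients_per_class = as.integer(patients_per_class),
                 planes = planes, image_side = as.integer(image_side),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 images_per_class = images_per_class),
            class = "synthetic_cohort_spec")
}

#' The KAUH-like cohort preset
#'
#' Reproduces the per-class image totals of the reference uterine-MRI
#' cohort this generator emulates: 497 Normal, 699 Benign and 618
#' Malignant images (1,814 in total), organized as three-plane patients
#' with a final partial patient where a total is not divisible by three.
#'
#' @param image_side image side (default 64).
#' @param separation class separation (default 0.7).
#' @param noise_sd pixel noise (default 0.05).
#' @param seed integer seed.
#' @return a `synthetic_cohort_spec`.
#' @export
kauh_like_spec <- function(image_side = 64, separation = 0.7,
                           noise_sd = 0.05, seed = 1) {
  synthetic_cohort_spec(
    patients_per_class = 1, image_side = image_side,
    separation = separation, noise_sd = noise_sd, seed = seed,
    images_per_class = c(Normal = 497, Benign = 699, Malignant = 618))
}

#' Build the cohort manifest without generating pixels
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return data.frame with `image_id`, `patient_id`, `plane`, `class`,
#'   `path`, `augmented`, `source_image_id`.
#' @export
cohort_manifest <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  classes <- class_levels()
  rows <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    if (!is.null(spec$images_per_class)) {
      total <- as.integer(spec$images_per_class[[ci]])
      n_full <- total %/% 3L
      rem <- total %% 3L
      n_pat <- n_full + (rem > 0L)
      plane_counts <- c(rep(3L, n_full), if (rem > 0L) rem)
      plane_set <- c("sagittal", "coronal", "axial")
    } else {
      n_pat <- spec$patients_per_class
      plane_counts <- rep(length(spec$planes), n_pat)
      plane_set <- spec$planes
    }
    for (p in seq_len(n_pat)) {
      pid <- sprintf("%s_p%04d", tolower(substr(cl, 1, 3)), p)
      for (k in seq_len(plane_counts[p])) {
        plane <- plane_set[k]
        iid <- sprintf("%s_%s", pid, plane)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = iid, patient_id = pid, plane = plane, class = cl,
          path = file.path(cl, paste0(iid, ".png")),
          augmented = FALSE, source_image_id = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

# Pixel synthesis for one image.  All stochastic inputs are passed in so
# the caller controls the RNG stream layout (patient-level draws shared
# across planes, image-level draws fresh per image).
render_synthetic_image <- function(side, class, plane, patient, img_draws,
                                   separation, noise_sd) {
  ax <- seq(-1, 1, length.out = side)
  gx <- matrix(ax, side, side, byrow = TRUE)  # x varies along columns
  gy <- matrix(ax, side, side)                # y varies along rows
  # plane-dependent organ aspect: sagittal tall, coronal wide, axial round
  aspect <- switch(plane, sagittal = c(0.75, 0.5), coronal = c(0.5, 0.75),
                   axial = c(0.62, 0.62))
  a <- aspect[1] * (1 + patient$shape_jit[1])
  b <- aspect[2] * (1 + patient$shape_jit[2])
  r2 <- (gx / a)^2 + (gy / b)^2
  organ <- (0.42 + patient$offset) * exp(-r2^1.6) # smooth elliptical organ
  img <- 0.06 + organ
  if (class == "Benign") {
    # well-circumscribed bright blob: sharp-edged super-Gaussian profile
    amp <- 0.6 * separation
    r_b <- 0.14 + 0.10 * img_draws$u1
    bx <- 0.45 * a * cos(2 * pi * img_draws$u2)
    by <- 0.45 * b * sin(2 * pi * img_draws$u2)
    rb2 <- ((gx - bx)^2 + (gy - by)^2) / r_b^2
    img <- img + amp * exp(-rb2^2)
  } else if (class == "Malignant") {
    # irregular textured region: lobulated boundary, high-frequency interior
    amp <- 0.5 * separation
    r_m <- 0.20 + 0.12 * img_draws$u1
    mx <- 0.35 * a * cos(2 * pi * img_draws$u2)
    my <- 0.35 * b * sin(2 * pi * img_draws$u2)
    theta <- atan2(gy - my, gx - mx)
    wobble <- 1 + 0.35 * sin(5 * theta + 2 * pi * img_draws$u3) +
      0.2 * sin(9 * theta + 2 * pi * img_draws$u4)
    rr <- sqrt((gx - mx)^2 + (gy - my)^2)
    inside <- rr < r_m * wobble
    k1 <- 18 + 10 * img_draws$u3
    k2 <- 22 + 10 * img_draws$u4
    texture <- sin(k1 * gx + 2 * pi * img_draws$u5) *
      sin(k2 * gy + 2 * pi * img_draws$u6)
    img <- img + amp * inside * (0.45 + 0.55 * abs(texture))
  }
  img <- array(rep(img, 3L), c(side, side, 3L))
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(side * side * 3L, 0, noise_sd),
                       c(side, side, 3L))
  }
  clamp(img, 0, 1)
}

#' Generate a synthetic cohort
#'
#' Renders every image of the cohort described by `spec`; with `dir` set,
#' also writes the directory-per-class PNG tree plus `manifest.csv` in the
#' same format [read_image_dataset()] consumes.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir optional output directory.
#' @return (invisibly when writing) a dataset list with `images`
#'   (side, side, 3, N array in [0,1]) and `manifest`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  man <- cohort_manifest(spec)
  side <- spec$image_side
  images <- array(0, c(side, side, 3L, nrow(man)))
  withr::with_seed(spec$seed, {
    patients <- unique(man$patient_id)
    patient_fx <- lapply(patients, function(p) {
      list(offset = stats::runif(1, -0.06, 0.06),
           shape_jit = stats::runif(2, -0.12, 0.12))
    })
    names(patient_fx) <- patients
    for (i in seq_len(nrow(man))) {
      draws <- list(u1 = stats::runif(1), u2 = stats::runif(1),
                    u3 = stats::runif(1), u4 = stats::runif(1),
                    u5 = stats::runif(1), u6 = stats::runif(1))
      images[, , , i] <- render_synthetic_image(
        side, man$class[i], man$plane[i], patient_fx[[man$patient_id[i]]],
        draws, spec$separation, spec$noise_sd)
    }
  })
  dataset <- list(images = images, manifest = man)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cl in unique(man$class)) {
      dir.create(file.path(dir, cl), showWarnings = FALSE)
    }
    for (i in seq_len(nrow(man))) {
      png::writePNG(images[, , , i], file.path(dir, man$path[i]))
    }
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    return(invisible(dataset))
  }
  dataset
}
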