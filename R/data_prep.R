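#' Standard class-label order
#'
#' The fixed three-class label encoding used throughout the package:
#' Normal = 0, Benign = 1, Malignant = 2.
#'
#' @return `c("Normal", "Benign", "Malignant")`.
#' @export
class_levels <- function() c("Normal", "Benign", "Malignant")

#' Encode a class name as an integer index
#' @param name one or more of "Normal", "Benign", "Malignant".
#' @return integer codes (Normal 0, Benign 1, Malignant 2).
#' @export
encode_label <- function(name) {
  m <- match(as.character(name), class_levels())
  if (anyNA(m)) {
    stop("unknown class label(s): ",
         paste(unique(name[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  m - 1L
}

#' Decode integer indices back to class names
#' @param index integer codes in 0..2.
#' @return character class names.
#' @export
decode_label <- function(index) {
  if (any(index < 0 | index > 2)) stop("index outside 0..2", call. = FALSE)
  class_levels()[as.integer(index) + 1L]
}

#' Preprocess a raw image
#'
#' Resizes to `side` x `side` with bilinear interpolation and rescales
#' intensities from the native 0-255 range to [0,1].  Accepts a file path
#' (PNG/JPEG, read via EBImage) or a numeric array on the 0-255 scale with
#' shape (H, W), (H, W, 1) or (H, W, 3); grayscale input is replicated to
#' three channels.
#'
#' @param x file path or raw pixel array (values 0-255).
#' @param side output side in pixels (default 224).
#' @return array (side, side, 3) with values in [0,1].
#' @export
preprocess_image <- function(x, side = 224) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read image file: ", x, call. = FALSE)
    img <- tryCatch(EBImage::imageData(EBImage::readImage(x)),
                    error = function(e) {
                      stop("cannot read image file: ", x, " (",
                           conditionMessage(e), ")", call. = FALSE)
                    })
    # EBImage stores (x, y, channel); convert to row-major (H, W, channel)
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
    img <- img * 255 # readImage scales to [0,1]; restore the raw scale
  } else {
    img <- x
  }
  img <- as.array(img)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] != 3L) {
    stop("expected 1 or 3 channels, got ", dim(img)[3], call. = FALSE)
  }
  if (dim(img)[1] != side || dim(img)[2] != side) {
    # EBImage::resize uses bilinear filtering by default
    img <- EBImage::imageData(EBImage::resize(
      EBImage::Image(img, colormode = "Color"), w = side, h = side))
  }
  clamp(img / 255, 0, 1)
}

#' Patient-level stratified train/validation/test split
#'
#' Patients are atomic: all images of a patient land in one subset, so no
#' identity leaks across subsets.  Within each class, patients are shuffled
#' by `seed` and allocated greedily to the subset with the largest
#' remaining image-count deficit relative to the target fractions, which
#' hits the targets as closely as patient atomicity allows (exactly, when
#' every patient contributes one image).
#'
#' @param manifest data.frame with columns `image_id`, `patient_id`,
#'   `class` (and any others, preserved).
#' @param fractions named numeric vector `c(train=, val=, test=)`
#'   summing to 1.
#' @param seed integer seed; the split is deterministic in
#'   (manifest, fractions, seed).
#' @return the manifest with an added `split` column
#'   ("train"/"val"/"test").
#' @export
patient_stratified_split <- function(manifest,
                                     fractions = c(train = 0.8, val = 0.1,
                                                   test = 0.1),
                                     seed = 1) {
  stopifnot(all(c("image_id", "patient_id", "class") %in% names(manifest)),
            abs(sum(fractions) - 1) < 1e-9,
            all(c("train", "val", "test") %in% names(fractions)))
  pc <- unique(manifest[, c("patient_id", "class")])
  dup <- pc$patient_id[duplicated(pc$patient_id)]
  if (length(dup)) {
    stop("patient(s) with records in more than one class: ",
         paste(utils::head(unique(dup), 5), collapse = ", "), call. = FALSE)
  }
  manifest$split <- NA_character_
  subsets <- c("train", "val", "test")
  withr::with_seed(seed, {
    for (cl in unique(manifest$class)) {
      rows <- manifest$class == cl
      counts <- table(manifest$patient_id[rows])
      patients <- sample(names(counts))
      n_images <- sum(counts)
      target <- fractions[subsets] * n_images
      filled <- stats::setNames(numeric(3), subsets)
      assign_to <- character(length(patients))
      for (i in seq_along(patients)) {
        deficit <- target - filled
        pick <- subsets[which.max(deficit)]
        assign_to[i] <- pick
        filled[pick] <- filled[pick] + counts[[patients[i]]]
      }
      map <- stats::setNames(assign_to, patients)
      manifest$split[rows] <- map[manifest$patient_id[rows]]
    }
  })
  manifest
}

#' Augmentation policy
#'
#' @param shear maximum shear intensity (default 0.2).
#' @param zoom maximum relative zoom in/out (default 0.2).
#' @param horizontal_flip allow random horizontal flips (default TRUE).
#' @param target_per_class per-class image count to top up to; `NULL`
#'   means "the largest current class count".
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(shear = 0.2, zoom = 0.2,
                                horizontal_flip = TRUE,
                                target_per_class = NULL) {
  stopifnot(shear >= 0, zoom >= 0)
  structure(list(shear = shear, zoom = zoom,
                 horizontal_flip = horizontal_flip,
                 target_per_class = target_per_class),
            class = "augmentation_policy")
}

# Bilinear affine warp about the image center.  A maps output pixel
# coordinates to input sample coordinates; out-of-range samples clamp to
# the border.  Used for the shear/zoom/flip augmentations.
affine_warp <- function(img, A) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  sy <- A[1, 1] * gy + A[1, 2] * gx + cy
  sx <- A[2, 1] * gy + A[2, 2] * gx + cx
  sy <- clamp(sy, 1, H)
  sx <- clamp(sx, 1, W)
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  wy <- sy - y0; wx <- sx - x0
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    v00 <- plane[cbind(y0, x0)]
    v10 <- plane[cbind(y0 + 1L, x0)]
    v01 <- plane[cbind(y0, x0 + 1L)]
    v11 <- plane[cbind(y0 + 1L, x0 + 1L)]
    out[, , ch] <- (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
      (1 - wy) * wx * v01 + wy * wx * v11
  }
  out
}

# One random augmented copy: shear ~ U(-shear, shear), zoom factor
# ~ U(1 - zoom, 1 + zoom), horizontal flip with probability 1/2.  Draws
# come from the current RNG stream (callers seed it).
augment_image <- function(img, policy) {
  sh <- stats::runif(1, -policy$shear, policy$shear)
  zm <- stats::runif(1, 1 - policy$zoom, 1 + policy$zoom)
  fl <- policy$horizontal_flip && stats::runif(1) < 0.5
  # output->input mapping: inverse zoom, inverse shear (x' = x + sh*y),
  # then optional x mirror
  A <- matrix(c(1 / zm, 0, -sh / zm, 1 / zm), 2, 2, byrow = TRUE)
  if (fl) A[, 2] <- -A[, 2]
  affine_warp(img, A)
}

#' Top up under-represented classes by augmentation
#'
#' Adds transformed copies (shear, zoom, horizontal flip) of randomly
#' chosen source images to every class below `target_per_class`, tagging
#' each copy with `augmented = TRUE` and the id of its source image.
#' Originals are never removed; classes at or above the target are left
#' untouched (with a warning when the target is below a current count).
#' Intended for the training subset only — keeping augmented copies out of
#' validation/test is assertable from the provenance tags.
#'
#' @param dataset an image dataset: list with `images` (S, S, 3, N array)
#'   and `manifest` (data.frame with `image_id`, `class`, ...).
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @return the dataset with augmented records appended; the manifest gains
#'   `augmented` and `source_image_id` columns.
#' @export
augment_to_balance <- function(dataset, policy = augmentation_policy(),
                               seed = 1) {
  man <- dataset$manifest
  if (is.null(man$augmented)) man$augmented <- FALSE
  if (is.null(man$source_image_id)) man$source_image_id <- NA_character_
  counts <- table(man$class)
  target <- policy$target_per_class %||% max(counts)
  if (any(counts > target)) {
    warning("target_per_class (", target, ") below current count for: ",
            paste(names(counts)[counts > target], collapse = ", "),
            "; those classes are left as-is")
  }
  new_imgs <- list()
  new_rows <- list()
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need <= 0) next
      src_rows <- which(man$class == cl & !man$augmented)
      picks <- src_rows[(seq_len(need) - 1L) %% length(src_rows) + 1L]
      picks <- sample(picks) # vary pairing of copy index and source
      for (k in seq_len(need)) {
        src <- picks[k]
        img <- dataset$images[, , , src]
        new_imgs[[length(new_imgs) + 1L]] <- augment_image(img, policy)
        row <- man[src, ]
        row$image_id <- sprintf("%s_aug%03d", man$image_id[src], k)
        row$augmented <- TRUE
        row$source_image_id <- man$image_id[src]
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  })
  if (length(new_imgs)) {
    d <- dim(dataset$images)
    add <- array(unlist(new_imgs, use.names = FALSE),
                 dim = c(d[1], d[2], d[3], length(new_imgs)))
    combined <- array(0, c(d[1], d[2], d[3], d[4] + length(new_imgs)))
    combined[, , , seq_len(d[4])] <- dataset$images
    combined[, , , d[4] + seq_along(new_imgs)] <- add
    dataset$images <- combined
    man <- rbind(man, do.call(rbind, new_rows))
  }
  dataset$manifest <- man
  dataset
}

#' Slice a dataset by the split column into model-ready pieces
#'
#' @param dataset list with `images` (S, S, 3, N) and `manifest` carrying a
#'   `split` column.
#' @return list of `train` / `val` / `test`, each with `x` (image array),
#'   `y` (integer labels) and `manifest`.
#' @export
split_dataset <- function(dataset) {
  man <- dataset$manifest
  stopifnot(!is.null(man$split))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    idx <- which(man$split == s)
    list(x = dataset$images[, , , idx, drop = FALSE],
         y = encode_label(man$class[idx]),
         manifest = man[idx, , drop = FALSE])
  })
  out
}

#' Load an image dataset from a directory tree and manifest
#'
#' The manifest CSV carries `image_id`, `patient_id`, `plane`, `class` and
#' `path` (relative to `dir`); every image is preprocessed to
#' (`side`, `side`, 3) in [0,1].
#'
#' @param dir dataset root directory.
#' @param side target image side.
#' @param manifest_file manifest CSV name within `dir`.
#' @return list with `images` and `manifest`.
#' @export
read_image_dataset <- function(dir, side = 64,
                               manifest_file = "manifest.csv") {
  man_path <- file.path(dir, manifest_file)
  require_artifact(man_path, "whalenet synth (or point --data at a dataset)")
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "patient_id", "plane", "class", "path") %in%
                  names(man)))
  images <- array(0, c(side, side, 3L, nrow(man)))
  for (i in seq_len(nrow(man))) {
    images[, , , i] <- preprocess_image(file.path(dir, man$path[i]), side)
  }
  list(images = images, manifest = man)
}
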