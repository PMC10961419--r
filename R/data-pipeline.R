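# Dataset manifest handling, the stratified 8:2 split, per-class
# augmentation expansion, and robustness perturbations.
#
# Images are numeric arrays dim c(H, W, 3) on the 0-255 scale; folders use a
# class-per-subdirectory layout with a CSV manifest.

#' Reference 22-class leaf disease manifest
#'
#' The per-class record of a 22-class, 6-crop field leaf-disease dataset:
#' class code, crop group, original and augmented training counts, test
#' count, and the integer augmentation expansion factor
#' (`n_augmented = factor * n_original` for every class).
#'
#' @return data frame with columns crop, class_name, class_code, n_original,
#'   n_augmented, n_test, factor.
#' @export
leaf_disease_manifest <- function() {
  m <- data.frame(
    crop = c(rep("Apple", 7), rep("Bean", 3), rep("Maize", 4),
             rep("Strawberry", 2), rep("Sugarcane", 3), rep("Wheat", 3)),
    class_name = c("Alternaria leaf spot", "Grey spot", "Health", "Mosaic",
                   "Powdery mildew", "Rust", "Scab",
                   "Angular leaf spot", "Bean rust", "Healthy",
                   "Gray Leaf Spot", "Health", "Northern leaf blight",
                   "Northern leaf spot",
                   "Calciumdeficieny", "Healthy",
                   "Bacterial blight", "Healthy", "Red rot",
                   "Powdery mildew", "Smut", "Rust"),
    class_code = c("A1", "A2", "A3", "A4", "A5", "A6", "A7",
                   "B1", "B2", "B3", "M1", "M2", "M3", "M4",
                   "S1", "S2", "SU1", "SU2", "SU3", "W1", "W2", "W3"),
    n_original = c(219L, 131L, 516L, 137L, 549L, 447L, 477L,
                   264L, 264L, 264L, 398L, 265L, 419L, 441L,
                   378L, 369L, 80L, 80L, 80L, 208L, 330L, 416L),
    n_augmented = c(1095L, 1048L, 1032L, 1096L, 1098L, 894L, 954L,
                    1056L, 1056L, 1056L, 1194L, 1060L, 1257L, 882L,
                    1134L, 1107L, 640L, 640L, 640L, 1040L, 990L, 1248L),
    n_test = c(54L, 32L, 129L, 34L, 137L, 111L, 119L,
               66L, 66L, 66L, 99L, 66L, 104L, 110L,
               94L, 92L, 20L, 20L, 20L, 51L, 82L, 104L),
    stringsAsFactors = FALSE)
  m$factor <- m$n_augmented %/% m$n_original
  stopifnot(all(m$factor * m$n_original == m$n_augmented))
  m
}

#' Read / write a dataset manifest CSV
#'
#' @param manifest a manifest data frame (see [leaf_disease_manifest()]).
#' @param path CSV file path.
#' @return `read_manifest()`: the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  int_cols <- intersect(c("n_original", "n_augmented", "n_test", "factor"),
                        names(m))
  for (cc in int_cols) m[[cc]] <- as.integer(m[[cc]])
  m
}

#' Stratified train/test split
#'
#' Per class, `floor(test_ratio * n)` items are drawn uniformly at random
#' (under `seed`) into the test set; the remainder form the training set.
#' Train and test are disjoint and exhaustive within every class.
#'
#' @param class_items named list; one vector of items per class.
#' @param test_ratio fraction of each class reserved for testing (default
#'   0.2, the 8:2 split).
#' @param seed integer seed for the random selection.
#' @return list with named lists `train` and `test`.
#' @examples
#' s <- split_dataset(list(a = 1:273), 0.2, seed = 1)
#' lengths(s$test)  # 54
#' @export
split_dataset <- function(class_items, test_ratio = 0.2, seed = 1L) {
  if (test_ratio <= 0 || test_ratio >= 1) stop("test_ratio must be in (0, 1)")
  if (any(lengths(class_items) == 0L)) stop("empty class")
  set.seed(seed)
  train <- list(); test <- list()
  for (cls in names(class_items)) {
    items <- class_items[[cls]]
    n_test <- floor(test_ratio * length(items))
    ti <- if (n_test > 0) sample(seq_along(items), n_test) else integer(0)
    test[[cls]] <- items[sort(ti)]
    train[[cls]] <- if (n_test > 0) items[-ti] else items
  }
  list(train = train, test = test)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j > (n - 1L), p - j, j) + 1L
}

#' Rotate an image about its centre
#'
#' Bilinear inverse-mapped rotation with reflective boundary fill, so no
#' artificial constant-colour corners are introduced.  Dimensions are
#' preserved.
#'
#' @param img array `c(H, W, 3)` on the 0-255 scale.
#' @param angle rotation angle in degrees (counter-clockwise).
#' @return the rotated image, same dimensions.
#' @export
rotate_image <- function(img, angle) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  a <- angle * pi / 180
  # exact 90-degree multiples stay lossless permutations
  if (isTRUE(all.equal(angle %% 360, 0))) return(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep(seq_len(H), times = W) - cy
  c0 <- rep(seq_len(W), each = H) - cx
  sy <- cos(a) * r - sin(a) * c0 + cy
  sx <- sin(a) * r + cos(a) * c0 + cx
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0;   wx <- sx - x0
  iy0 <- reflect_index(as.integer(y0), H); iy1 <- reflect_index(as.integer(y0) + 1L, H)
  ix0 <- reflect_index(as.integer(x0), W); ix1 <- reflect_index(as.integer(x0) + 1L, W)
  out <- array(0, dim = d)
  for (ch in 1:3) {
    m <- img[, , ch]
    v <- (1 - wy) * (1 - wx) * m[cbind(iy0, ix0)] +
         (1 - wy) * wx       * m[cbind(iy0, ix1)] +
         wy       * (1 - wx) * m[cbind(iy1, ix0)] +
         wy       * wx       * m[cbind(iy1, ix1)]
    out[, , ch] <- matrix(v, H, W)
  }
  clip255(out)
}

#' Single augmentation operation
#'
#' Label- and dimension-preserving photometric/geometric edits: brightness
#' scaling with clipping to `[0, 255]`, centre rotation with reflective
#' fill, and exact mirror flips.
#'
#' @param img array `c(H, W, 3)`, 0-255 scale.
#' @param op one of `"brighten"`, `"darken"`, `"rotate"`, `"flip"`.
#' @param factor brightness multiplier (defaults: 1.3 brighten, 0.7 darken).
#' @param angle rotation angle in degrees (rotate only).
#' @param direction `"horizontal"` or `"vertical"` (flip only).
#' @return the augmented image, same dimensions.
#' @export
augment_image <- function(img, op, factor = NULL, angle = 90,
                          direction = "horizontal") {
  op <- match.arg(op, c("brighten", "darken", "rotate", "flip"))
  switch(op,
    brighten = clip255(img * (if (is.null(factor)) 1.3 else factor)),
    darken   = clip255(img * (if (is.null(factor)) 0.7 else factor)),
    rotate   = rotate_image(img, angle),
    flip     = {
      if (direction == "horizontal") img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
      else img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
    })
}

# the cyclic augmentation plan: brightness up/down, right-angle rotations,
# flips, and free rotation within +/- 30 degrees
augmentation_ops <- function() {
  list(
    function(img, rng_angle) augment_image(img, "brighten", factor = 1.3),
    function(img, rng_angle) augment_image(img, "darken", factor = 0.7),
    function(img, rng_angle) augment_image(img, "rotate", angle = 90),
    function(img, rng_angle) augment_image(img, "rotate", angle = 180),
    function(img, rng_angle) augment_image(img, "rotate", angle = 270),
    function(img, rng_angle) augment_image(img, "flip", direction = "horizontal"),
    function(img, rng_angle) augment_image(img, "flip", direction = "vertical"),
    function(img, rng_angle) augment_image(img, "rotate", angle = rng_angle))
}

#' Expand one class's training images by its augmentation factor
#'
#' Every original image yields exactly `factor` outputs: the original plus
#' `factor - 1` augmented variants, chosen by deterministically cycling over
#' the augmentation plan with an offset given by the image index under the
#' run seed.
#'
#' @param images list of `c(H, W, 3)` arrays of one class.
#' @param factor integer expansion factor (>= 1).
#' @param seed integer run seed.
#' @return list of `length(images) * factor` images, originals first within
#'   each image's block.
#' @export
expand_class_images <- function(images, factor, seed = 1L) {
  if (factor < 1L) stop("expansion factor must be >= 1")
  set.seed(seed)
  ops <- augmentation_ops()
  out <- vector("list", length(images) * factor)
  k <- 0L
  for (i in seq_along(images)) {
    k <- k + 1L
    out[[k]] <- images[[i]]
    for (j in seq_len(factor - 1L)) {
      op_idx <- ((i - 1L + j - 1L) %% length(ops)) + 1L
      k <- k + 1L
      out[[k]] <- ops[[op_idx]](images[[i]], rng_angle = runif(1, -30, 30))
    }
  }
  out
}

#' Expand a full training set according to its manifest
#'
#' @param manifest manifest data frame with `class_code` and `factor`.
#' @param images_by_class named list (by class code) of image lists.
#' @param seed integer run seed.
#' @return named list of expanded image lists; per-class output counts equal
#'   `factor * n_images`.
#' @export
expand_training_set <- function(manifest, images_by_class, seed = 1L) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    code <- manifest$class_code[i]
    if (is.null(images_by_class[[code]])) next
    out[[code]] <- expand_class_images(images_by_class[[code]],
                                       manifest$factor[i],
                                       seed = seed + i)
  }
  out
}

#' Robustness perturbation specification
#'
#' @param kind `"gaussian_noise"`, `"rotate"` or `"brightness"`.
#' @param sigma noise standard deviation on the 0-255 scale (default 25).
#' @param angle rotation angle in degrees (default 15).
#' @param factor brightness multiplier (default 0.6; 1.4 for the increase
#'   treatment).
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind, sigma = 25, angle = 15, factor = 0.6) {
  kind <- match.arg(kind, c("gaussian_noise", "rotate", "brightness"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (factor <= 0) stop("brightness factor must be > 0")
  structure(list(kind = kind, sigma = sigma, angle = angle, factor = factor),
            class = "perturbation_spec")
}

#' Apply a robustness perturbation
#'
#' Gaussian noise adds i.i.d. `N(0, sigma^2)` per channel (clipped to
#' `[0, 255]`); rotation and brightness reuse the augmentation operators.
#' Dimensions are always preserved and the result is deterministic under
#' `seed`.
#'
#' @param img array `c(H, W, 3)`, 0-255 scale.
#' @param spec a [perturbation_spec()].
#' @param seed integer seed (noise only).
#' @return the perturbed image.
#' @export
perturb_image <- function(img, spec, seed = 1L) {
  stopifnot(inherits(spec, "perturbation_spec"))
  switch(spec$kind,
    gaussian_noise = {
      if (spec$sigma == 0) return(img)
      set.seed(seed)
      clip255(img + array(rnorm(length(img), sd = spec$sigma), dim = dim(img)))
    },
    rotate = rotate_image(img, spec$angle),
    brightness = clip255(img * spec$factor))
}

# -- folder I/O -------------------------------------------------------------

#' Write / load a class-per-subdirectory PNG image folder
#'
#' Layout: `root/<class_code>/<stem>_NNN.png`; filenames never carry label
#' information beyond the directory.
#'
#' @param images_by_class named list (class code) of image lists
#'   (`c(H, W, 3)`, 0-255).
#' @param root folder root.
#' @param classes optional subset of class codes to load.
#' @return `load_image_folder()`: list with `images_by_class` and `classes`.
#' @export
write_image_folder <- function(images_by_class, root) {
  for (cls in names(images_by_class)) {
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    imgs <- images_by_class[[cls]]
    for (i in seq_along(imgs))
      png::writePNG(imgs[[i]] / 255,
                    file.path(root, cls, sprintf("img_%04d.png", i)))
  }
  invisible(root)
}

#' @rdname write_image_folder
#' @export
load_image_folder <- function(root, classes = NULL) {
  if (is.null(classes))
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  images_by_class <- lapply(classes, function(cls) {
    files <- sort(list.files(file.path(root, cls), pattern = "\\.png$",
                             full.names = TRUE))
    lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
      a[, , 1:3, drop = FALSE] * 255
    })
  })
  names(images_by_class) <- classes
  list(images_by_class = images_by_class, classes = classes)
}

#' Stack a list of images into a network input batch
#'
#' Converts `c(H, W, 3)` images (0-255) into the channel-first activation
#' layout `c(3, H, W, N)`.
#'
#' @param images list of equally sized images.
#' @param labels optional integer labels (1-based).
#' @return list with `x` (the batch array) and `y` (labels, if given).
#' @export
images_to_batch <- function(images, labels = NULL) {
  d <- dim(images[[1L]])
  x <- array(0, dim = c(3L, d[1L], d[2L], length(images)))
  for (i in seq_along(images)) x[, , , i] <- aperm(images[[i]], c(3L, 1L, 2L))
  out <- list(x = x)
  if (!is.null(labels)) out$y <- as.integer(labels)
  out
}
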