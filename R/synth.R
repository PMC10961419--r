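# Deterministic generator of leaf-disease-like image datasets.
#
# Each image is a cluttered background, an elliptical green leaf, and
# class-specific lesion spots (count, radius and colour drawn from per-class
# ranges).  The class signal lives ONLY in the lesions: background and leaf
# statistics are drawn from the same distribution for every class, so a
# classifier can only succeed by reading the spots.

#' Synthetic dataset specification
#'
#' Defines the class structure and rendering parameters of a synthetic
#' leaf-disease dataset.  The default is 4 classes — healthy (no spots) plus
#' three lesion types differing in spot count, radius and hue — with 100
#' training and 25 test images per class at 64 px.  `"easy"` uses disjoint
#' lesion parameter ranges; `"hard"` overlaps them so classes are genuinely
#' confusable.
#'
#' @param n_classes 2 to 4 (classes are taken in order from the palette).
#' @param n_train,n_test images per class.
#' @param image_size square image side in pixels (divisible by 4).
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed integer seed; identical spec + seed regenerates bit-identical
#'   images.
#' @return object of class `synth_spec` with a per-class parameter table
#'   (spot count range, radius range as a fraction of image size, RGB spot
#'   colour).
#' @export
synth_spec <- function(n_classes = 4L, n_train = 100L, n_test = 25L,
                       image_size = 64L, difficulty = c("easy", "hard"),
                       seed = 0L) {
  difficulty <- match.arg(difficulty)
  if (n_train < 1L || n_test < 1L) stop("images_per_class must be >= 1")
  if (n_classes < 2L || n_classes > 4L) stop("n_classes must be in 2..4")
  if (image_size %% 4L != 0L) stop("image_size must be divisible by 4")
  classes <- if (difficulty == "easy") data.frame(
    name = c("healthy", "brown_spot", "dark_speck", "yellow_blotch"),
    spot_min = c(0L, 3L, 12L, 2L),
    spot_max = c(0L, 5L, 18L, 4L),
    r_min = c(0, 0.06, 0.020, 0.09),
    r_max = c(0, 0.09, 0.032, 0.13),
    col_r = c(NA, 139, 45, 230),
    col_g = c(NA, 69, 35, 200),
    col_b = c(NA, 19, 30, 60)
  ) else data.frame(
    name = c("healthy", "brown_spot", "dark_speck", "yellow_blotch"),
    spot_min = c(0L, 2L, 4L, 2L),
    spot_max = c(0L, 8L, 10L, 8L),
    r_min = c(0, 0.04, 0.030, 0.04),
    r_max = c(0, 0.08, 0.060, 0.08),
    col_r = c(NA, 120, 95, 150),
    col_g = c(NA, 80, 70, 120),
    col_b = c(NA, 40, 45, 55)
  )
  structure(list(n_classes = as.integer(n_classes),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 image_size = as.integer(image_size),
                 difficulty = difficulty, seed = as.integer(seed),
                 classes = classes[seq_len(n_classes), , drop = FALSE]),
            class = "synth_spec")
}

#' Render one synthetic leaf image
#'
#' Draws a textured cluttered background, an elliptical leaf with jittered
#' pose and green texture, and `spot_min..spot_max` lesion disks whose
#' centres are placed so every spot lies entirely inside the leaf ellipse.
#' Consumes the current R random number stream: seed the RNG before calling
#' for reproducible output.
#'
#' @param class_row one row of the `classes` table of a [synth_spec()].
#' @param image_size square image side in pixels.
#' @return image array `c(image_size, image_size, 3)` on the 0-255 scale,
#'   with attribute `"leaf_mask"` (logical matrix of in-leaf pixels).
#' @export
render_leaf_image <- function(class_row, image_size = 64L) {
  S <- image_size
  yy <- matrix(rep(seq_len(S), times = S), S, S)
  xx <- matrix(rep(seq_len(S), each = S), S, S)

  # background: brownish base + smooth colour blobs + grain (class-independent)
  img <- array(0, dim = c(S, S, 3))
  base <- c(105, 95, 70)
  blob_field <- array(0, dim = c(S, S, 3))
  for (bl in 1:6) {
    bx <- runif(1, 1, S); by <- runif(1, 1, S)
    sg <- runif(1, 0.10, 0.25) * S
    amp <- runif(3, -45, 45)
    g <- exp(-((yy - by)^2 + (xx - bx)^2) / (2 * sg^2))
    for (ch in 1:3) blob_field[, , ch] <- blob_field[, , ch] + amp[ch] * g
  }
  for (ch in 1:3)
    img[, , ch] <- base[ch] + blob_field[, , ch] +
      matrix(rnorm(S * S, sd = 8), S, S)

  # leaf ellipse with jittered pose
  cy <- S / 2 + runif(1, -0.05, 0.05) * S
  cx <- S / 2 + runif(1, -0.05, 0.05) * S
  a <- runif(1, 0.30, 0.40) * S   # semi-major
  b <- runif(1, 0.22, 0.30) * S   # semi-minor
  th <- runif(1, 0, pi)
  u <- cos(th) * (yy - cy) + sin(th) * (xx - cx)
  v <- -sin(th) * (yy - cy) + cos(th) * (xx - cx)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  leaf_col <- c(60, 140, 55)
  vein <- 12 * sin(2 * pi * u / (0.5 * S))
  for (ch in 1:3) {
    tex <- leaf_col[ch] + vein + matrix(rnorm(S * S, sd = 10), S, S)
    m <- img[, , ch]
    m[mask] <- tex[mask]
    img[, , ch] <- m
  }

  # class-specific lesion spots, fully inside the ellipse
  n_spots <- if (class_row$spot_max > 0)
    sample(class_row$spot_min:class_row$spot_max, 1L) else 0L
  if (n_spots > 0L) {
    if (class_row$r_max * S > b)
      stop("lesion radius exceeds the leaf minor axis")
    col <- c(class_row$col_r, class_row$col_g, class_row$col_b)
    for (sp in seq_len(n_spots)) {
      r <- runif(1, class_row$r_min, class_row$r_max) * S
      margin <- r / min(a, b)
      rho <- sqrt(runif(1)) * max(0, 1 - margin)
      phi <- runif(1, 0, 2 * pi)
      py <- cy + cos(th) * (a * rho * cos(phi)) - sin(th) * (b * rho * sin(phi))
      px <- cx + sin(th) * (a * rho * cos(phi)) + cos(th) * (b * rho * sin(phi))
      dist <- sqrt((yy - py)^2 + (xx - px)^2)
      wgt <- pmin(pmax(1.5 * (1 - dist / r), 0), 1)
      jit <- runif(3, -15, 15)
      for (ch in 1:3)
        img[, , ch] <- (1 - wgt) * img[, , ch] + wgt * (col[ch] + jit[ch])
    }
  }
  out <- clip255(img)
  attr(out, "leaf_mask") <- mask
  out
}

#' Generate a synthetic leaf-disease dataset
#'
#' Renders the full train and test sets of a [synth_spec()] deterministically
#' under its seed, returns them as network-ready batches, and (optionally)
#' writes a class-per-subdirectory PNG folder plus a CSV manifest matching
#' the data-pipeline interface.  Train and test images are separate renders,
#' so the two sets are disjoint by construction.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory; when given, `train/` and `test/`
#'   folders and `manifest.csv` are written beneath it.
#' @return list with `train` and `test` (each `x` array `c(3, S, S, N)` and
#'   integer labels `y`), `classes` (names), `manifest`, and the resolved
#'   `spec`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  S <- spec$image_size
  render_split <- function(n_per_class) {
    imgs <- list(); labs <- integer(0)
    for (ci in seq_len(spec$n_classes)) {
      row <- spec$classes[ci, ]
      for (i in seq_len(n_per_class)) {
        imgs[[length(imgs) + 1L]] <- render_leaf_image(row, S)
        labs <- c(labs, ci)
      }
    }
    c(images_to_batch(imgs, labs), list(images = imgs))
  }
  tr <- render_split(spec$n_train)
  te <- render_split(spec$n_test)
  manifest <- data.frame(
    crop = "synthetic", class_name = spec$classes$name,
    class_code = sprintf("C%d", seq_len(spec$n_classes)),
    n_original = spec$n_train, n_augmented = spec$n_train,
    n_test = spec$n_test, factor = 1L, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    by_class <- function(split, n) split(split$images, rep(manifest$class_code, each = n))
    write_image_folder(by_class(tr, spec$n_train), file.path(dir, "train"))
    write_image_folder(by_class(te, spec$n_test), file.path(dir, "test"))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(train = list(x = tr$x, y = tr$y), test = list(x = te$x, y = te$y),
       classes = spec$classes$name, manifest = manifest, spec = spec)
}
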