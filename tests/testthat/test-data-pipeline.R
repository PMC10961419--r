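test_that("floor-based 8:2 split reproduces every manifest (train, test) pair", {
  man <- leaf_disease_manifest()
  # rebuild each class's full item list from original-train + test counts
  items <- lapply(seq_len(nrow(man)), function(i)
    seq_len(man$n_original[i] + man$n_test[i]))
  names(items) <- man$class_code
  sp <- split_dataset(items, test_ratio = 0.2, seed = 7)
  expect_identical(unname(lengths(sp$test)), man$n_test)
  expect_identical(unname(lengths(sp$train)), man$n_original)

  # partition property per class
  for (cls in man$class_code) {
    expect_identical(sort(c(sp$train[[cls]], sp$test[[cls]])), items[[cls]])
    expect_length(intersect(sp$train[[cls]], sp$test[[cls]]), 0)
  }
})

test_that("split arithmetic and validation", {
  sp <- split_dataset(list(a = 1:5), 0.2, seed = 1)
  expect_length(sp$test$a, 1)
  expect_length(sp$train$a, 4)
  expect_error(split_dataset(list(a = integer(0)), 0.2, 1), "empty")
  expect_error(split_dataset(list(a = 1:5), 0, 1), "ratio")
  expect_error(split_dataset(list(a = 1:5), 1, 1), "ratio")
  # seeded selection is reproducible
  expect_identical(split_dataset(list(a = 1:100), 0.2, 9),
                   split_dataset(list(a = 1:100), 0.2, 9))
})

test_that("augmentation operators are identity-, clip- and mirror-exact", {
  set.seed(30)
  img <- array(runif(16 * 16 * 3, 0, 255), dim = c(16, 16, 3))

  expect_equal(augment_image(img, "brighten", factor = 1.0), img)
  expect_equal(augment_image(augment_image(img, "flip"), "flip"), img)
  expect_equal(augment_image(augment_image(img, "flip", direction = "vertical"),
                             "flip", direction = "vertical"), img)

  px <- array(200, dim = c(2, 2, 3))
  expect_equal(augment_image(px, "brighten", factor = 1.3),
               array(255, dim = c(2, 2, 3)))

  rot <- augment_image(img, "rotate", angle = 17)
  expect_identical(dim(rot), dim(img))
  expect_true(all(rot >= 0 & rot <= 255))
  expect_equal(rotate_image(img, 360), img)
  expect_error(augment_image(img, "posterize"), "arg")
})

test_that("expansion produces exactly factor outputs per original", {
  set.seed(31)
  imgs <- replicate(5, array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3)),
                    simplify = FALSE)
  out <- expand_class_images(imgs, factor = 8L, seed = 1)
  expect_length(out, 40)
  expect_identical(out[[1]], imgs[[1]])        # original kept first
  expect_identical(expand_class_images(imgs, 1L, seed = 1), imgs)
  expect_error(expand_class_images(imgs, 0L), "factor")

  # manifest-driven expansion: counts equal the augmented column class by class
  man <- leaf_disease_manifest()
  sub <- man[man$class_code %in% c("SU1", "W2"), ]
  by_class <- list(SU1 = imgs[1:2], W2 = imgs[1:3])
  ex <- expand_training_set(sub, by_class, seed = 2)
  expect_length(ex$SU1, 2 * sub$factor[sub$class_code == "SU1"])  # factor 8
  expect_length(ex$W2, 3 * sub$factor[sub$class_code == "W2"])    # factor 3

  # full-manifest arithmetic: factors reproduce the augmented column exactly
  expect_identical(man$factor * man$n_original, man$n_augmented)
  expect_identical(sum(man$n_augmented), 22217L)
  expect_identical(sum(man$n_original), 6732L)
  expect_identical(sum(man$n_test), 1676L)
})

test_that("perturbations are dimension-preserving and seeded", {
  img <- array(128, dim = c(32, 32, 3))
  spec0 <- perturbation_spec("gaussian_noise", sigma = 0)
  expect_identical(perturb_image(img, spec0, seed = 1), img)

  spec <- perturbation_spec("gaussian_noise", sigma = 25)
  n1 <- perturb_image(img, spec, seed = 5)
  expect_identical(perturb_image(img, spec, seed = 5), n1)
  expect_identical(dim(n1), dim(img))
  # folded-normal mean absolute change ~ sigma * sqrt(2/pi) on mid-gray
  expect_equal(mean(abs(n1 - img)), 25 * sqrt(2 / pi), tolerance = 0.03)

  rot <- perturb_image(img, perturbation_spec("rotate", angle = 15), 1)
  expect_identical(dim(rot), dim(img))
  br <- perturb_image(img, perturbation_spec("brightness", factor = 1.4), 1)
  expect_equal(br, pmin(img * 1.4, 255))
  expect_error(perturbation_spec("gaussian_noise", sigma = -1), "sigma")
  expect_error(perturbation_spec("brightness", factor = 0), "factor")
})

test_that("manifest and image folders round-trip through disk", {
  man <- leaf_disease_manifest()
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  expect_identical(read_manifest(f), man)

  set.seed(32)
  imgs <- list(
    C1 = replicate(2, round(array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))),
                   simplify = FALSE),
    C2 = replicate(3, round(array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))),
                   simplify = FALSE))
  root <- file.path(tempfile(), "imgs")
  write_image_folder(imgs, root)
  got <- load_image_folder(root)
  expect_identical(got$classes, c("C1", "C2"))
  expect_length(got$images_by_class$C2, 3)
  expect_equal(got$images_by_class$C1[[1]], imgs$C1[[1]], tolerance = 1e-8)

  b <- images_to_batch(imgs$C1, labels = c(1, 1))
  expect_identical(dim(b$x), c(3L, 8L, 8L, 2L))
  expect_equal(b$x[, , , 1], aperm(imgs$C1[[1]], c(3, 1, 2)))
})
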