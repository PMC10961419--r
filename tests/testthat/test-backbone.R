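test_that("channel shuffle is the reshape-transpose permutation", {
  x <- array(rep(1:4, times = 4), dim = c(4, 2, 2, 1))
  expect_equal(as.vector(channel_shuffle(x, 2)[, 1, 1, 1]), c(1, 3, 2, 4))
  expect_equal(channel_shuffle(x, 1), x)                    # g = 1: identity
  expect_equal(channel_shuffle(channel_shuffle(x, 2), 2), x) # self-inverse when g = C/g
  expect_error(channel_shuffle(x, 3), "divisible")

  # bijectivity for all compatible (C, g)
  for (C in c(4, 6, 12, 24)) {
    for (g in c(2, 3, 4, 6)) {
      if (C %% g != 0) next
      perm <- leafcnn:::shuffle_permutation(C, g)
      expect_identical(sort(perm), seq_len(C))
      v <- rnorm(C)
      expect_identical(v[perm][order(perm)], v)  # shuffle then unshuffle
    }
  }
})

test_that("channel split and concat are exact inverses", {
  set.seed(1)
  x <- array(rnorm(96 * 2 * 2), dim = c(96, 2, 2, 1))
  halves <- channel_split(x)
  expect_identical(dim(halves[[1]])[1], 48L)
  expect_identical(leafcnn:::cat_channels(halves[[1]], halves[[2]]), x)
  expect_error(channel_split(array(0, c(3, 2, 2, 1))), "even")
})

test_that("units honour their shape contracts", {
  set.seed(2)
  cfg <- model_config(repeats = c(1, 1, 1), channels = c(8, 16, 32, 64),
                      attention = "edca", residual = "rm", num_classes = 4,
                      input_size = 16)
  bu <- leafcnn:::make_basic_unit(8L, cfg)
  x <- array(rnorm(8 * 6 * 6 * 2), dim = c(8, 6, 6, 2))
  expect_identical(dim(leafcnn:::nn_forward(bu, x)$y), c(8L, 6L, 6L, 2L))

  du <- leafcnn:::make_down_unit(8L, 16L, cfg)
  expect_identical(dim(leafcnn:::nn_forward(du, x)$y), c(16L, 3L, 3L, 2L))

  md <- leafcnn:::make_mdfem(8L)
  expect_identical(dim(leafcnn:::nn_forward(md, x)$y), dim(x))

  xi <- array(rnorm(3 * 16 * 16 * 2), dim = c(3, 16, 16, 2))
  for (kind in c("a", "b", "c", "msfem")) {
    st <- build_stem(kind)
    expect_identical(dim(leafcnn:::nn_forward(st, xi)$y), c(24L, 4L, 4L, 2L),
                     info = kind)
  }
})

test_that("plain basic unit equals manual composition of its primitives", {
  set.seed(3)
  cfg <- model_config(repeats = c(1, 1, 1), channels = c(8, 16, 32, 64),
                      attention = "none", residual = "none", num_classes = 4,
                      input_size = 16)
  bu <- leafcnn:::make_basic_unit(8L, cfg)
  x <- array(rnorm(8 * 5 * 5 * 2), dim = c(8, 5, 5, 2))
  got <- leafcnn:::nn_forward(bu, x)$y
  # oracle: split, run the right branch layer by layer, concat, shuffle
  halves <- channel_split(x)
  r <- halves[[2]]
  for (ly in bu$branch$children) r <- leafcnn:::nn_forward(ly, r)$y
  want <- channel_shuffle(leafcnn:::cat_channels(halves[[1]], r), 2)
  expect_equal(got, want)
})

test_that("zeroed branch with residual reduces to shuffle(concat(left, 0)) + x", {
  set.seed(4)
  cfg <- model_config(repeats = c(1, 1, 1), channels = c(8, 16, 32, 64),
                      attention = "none", residual = "rm", num_classes = 4,
                      input_size = 16)
  bu <- leafcnn:::make_basic_unit(8L, cfg)
  # force every branch conv weight and BN scale to zero
  for (i in seq_along(bu$branch$children)) {
    ly <- bu$branch$children[[i]]
    if (ly$type %in% c("conv", "dwconv")) ly$par$w[] <- 0
    if (ly$type == "bn") { ly$par$gamma[] <- 0; ly$par$beta[] <- 0 }
    bu$branch$children[[i]] <- ly
  }
  x <- array(rnorm(8 * 4 * 4 * 1), dim = c(8, 4, 4, 1))
  got <- leafcnn:::nn_forward(bu, x)$y
  halves <- channel_split(x)
  want <- channel_shuffle(leafcnn:::cat_channels(halves[[1]], halves[[2]] * 0), 2) + x
  expect_equal(got, want)
})

test_that("parameter accounting follows pooling-vs-convolution arithmetic", {
  p <- function(cfg) count_parameters(build_model(cfg, seed = 1))$total_params
  base <- function(res) p(model_config(repeats = c(2, 3, 2),
                                       channels = c(96, 192, 384, 1024),
                                       attention = "none", residual = res,
                                       stem = "a", mdfem = FALSE))
  # max-pool and average-pool shortcuts are parameter-free; a strided 3x3
  # convolution shortcut is not
  expect_identical(base("rm"), base("ra"))
  expect_lt(base("rm"), base("rc"))

  # stem accounting: 7x7 vs 3x3 differ by under 1e4 parameters; the
  # multi-scale stem is the largest, then the stacked-conv stem
  sp <- function(k) count_parameters(build_stem(k))$total_params
  expect_lt(abs(sp("b") - sp("a")), 1e4)
  expect_gt(sp("msfem"), sp("c"))
  expect_gt(sp("c"), sp("a"))

  # disabling the deep multi-scale block removes its parameters entirely
  cfg_on <- model_config(mdfem = TRUE); cfg_off <- model_config(mdfem = FALSE)
  m_on <- build_model(cfg_on, seed = 1)
  delta <- p(cfg_on) - p(cfg_off)
  expect_identical(delta, count_parameters(m_on)$per_component[["mdfem"]])

  # fully connected head example: 1024*22 + 22
  fc <- leafcnn:::layer_linear(1024L, 22L)
  expect_identical(leafcnn:::count_tree(leafcnn:::par_tree(fc)), 22550)

  # breakdown sums to total; fp32 bytes = 4x count
  rep <- count_parameters(build_model(tiny_leafnet_config(), seed = 1))
  expect_identical(sum(rep$per_component), rep$total_params)
  expect_identical(rep$fp32_bytes, 4 * rep$total_params)
})

test_that("attention toggling changes counts by exactly the kernel budget", {
  p <- function(cfg) count_parameters(build_model(cfg, seed = 1))$total_params
  cfgN <- model_config(attention = "none")
  cfgE <- model_config(attention = "edca")
  expected <- 0
  for (si in 1:3) {
    branch_ch <- cfgE$channels[si] %/% 2L
    n_units <- 1L + cfgE$repeats[si]
    expected <- expected + n_units * 2L * adaptive_kernel_size(branch_ch)
  }
  expect_identical(p(cfgE) - p(cfgN), as.numeric(expected))
})

test_that("configuration grid parameter totals are strictly decreasing", {
  p <- function(cfg) count_parameters(build_model(cfg, seed = 1))$total_params
  grid <- list(
    list(c(3, 7, 3), c(116, 232, 464, 1024)),
    list(c(3, 3, 3), c(116, 232, 464, 1024)),
    list(c(2, 3, 2), c(116, 232, 464, 1024)),
    list(c(1, 3, 1), c(116, 232, 464, 1024)),
    list(c(2, 3, 2), c(96, 192, 384, 1024)),
    list(c(2, 3, 2), c(96, 192, 384, 768)))
  counts <- vapply(grid, function(g) p(shufflenet_config(g[[1]], g[[2]])), numeric(1))
  expect_true(all(diff(counts) < 0))

  # the flagship preset carries more parameters than the tuned plain baseline
  expect_gt(p(leafnet_config()),
            p(shufflenet_config(c(2, 3, 2), c(96, 192, 384, 1024))))
})

test_that("full model forward meets its contracts", {
  set.seed(5)
  cfg <- tiny_leafnet_config(num_classes = 4, input_size = 32)
  m <- build_model(cfg, seed = 5)
  x <- array(rnorm(3 * 32 * 32 * 2), dim = c(3, 32, 32, 2))
  fw <- model_forward(m, x)
  expect_identical(dim(fw$logits), c(4L, 2L))
  expect_equal(colSums(softmax_probs(fw$logits)), c(1, 1))
  expect_error(model_forward(m, array(0, c(3, 30, 30, 1))), "divisible")
  expect_error(model_config(num_classes = 1), "num_classes")
  expect_error(model_config(channels = c(95, 192, 384, 1024)), "even")
})

test_that("one backward pass reaches every trainable parameter", {
  set.seed(6)
  cfg <- tiny_leafnet_config(num_classes = 4, input_size = 32)
  m <- build_model(cfg, seed = 6)
  x <- array(rnorm(3 * 32 * 32 * 2), dim = c(3, 32, 32, 2))
  fw <- leafcnn:::nn_forward(m, x, training = TRUE)
  ce <- leafcnn:::cross_entropy(fw$y, c(1L, 2L))
  bw <- leafcnn:::nn_backward(m, fw$cache, ce$grad)
  # every parameter leaf has a defined, finite gradient of matching length
  expect_true(grad_matches_params(leafcnn:::par_tree(m), bw$gpar))
  # stem gradients are not identically zero
  stem_g <- bw$gpar$children[[1]]
  expect_gt(sum(abs(unlist(stem_g))), 0)
  expect_gt(sum(abs(stem_g$shared$children[[1]]$par$w)), 0)
})

test_that("module backward passes agree with finite differences", {
  set.seed(8)
  cfg <- model_config(repeats = c(1, 1, 1), channels = c(8, 16, 32, 64),
                      attention = "edca", residual = "rm", num_classes = 4,
                      input_size = 16)
  x8 <- array(rnorm(8 * 6 * 6 * 2), dim = c(8, 6, 6, 2))
  mods <- list(
    conv3 = leafcnn:::layer_conv(8L, 5L, 3L, stride = 2L),
    conv1 = leafcnn:::layer_conv(8L, 5L, 1L),
    dwconv = leafcnn:::layer_dwconv(8L, 3L, 2L),
    bn = leafcnn:::layer_bn(8L),
    maxpool = leafcnn:::layer_maxpool(),
    avgpool = leafcnn:::layer_avgpool(),
    att_edca = leafcnn:::layer_attention(8L, "edca"),
    att_eca = leafcnn:::layer_attention(8L, "eca"),
    att_se = leafcnn:::layer_attention(8L, "se"),
    att_srm = leafcnn:::layer_attention(8L, "srm"),
    basic_unit = leafcnn:::make_basic_unit(8L, cfg),
    down_unit = leafcnn:::make_down_unit(8L, 16L, cfg),
    mdfem = leafcnn:::make_mdfem(8L))
  for (nm in names(mods))
    expect_lt(fd_module_check(mods[[nm]], x8), 1e-6, label = nm)
  x3 <- array(rnorm(3 * 16 * 16 * 2), dim = c(3, 16, 16, 2))
  expect_lt(fd_module_check(leafcnn:::make_msfem_stem(), x3), 1e-6)
})
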