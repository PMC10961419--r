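# ShuffleNetV2-style computational units and full model assembly.
#
# The backbone follows the stride-4 stem -> Stage2/3/4 -> pointwise head
# layout, each stage opening with one downsampling unit followed by a run of
# basic (shape-preserving) units.  Channel attention sits at the tail of the
# pointwise convolution inside every unit's transform branch; optional
# residual shortcuts reconnect the unit input to the shuffled output.

shuffle_permutation <- function(C, groups) {
  if (C %% groups != 0L) stop("channel count not divisible by groups")
  as.vector(t(matrix(seq_len(C), nrow = C %/% groups)))
}

#' Channel shuffle
#'
#' Interleaves channel groups: viewing the C channels as a `groups x (C/g)`
#' grid, the channel at position (g, i) moves to position (i, g).  A pure,
#' invertible permutation; spatial content is untouched.
#'
#' @param x numeric array with `dim = c(C, H, W, N)`.
#' @param groups number of groups; `C` must be divisible by it.
#' @return array of the same shape with permuted channels.
#' @examples
#' x <- array(rep(1:4, each = 4), dim = c(4, 2, 2, 1))
#' channel_shuffle(x, 2)[, 1, 1, 1] # 1 3 2 4
#' @export
channel_shuffle <- function(x, groups) {
  d <- dims4(x)
  perm <- shuffle_permutation(d[1L], groups)
  x[perm, , , , drop = FALSE]
}

#' Channel split
#'
#' Splits an activation into two halves along the channel axis;
#' concatenating the halves restores the input exactly.
#'
#' @param x numeric array with `dim = c(C, H, W, N)`, `C` even.
#' @return list of two arrays with `C/2` channels each.
#' @export
channel_split <- function(x) {
  d <- dims4(x)
  if (d[1L] %% 2L != 0L) stop("channel count must be even to split")
  h <- d[1L] %/% 2L
  list(x[seq_len(h), , , , drop = FALSE],
       x[(h + 1L):d[1L], , , , drop = FALSE])
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[-1L] == db[-1L])) stop("spatial/batch mismatch in concat")
  out <- array(0, dim = c(da[1L] + db[1L], da[2L], da[3L], da[4L]))
  out[seq_len(da[1L]), , , ] <- a
  out[(da[1L] + 1L):(da[1L] + db[1L]), , , ] <- b
  out
}

# -- units ------------------------------------------------------------------

make_basic_unit <- function(ch, cfg) {
  if (ch %% 2L != 0L) stop("basic unit needs an even channel count")
  h <- ch %/% 2L
  branch <- layer_seq(list(
    layer_conv(h, h, 1L), layer_bn(h), layer_relu(),
    layer_dwconv(h, 3L, 1L), layer_bn(h),
    layer_conv(h, h, 1L), layer_bn(h), layer_relu()))
  list(type = "basic_unit", ch = ch,
       residual = !identical(cfg$residual, "none"),
       perm = shuffle_permutation(ch, 2L),
       branch = branch,
       att = layer_attention(h, cfg$attention, cfg$gamma, cfg$b, cfg$se_reduction))
}

basic_unit_fwd <- function(mod, x, training) {
  d <- dims4(x)
  if (d[1L] != mod$ch) stop("basic unit: channel mismatch")
  h <- mod$ch %/% 2L
  left <- x[seq_len(h), , , , drop = FALSE]
  right <- x[(h + 1L):mod$ch, , , , drop = FALSE]
  rb <- nn_forward(mod$branch, right, training); mod$branch <- rb$mod
  ra <- nn_forward(mod$att, rb$y, training);     mod$att <- ra$mod
  y <- cat_channels(left, ra$y)[mod$perm, , , , drop = FALSE]
  if (mod$residual) y <- y + x
  list(y = y, cache = list(branch = rb$cache, att = ra$cache, d = d), mod = mod)
}

basic_unit_bwd <- function(mod, cache, gy) {
  h <- mod$ch %/% 2L
  g <- gy[order(mod$perm), , , , drop = FALSE]
  gleft <- g[seq_len(h), , , , drop = FALSE]
  gatt_in <- g[(h + 1L):mod$ch, , , , drop = FALSE]
  ga <- nn_backward(mod$att, cache$att, gatt_in)
  gb <- nn_backward(mod$branch, cache$branch, ga$gx)
  gx <- cat_channels(gleft, gb$gx)
  if (mod$residual) gx <- gx + gy
  list(gx = gx, gpar = list(branch = gb$gpar, att = ga$gpar))
}

make_down_unit <- function(in_ch, out_ch, cfg) {
  h <- out_ch %/% 2L
  left <- layer_seq(list(
    layer_dwconv(in_ch, 3L, 2L), layer_bn(in_ch),
    layer_conv(in_ch, h, 1L), layer_bn(h), layer_relu()))
  right <- layer_seq(list(
    layer_conv(in_ch, h, 1L), layer_bn(h), layer_relu(),
    layer_dwconv(h, 3L, 2L), layer_bn(h),
    layer_conv(h, h, 1L), layer_bn(h), layer_relu()))
  mod <- list(type = "down_unit", in_ch = in_ch, out_ch = out_ch,
              residual = cfg$residual,
              perm = shuffle_permutation(out_ch, 2L),
              left = left, right = right,
              att = layer_attention(h, cfg$attention, cfg$gamma, cfg$b, cfg$se_reduction))
  mod$shortcut <- switch(cfg$residual,
    none = NULL,
    rm = layer_seq(list(layer_maxpool(3L, 2L, 1L),
                        layer_conv(in_ch, out_ch, 1L), layer_bn(out_ch))),
    ra = layer_seq(list(layer_avgpool(3L, 2L, 1L),
                        layer_conv(in_ch, out_ch, 1L), layer_bn(out_ch))),
    rc = layer_seq(list(layer_conv(in_ch, out_ch, 3L, stride = 2L, pad = 1L),
                        layer_bn(out_ch))),
    stop("unknown residual kind: ", cfg$residual))
  mod
}

down_unit_fwd <- function(mod, x, training) {
  d <- dims4(x)
  if (d[1L] != mod$in_ch) stop("down unit: channel mismatch")
  lf <- nn_forward(mod$left, x, training);  mod$left <- lf$mod
  rf <- nn_forward(mod$right, x, training); mod$right <- rf$mod
  ra <- nn_forward(mod$att, rf$y, training); mod$att <- ra$mod
  y <- cat_channels(lf$y, ra$y)[mod$perm, , , , drop = FALSE]
  cache <- list(left = lf$cache, right = rf$cache, att = ra$cache, d = d)
  if (!is.null(mod$shortcut)) {
    sc <- nn_forward(mod$shortcut, x, training); mod$shortcut <- sc$mod
    y <- y + sc$y
    cache$shortcut <- sc$cache
  }
  list(y = y, cache = cache, mod = mod)
}

down_unit_bwd <- function(mod, cache, gy) {
  h <- mod$out_ch %/% 2L
  gpar <- list()
  gx <- NULL
  if (!is.null(mod$shortcut)) {
    gs <- nn_backward(mod$shortcut, cache$shortcut, gy)
    gx <- gs$gx
    gpar$shortcut <- gs$gpar
  }
  g <- gy[order(mod$perm), , , , drop = FALSE]
  gl_in <- g[seq_len(h), , , , drop = FALSE]
  gr_in <- g[(h + 1L):mod$out_ch, , , , drop = FALSE]
  ga <- nn_backward(mod$att, cache$att, gr_in)
  gr <- nn_backward(mod$right, cache$right, ga$gx)
  gl <- nn_backward(mod$left, cache$left, gl_in)
  gxi <- gl$gx + gr$gx
  if (!is.null(gx)) gxi <- gxi + gx
  gpar$left <- gl$gpar; gpar$right <- gr$gpar; gpar$att <- ga$gpar
  list(gx = gxi, gpar = gpar)
}

# -- multi-scale deep feature extraction ------------------------------------

make_mdfem <- function(ch) {
  h <- ch %/% 2L
  list(type = "mdfem", ch = ch,
       b3 = layer_seq(list(layer_conv(ch, h, 3L), layer_bn(h), layer_relu())),
       b5 = layer_seq(list(layer_conv(ch, h, 5L), layer_bn(h), layer_relu())),
       fuse = layer_seq(list(layer_conv(2L * h, ch, 1L), layer_bn(ch), layer_relu())))
}

mdfem_fwd <- function(mod, x, training) {
  dims4(x)
  r3 <- nn_forward(mod$b3, x, training); mod$b3 <- r3$mod
  r5 <- nn_forward(mod$b5, x, training); mod$b5 <- r5$mod
  rf <- nn_forward(mod$fuse, cat_channels(r3$y, r5$y), training); mod$fuse <- rf$mod
  list(y = rf$y, cache = list(b3 = r3$cache, b5 = r5$cache, fuse = rf$cache),
       mod = mod)
}

mdfem_bwd <- function(mod, cache, gy) {
  h <- mod$ch %/% 2L
  gf <- nn_backward(mod$fuse, cache$fuse, gy)
  g3_in <- gf$gx[seq_len(h), , , , drop = FALSE]
  g5_in <- gf$gx[(h + 1L):(2L * h), , , , drop = FALSE]
  g3 <- nn_backward(mod$b3, cache$b3, g3_in)
  g5 <- nn_backward(mod$b5, cache$b5, g5_in)
  list(gx = g3$gx + g5$gx,
       gpar = list(b3 = g3$gpar, b5 = g5$gpar, fuse = gf$gpar))
}

# -- stems ------------------------------------------------------------------

make_msfem_stem <- function(out_ch = 24L) {
  list(type = "msfem", out_ch = out_ch,
       shared = layer_seq(list(layer_conv(3L, 16L, 3L, stride = 2L), layer_bn(16L), layer_relu())),
       pool = layer_maxpool(3L, 2L, 1L),
       convbranch = layer_seq(list(
         layer_conv(16L, 16L, 3L), layer_bn(16L), layer_relu(),
         layer_conv(16L, 16L, 3L, stride = 2L), layer_bn(16L), layer_relu())),
       fuse = layer_seq(list(layer_conv(32L, out_ch, 1L), layer_bn(out_ch), layer_relu())))
}

msfem_fwd <- function(mod, x, training) {
  rs <- nn_forward(mod$shared, x, training); mod$shared <- rs$mod
  rp <- nn_forward(mod$pool, rs$y, training)
  rc <- nn_forward(mod$convbranch, rs$y, training); mod$convbranch <- rc$mod
  rf <- nn_forward(mod$fuse, cat_channels(rp$y, rc$y), training); mod$fuse <- rf$mod
  list(y = rf$y,
       cache = list(shared = rs$cache, pool = rp$cache, convbranch = rc$cache,
                    fuse = rf$cache),
       mod = mod)
}

msfem_bwd <- function(mod, cache, gy) {
  gf <- nn_backward(mod$fuse, cache$fuse, gy)
  gp_in <- gf$gx[1:16, , , , drop = FALSE]
  gc_in <- gf$gx[17:32, , , , drop = FALSE]
  gp <- nn_backward(mod$pool, cache$pool, gp_in)
  gc <- nn_backward(mod$convbranch, cache$convbranch, gc_in)
  gs <- nn_backward(mod$shared, cache$shared, gp$gx + gc$gx)
  list(gx = gs$gx,
       gpar = list(shared = gs$gpar, convbranch = gc$gpar, fuse = gf$gpar))
}

#' Build a stem (shallow feature extraction) block
#'
#' All stems map an RGB image to a 24-channel feature map at overall stride 4
#' so they are drop-in interchangeable: `"a"` is a 3x3 stride-2 convolution
#' plus 3x3 stride-2 max pooling, `"b"` replaces the convolution by a 7x7,
#' `"c"` stacks three 3x3 convolutions before the pooling, and `"msfem"` is
#' the multi-scale shallow block (a shared stride-2 convolution feeding a
#' max-pool branch and a stacked-convolution branch, concatenated and fused
#' by a pointwise convolution).
#'
#' @param kind one of `"a"`, `"b"`, `"c"`, `"msfem"`.
#' @param out_ch output channels (default 24).
#' @return a module usable with the internal forward/backward engine.
#' @export
build_stem <- function(kind = c("a", "b", "c", "msfem"), out_ch = 24L) {
  kind <- match.arg(kind)
  switch(kind,
    a = layer_seq(list(layer_conv(3L, out_ch, 3L, stride = 2L), layer_bn(out_ch),
                       layer_relu(), layer_maxpool(3L, 2L, 1L))),
    b = layer_seq(list(layer_conv(3L, out_ch, 7L, stride = 2L, pad = 3L),
                       layer_bn(out_ch), layer_relu(), layer_maxpool(3L, 2L, 1L))),
    c = layer_seq(list(layer_conv(3L, 12L, 3L, stride = 2L), layer_bn(12L), layer_relu(),
                       layer_conv(12L, 12L, 3L), layer_bn(12L), layer_relu(),
                       layer_conv(12L, out_ch, 3L), layer_bn(out_ch), layer_relu(),
                       layer_maxpool(3L, 2L, 1L))),
    msfem = make_msfem_stem(out_ch))
}

# -- configuration ----------------------------------------------------------

#' Architecture configuration
#'
#' Describes a full network: stage repeats, channel widths, attention kind,
#' residual kind, stem kind, the deep multi-scale block flag and the class
#' count.  `repeats` counts basic (shape-preserving) units per stage; every
#' stage is additionally opened by exactly one downsampling unit.
#'
#' @param repeats integer vector of 3 basic-unit repetitions for
#'   Stage2/3/4.
#' @param channels integer vector of 4 output widths: Stage2, Stage3, Stage4
#'   and the final pointwise layer.  Stage widths must be even.
#' @param attention `"edca"`, `"eca"`, `"se"`, `"srm"` or `"none"`.
#' @param residual `"none"`, `"rm"` (max-pool shortcut), `"ra"` (average-pool
#'   shortcut) or `"rc"` (strided 3x3 convolution shortcut) in downsampling
#'   units; any non-`"none"` kind also enables the identity shortcut in basic
#'   units.
#' @param stem stem kind, see [build_stem()].
#' @param mdfem logical; insert the deep multi-scale block (parallel 3x3 and
#'   5x5 branches) after Stage4.
#' @param num_classes number of output classes (>= 2).
#' @param input_size expected square input size in pixels (must be divisible
#'   by 4).
#' @param gamma,b adaptive kernel-size parameters for the attention operator.
#' @param se_reduction bottleneck reduction ratio of the SE comparator.
#' @return an object of class `leafcnn_config`.
#' @export
model_config <- function(repeats = c(2L, 3L, 2L),
                         channels = c(96L, 192L, 384L, 1024L),
                         attention = "edca",
                         residual = "rm",
                         stem = "msfem",
                         mdfem = TRUE,
                         num_classes = 22L,
                         input_size = 224L,
                         gamma = 2, b = 1, se_reduction = 16L) {
  repeats <- as.integer(repeats); channels <- as.integer(channels)
  stopifnot(length(repeats) == 3L, all(repeats >= 1L),
            length(channels) == 4L, all(channels >= 2L))
  if (any(channels[1:3] %% 2L != 0L))
    stop("stage channels must be even (channel split needs halves)")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (input_size %% 4L != 0L) stop("input_size must be divisible by 4")
  structure(list(repeats = repeats, channels = channels,
                 attention = match.arg(attention, c("edca", "eca", "se", "srm", "none")),
                 residual = match.arg(residual, c("none", "rm", "ra", "rc")),
                 stem = match.arg(stem, c("a", "b", "c", "msfem")),
                 mdfem = isTRUE(mdfem),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 gamma = gamma, b = b, se_reduction = as.integer(se_reduction)),
            class = "leafcnn_config")
}

#' Flagship and reference presets
#'
#' `leafnet_config()` is the flagship preset: repeats `[2, 3, 2]`, channels
#' `[96, 192, 384, 1024]`, dual-pool channel attention, max-pool residual
#' shortcuts, multi-scale stem and deep block, 22 classes.
#' `shufflenet_config()` is a plain ShuffleNetV2 configuration (no attention,
#' no residual, stem `"a"`); its defaults are the standard 1.0x width.
#' `tiny_leafnet_config()` is a reduced variant for desk-scale experiments.
#'
#' @param num_classes,input_size passed through to [model_config()].
#' @param repeats,channels stage layout (ShuffleNetV2 preset only).
#' @param ... further arguments to [model_config()].
#' @return a `leafcnn_config`.
#' @export
leafnet_config <- function(num_classes = 22L, input_size = 224L, ...) {
  model_config(repeats = c(2L, 3L, 2L), channels = c(96L, 192L, 384L, 1024L),
               attention = "edca", residual = "rm", stem = "msfem", mdfem = TRUE,
               num_classes = num_classes, input_size = input_size, ...)
}

#' @rdname leafnet_config
#' @export
shufflenet_config <- function(repeats = c(3L, 7L, 3L),
                              channels = c(116L, 232L, 464L, 1024L),
                              num_classes = 22L, input_size = 224L, ...) {
  model_config(repeats = repeats, channels = channels, attention = "none",
               residual = "none", stem = "a", mdfem = FALSE,
               num_classes = num_classes, input_size = input_size, ...)
}

#' @rdname leafnet_config
#' @export
tiny_leafnet_config <- function(num_classes = 4L, input_size = 64L, ...) {
  model_config(repeats = c(1L, 1L, 1L), channels = c(24L, 48L, 96L, 256L),
               attention = "edca", residual = "rm", stem = "msfem", mdfem = TRUE,
               num_classes = num_classes, input_size = input_size, ...)
}

# -- model ------------------------------------------------------------------

#' Build a network from a configuration
#'
#' Assembles stem, three stages (one downsampling unit plus the configured
#' run of basic units each), the optional deep multi-scale block, the final
#' pointwise convolution, global average pooling and the fully connected
#' classifier head.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer; when given, parameter initialisation is
#'   seeded and fully reproducible.
#' @return an object of class `leafcnn_model`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "leafcnn_config"))
  if (!is.null(seed)) set.seed(seed)
  stem_ch <- 24L
  children <- list(stem = build_stem(cfg$stem, stem_ch))
  in_ch <- stem_ch
  for (si in 1:3) {
    ch <- cfg$channels[si]
    units <- vector("list", 1L + cfg$repeats[si])
    units[[1L]] <- make_down_unit(in_ch, ch, cfg)
    for (r in seq_len(cfg$repeats[si]))
      units[[1L + r]] <- make_basic_unit(ch, cfg)
    children[[paste0("stage", si + 1L)]] <- layer_seq(units)
    in_ch <- ch
  }
  if (cfg$mdfem) children$mdfem <- make_mdfem(in_ch)
  children$head_conv <- layer_seq(list(
    layer_conv(in_ch, cfg$channels[4L], 1L), layer_bn(cfg$channels[4L]), layer_relu()))
  children$gap <- layer_gap()
  children$fc <- layer_linear(cfg$channels[4L], cfg$num_classes)
  structure(list(type = "seq", children = children, cfg = cfg),
            class = c("leafcnn_model", "list"))
}

#' Forward pass of a built model
#'
#' @param model a [build_model()] result.
#' @param x input array `dim = c(3, H, W, N)` with H, W divisible by 4.
#' @param training logical; training mode updates batch-norm statistics.
#' @return list with `logits` (`num_classes x N`), and the possibly updated
#'   `model` plus the backward `cache` when `training = TRUE`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dims4(x)
  if (d[1L] != 3L) stop("model input must have 3 channels")
  if (d[2L] %% 4L != 0L || d[3L] %% 4L != 0L)
    stop("input spatial size must be divisible by 4")
  r <- nn_forward(model, x, training)
  out <- list(logits = r$y, model = r$mod)
  if (training) out$cache <- r$cache
  out$model$cfg <- model$cfg
  class(out$model) <- class(model)
  out
}

#' Softmax class probabilities
#'
#' @param logits `K x N` matrix of logits.
#' @return `K x N` matrix of probabilities; columns sum to 1.
#' @export
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 2L, max)[col(logits)]
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

#' Count trainable parameters
#'
#' Walks the module tree and reports the exact trainable parameter count,
#' its fp32 byte size (4 bytes per parameter) and a per-component breakdown
#' that sums to the total.
#'
#' @param model a `leafcnn_model` (or any module).
#' @return object of class `parameter_report` with fields `total_params`,
#'   `fp32_bytes` and `per_component`.
#' @export
count_parameters <- function(model) {
  if (!is.null(model$children)) {
    per <- vapply(model$children, function(ch) count_tree(par_tree(ch)), numeric(1))
    nm <- names(model$children)
    if (is.null(nm)) nm <- paste0("child", seq_along(per))
    names(per) <- nm
  } else {
    per <- c(total = count_tree(par_tree(model)))
  }
  total <- sum(per)
  structure(list(total_params = total, fp32_bytes = 4 * total, per_component = per),
            class = "parameter_report")
}

#' @export
print.parameter_report <- function(x, ...) {
  cat(sprintf("total parameters: %d (%.2f MB fp32)\n",
              x$total_params, x$fp32_bytes / 2^20))
  for (nm in names(x$per_component))
    cat(sprintf("  %-10s %10d\n", nm, x$per_component[[nm]]))
  invisible(x)
}

#' @export
print.leafcnn_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("network: repeats [%s], channels [%s]\n",
              paste(cfg$repeats, collapse = ", "),
              paste(cfg$channels, collapse = ", ")))
  cat(sprintf("  attention=%s residual=%s stem=%s mdfem=%s classes=%d\n",
              cfg$attention, cfg$residual, cfg$stem, cfg$mdfem, cfg$num_classes))
  cat(sprintf("  parameters: %d\n", count_parameters(x)$total_params))
  invisible(x)
}
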