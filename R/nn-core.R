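#' @useDynLib leafcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Activation layout: numeric array with dim c(C, H, W, N) (channel fastest).
# Every layer is a plain list carrying its type, hyper-parameters, trainable
# params under $par and non-trainable buffers under $buf.  nn_forward()
# returns list(y, cache, mod) (mod comes back because batch-norm updates its
# running statistics in training mode); nn_backward() consumes the cache and
# returns list(gx, gpar) with gpar mirroring $par.
# ---------------------------------------------------------------------------

dims4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a 4-d activation array with dim c(C, H, W, N)")
  d
}

as_feature_map <- function(values, C, H, W, N = 1L) {
  stopifnot(C >= 1L, H >= 1L, W >= 1L, N >= 1L)
  x <- array(as.numeric(values), dim = c(C, H, W, N))
  if (any(!is.finite(x))) stop("feature map values must be finite")
  x
}

# -- constructors -----------------------------------------------------------

he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(in_ch, out_ch, k = 1L, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- k %/% 2L
  w <- array(he_init(in_ch * k * k * out_ch, in_ch * k * k),
             dim = c(in_ch, k, k, out_ch))
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad, par = list(w = w))
}

layer_dwconv <- function(ch, k = 3L, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- k %/% 2L
  w <- array(he_init(k * k * ch, k * k), dim = c(k, k, ch))
  list(type = "dwconv", ch = ch, k = k, stride = stride, pad = pad,
       par = list(w = w))
}

layer_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", ch = ch, eps = eps, momentum = momentum,
       par = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buf = list(running_mean = rep(0, ch), running_var = rep(1, ch)))
}

layer_relu <- function() list(type = "relu")

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)

layer_avgpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "avgpool", k = k, stride = stride, pad = pad)

layer_gap <- function() list(type = "gap")

layer_linear <- function(in_ch, out_ch) {
  list(type = "linear", in_ch = in_ch, out_ch = out_ch,
       par = list(W = matrix(he_init(out_ch * in_ch, in_ch), out_ch, in_ch),
                  b = rep(0, out_ch)))
}

layer_shuffle <- function(ch, groups = 2L) {
  if (ch %% groups != 0L) stop("channel count not divisible by groups")
  list(type = "shuffle", ch = ch, groups = groups,
       perm = shuffle_permutation(ch, groups))
}

layer_seq <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.null(children[[1L]]$type))
    children <- children[[1L]]
  list(type = "seq", children = children)
}

# -- forward ----------------------------------------------------------------

conv_out_hw <- function(H, k, s, p) (H + 2L * p - k) %/% s + 1L

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$type,
    conv = {
      d <- dims4(x)
      if (d[1L] != mod$in_ch) stop("conv: channel mismatch")
      oh <- conv_out_hw(d[2L], mod$k, mod$stride, mod$pad)
      ow <- conv_out_hw(d[3L], mod$k, mod$stride, mod$pad)
      wm <- matrix(mod$par$w, nrow = mod$in_ch * mod$k * mod$k)
      if (mod$k == 1L && mod$stride == 1L) {
        xm <- matrix(x, nrow = d[1L])
        y <- array(crossprod(wm, xm), dim = c(mod$out_ch, d[2L], d[3L], d[4L]))
      } else {
        cols <- im2col_chw(x, d[1L], d[2L], d[3L], d[4L],
                           mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad)
        y <- array(crossprod(wm, cols), dim = c(mod$out_ch, oh, ow, d[4L]))
      }
      list(y = y, cache = list(x = x, d = d), mod = mod)
    },
    dwconv = {
      d <- dims4(x)
      if (d[1L] != mod$ch) stop("dwconv: channel mismatch")
      oh <- conv_out_hw(d[2L], mod$k, mod$stride, mod$pad)
      ow <- conv_out_hw(d[3L], mod$k, mod$stride, mod$pad)
      y <- array(dwconv_fwd(x, mod$par$w, d[1L], d[2L], d[3L], d[4L],
                            mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                 dim = c(d[1L], oh, ow, d[4L]))
      list(y = y, cache = list(x = x, d = d), mod = mod)
    },
    bn = {
      d <- dims4(x)
      C <- d[1L]; M <- length(x) %/% C
      xm <- matrix(x, C, M)
      if (training) {
        m <- rowMeans(xm)
        v <- pmax(rowMeans(xm * xm) - m * m, 0)
        mod$buf$running_mean <- (1 - mod$momentum) * mod$buf$running_mean + mod$momentum * m
        mod$buf$running_var  <- (1 - mod$momentum) * mod$buf$running_var  + mod$momentum * v
      } else {
        m <- mod$buf$running_mean
        v <- mod$buf$running_var
      }
      inv <- 1 / sqrt(v + mod$eps)
      xhat <- (xm - m) * inv
      y <- array(mod$par$gamma * xhat + mod$par$beta, dim = d)
      list(y = y, cache = list(xhat = xhat, inv = inv, d = d, training = training),
           mod = mod)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask), mod = mod)
    },
    maxpool = {
      d <- dims4(x)
      oh <- conv_out_hw(d[2L], mod$k, mod$stride, mod$pad)
      ow <- conv_out_hw(d[3L], mod$k, mod$stride, mod$pad)
      r <- maxpool_fwd(x, d[1L], d[2L], d[3L], d[4L],
                       mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad)
      list(y = array(r$out, dim = c(d[1L], oh, ow, d[4L])),
           cache = list(argmax = r$argmax, d = d), mod = mod)
    },
    avgpool = {
      d <- dims4(x)
      oh <- conv_out_hw(d[2L], mod$k, mod$stride, mod$pad)
      ow <- conv_out_hw(d[3L], mod$k, mod$stride, mod$pad)
      w <- array(1 / (mod$k * mod$k), dim = c(mod$k, mod$k, d[1L]))
      y <- array(dwconv_fwd(x, w, d[1L], d[2L], d[3L], d[4L],
                            mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                 dim = c(d[1L], oh, ow, d[4L]))
      list(y = y, cache = list(d = d), mod = mod)
    },
    gap = {
      d <- dims4(x)
      arr <- x; dim(arr) <- c(d[1L], d[2L] * d[3L], d[4L])
      y <- colSums(aperm(arr, c(2L, 1L, 3L))) / (d[2L] * d[3L])
      if (is.null(dim(y))) y <- matrix(y, d[1L], d[4L])
      list(y = y, cache = list(d = d), mod = mod)
    },
    linear = {
      y <- mod$par$W %*% x + mod$par$b
      list(y = y, cache = list(x = x), mod = mod)
    },
    shuffle = {
      dims4(x)
      list(y = x[mod$perm, , , , drop = FALSE], cache = NULL, mod = mod)
    },
    attention = attention_fwd(mod, x, training),
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- nn_forward(mod$children[[i]], x, training)
        x <- r$y
        caches[i] <- list(r$cache)   # [[<- would drop NULL caches
        mod$children[[i]] <- r$mod
      }
      list(y = x, cache = caches, mod = mod)
    },
    basic_unit = basic_unit_fwd(mod, x, training),
    down_unit = down_unit_fwd(mod, x, training),
    mdfem = mdfem_fwd(mod, x, training),
    msfem = msfem_fwd(mod, x, training),
    stop("unknown module type: ", mod$type)
  )
}

# -- backward ---------------------------------------------------------------

nn_backward <- function(mod, cache, gy) {
  switch(mod$type,
    conv = {
      d <- cache$d
      gm <- matrix(gy, mod$out_ch)
      wm <- matrix(mod$par$w, nrow = mod$in_ch * mod$k * mod$k)
      if (mod$k == 1L && mod$stride == 1L) {
        xm <- matrix(cache$x, d[1L])
        gw <- array(tcrossprod(xm, gm), dim = dim(mod$par$w))
        gx <- array(wm %*% gm, dim = d)
      } else {
        cols <- im2col_chw(cache$x, d[1L], d[2L], d[3L], d[4L],
                           mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad)
        gw <- array(tcrossprod(cols, gm), dim = dim(mod$par$w))
        gcols <- wm %*% gm
        gx <- array(col2im_chw(gcols, d[1L], d[2L], d[3L], d[4L],
                               mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                    dim = d)
      }
      list(gx = gx, gpar = list(par = list(w = gw)))
    },
    dwconv = {
      d <- cache$d
      gw <- array(dwconv_bwd_weight(cache$x, gy, d[1L], d[2L], d[3L], d[4L],
                                    mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                  dim = dim(mod$par$w))
      gx <- array(dwconv_bwd_input(gy, mod$par$w, d[1L], d[2L], d[3L], d[4L],
                                   mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                  dim = d)
      list(gx = gx, gpar = list(par = list(w = gw)))
    },
    bn = {
      d <- cache$d
      C <- d[1L]
      gm <- matrix(gy, C)
      ggamma <- rowSums(gm * cache$xhat)
      gbeta <- rowSums(gm)
      dxhat <- gm * mod$par$gamma
      if (cache$training) {
        gx <- cache$inv * (dxhat - rowMeans(dxhat) -
                             cache$xhat * rowMeans(dxhat * cache$xhat))
      } else {
        gx <- cache$inv * dxhat
      }
      list(gx = array(gx, dim = d), gpar = list(par = list(gamma = ggamma, beta = gbeta)))
    },
    relu = list(gx = gy * cache$mask, gpar = NULL),
    maxpool = {
      d <- cache$d
      gx <- array(maxpool_bwd(gy, cache$argmax, d[1L], d[2L], d[3L], d[4L]), dim = d)
      list(gx = gx, gpar = NULL)
    },
    avgpool = {
      d <- cache$d
      w <- array(1 / (mod$k * mod$k), dim = c(mod$k, mod$k, d[1L]))
      gx <- array(dwconv_bwd_input(gy, w, d[1L], d[2L], d[3L], d[4L],
                                   mod$k, mod$k, mod$stride, mod$stride, mod$pad, mod$pad),
                  dim = d)
      list(gx = gx, gpar = NULL)
    },
    gap = {
      d <- cache$d
      hw <- d[2L] * d[3L]
      gm <- (if (is.null(dim(gy))) matrix(gy, d[1L], d[4L]) else gy) / hw
      gx <- array(gm[, rep(seq_len(d[4L]), each = hw), drop = FALSE], dim = d)
      list(gx = gx, gpar = NULL)
    },
    linear = {
      gW <- tcrossprod(gy, cache$x)
      gb <- rowSums(gy)
      gx <- crossprod(mod$par$W, gy)
      list(gx = gx, gpar = list(par = list(W = gW, b = gb)))
    },
    shuffle = {
      inv <- order(mod$perm)
      list(gx = gy[inv, , , , drop = FALSE], gpar = NULL)
    },
    attention = attention_bwd(mod, cache, gy),
    seq = {
      n <- length(mod$children)
      gpar <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nn_backward(mod$children[[i]], cache[[i]], gy)
        gy <- r$gx
        gpar[i] <- list(r$gpar)      # [[<- would drop NULL gradients
      }
      list(gx = gy, gpar = list(children = gpar))
    },
    basic_unit = basic_unit_bwd(mod, cache, gy),
    down_unit = down_unit_bwd(mod, cache, gy),
    mdfem = mdfem_bwd(mod, cache, gy),
    msfem = msfem_bwd(mod, cache, gy),
    stop("unknown module type: ", mod$type)
  )
}

# -- parameter-tree utilities ----------------------------------------------

#' Walk a module tree and collect its trainable parameters
#'
#' @param mod a module as built by [build_model()] or the layer constructors.
#' @return a nested list mirroring the module hierarchy whose leaves are the
#'   parameter arrays.
#' @keywords internal
par_tree <- function(mod) {
  out <- list()
  if (!is.null(mod$par)) out$par <- mod$par
  if (!is.null(mod$children)) out$children <- lapply(mod$children, par_tree)
  for (nm in composite_child_names(mod)) out[[nm]] <- par_tree(mod[[nm]])
  out
}

set_par_tree <- function(mod, tree) {
  if (!is.null(tree$par)) mod$par <- tree$par
  if (!is.null(mod$children))
    for (i in seq_along(mod$children))
      mod$children[[i]] <- set_par_tree(mod$children[[i]], tree$children[[i]])
  for (nm in composite_child_names(mod)) mod[[nm]] <- set_par_tree(mod[[nm]], tree[[nm]])
  mod
}

composite_child_names <- function(mod) {
  switch(mod$type,
    basic_unit = c("branch", "att"),
    down_unit  = {
      nm <- c("left", "right", "att")
      if (!is.null(mod$shortcut)) nm <- c(nm, "shortcut")
      nm
    },
    mdfem = c("b3", "b5", "fuse"),
    msfem = c("shared", "convbranch", "fuse"),
    character(0))
}

count_tree <- function(tree) {
  if (is.null(tree)) return(0)
  if (is.numeric(tree)) return(length(tree))
  sum(vapply(tree, count_tree, numeric(1)))
}

# elementwise map over two parallel parameter trees
tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) out[i] <- list(tree_map2(a[[i]], b[[i]], f))
  out
}

tree_map <- function(a, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a))
  out <- a
  for (i in seq_along(a)) out[i] <- list(tree_map(a[[i]], f))
  out
}
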