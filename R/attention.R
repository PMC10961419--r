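# Channel attention operators.
#
# EDCA (efficient dual channel attention) summarises each channel of an
# N x C x H x W activation by its spatial mean (AvgPool path) and population
# standard deviation (StdPool path), passes each C-vector through a bias-free
# 1-D convolution of adaptive odd size K along the channel axis, sums the two
# paths and squashes through a sigmoid to obtain one recalibration weight per
# channel.  ECA is the average-pool path alone; SE and SRM are the classic
# comparators used in ablations.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Per-channel mean and standard deviation descriptors
#'
#' Computes, for every channel and sample, the spatial average and the
#' population standard deviation (divisor \eqn{HW}) of the activation.  These
#' are the AvgPool and StdPool descriptors feeding the dual-pool channel
#' attention operator.
#'
#' @param x numeric array with `dim = c(C, H, W, N)`.
#' @return list with matrices `avg` and `std`, each `C x N`.  `std` is zero
#'   for a spatially constant channel.
#' @examples
#' x <- array(1:4, dim = c(1, 2, 2, 1))
#' channel_stats(x) # avg 2.5, std sqrt(1.25)
#' @export
channel_stats <- function(x) {
  d <- dims4(x)
  if (d[2L] * d[3L] < 1L) stop("empty spatial extent")
  if (any(!is.finite(x))) stop("feature map values must be finite")
  hw <- d[2L] * d[3L]
  arr <- x; dim(arr) <- c(d[1L], hw, d[4L])
  ap <- aperm(arr, c(2L, 1L, 3L))
  avg <- colSums(ap) / hw
  ex2 <- colSums(ap * ap) / hw
  if (is.null(dim(avg))) { avg <- matrix(avg, d[1L], d[4L]); ex2 <- matrix(ex2, d[1L], d[4L]) }
  std <- sqrt(pmax(ex2 - avg * avg, 0))
  list(avg = avg, std = std)
}

#' Adaptive 1-D kernel size for channel attention
#'
#' Maps the channel count C to an odd kernel size
#' \eqn{K = |log2(C)/\gamma + b/\gamma|_{odd}} so that wider layers get a
#' larger cross-channel interaction range.  Rounding follows the established
#' ECA convention: truncate to an integer, then bump even values up to the
#' next odd number (which also resolves exact ties upward).
#'
#' @param C channel count (>= 1).
#' @param gamma,b slope divisor and offset of the mapping; defaults 2 and 1.
#' @return an odd integer >= 1.
#' @examples
#' adaptive_kernel_size(96)   # 3
#' adaptive_kernel_size(1024) # 5
#' @export
adaptive_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || !is.finite(C) || C < 1) stop("C must be >= 1")
  if (gamma <= 0) stop("gamma must be > 0")
  t <- abs(log2(C) / gamma + b / gamma)
  K <- as.integer(floor(t))
  if (K %% 2L == 0L) K <- K + 1L
  max(1L, K)
}

# zero-padded cross-correlation of an odd kernel along the rows of a (C, N)
# matrix: z[c] = sum_j k[j] * y[c + j - 1 - K%/%2]
conv1d_cols <- function(y, k) {
  K <- length(k); P <- K %/% 2L; C <- nrow(y)
  z <- matrix(0, C, ncol(y))
  for (j in seq_len(K)) {
    off <- j - 1L - P
    lo <- max(1L, 1L - off); hi <- min(C, C - off)
    if (lo > hi) next
    rows <- lo:hi
    z[rows, ] <- z[rows, , drop = FALSE] + k[j] * y[rows + off, , drop = FALSE]
  }
  z
}

expand_cols <- function(m, hw) m[, rep(seq_len(ncol(m)), each = hw), drop = FALSE]

reduce_cols <- function(m, C, hw, N) {
  dim(m) <- c(C, hw, N)
  r <- colSums(aperm(m, c(2L, 1L, 3L)))
  if (is.null(dim(r))) r <- matrix(r, C, N)
  r
}

#' Dual-pool channel attention forward pass
#'
#' Applies the dual-pool channel attention operator to an activation: the
#' per-channel average and standard-deviation descriptors are each convolved
#' by a bias-free 1-D kernel along the channel axis (zero padding `K %/% 2`),
#' summed, squashed by a sigmoid, and the resulting per-channel weights in
#' (0, 1) rescale the input.
#'
#' @param x numeric array with `dim = c(C, H, W, N)`.
#' @param k1,k2 numeric kernels of identical odd length
#'   `adaptive_kernel_size(C, gamma, b)`; `k1` acts on the average path and
#'   `k2` on the standard-deviation path.
#' @param gamma,b parameters of the adaptive kernel-size map.
#' @return list with `y` (the rescaled activation, same shape as `x`) and
#'   `omega` (the `C x N` matrix of channel weights).
#' @export
edca_forward <- function(x, k1, k2, gamma = 2, b = 1) {
  d <- dims4(x)
  K <- adaptive_kernel_size(d[1L], gamma, b)
  if (length(k1) != K || length(k2) != K)
    stop("kernel length must equal the adaptive kernel size ", K)
  if (length(k1) %% 2L == 0L) stop("kernel length must be odd")
  st <- channel_stats(x)
  omega <- sigmoid(conv1d_cols(st$avg, k1) + conv1d_cols(st$std, k2))
  hw <- d[2L] * d[3L]
  xm <- matrix(x, d[1L])
  y <- array(xm * expand_cols(omega, hw), dim = d)
  list(y = y, omega = omega)
}

#' Comparator channel-attention forward pass
#'
#' Forward pass of the reference channel-attention operators used alongside
#' the dual-pool module in ablations: SE (global average pool, bottleneck of
#' reduction `r`, sigmoid), ECA (adaptive 1-D convolution on the average-pool
#' descriptor) and SRM (per-channel linear recalibration of the (avg, std)
#' style vector).  All preserve the input shape.
#'
#' @param x numeric array with `dim = c(C, H, W, N)`.
#' @param kind one of `"se"`, `"eca"`, `"srm"`.
#' @param params named list of parameters: `k` (ECA kernel), `W1`/`W2`
#'   (SE bottleneck matrices), `w1`/`w2` (SRM per-channel weights).
#' @param gamma,b adaptive kernel-size parameters (ECA only).
#' @return list with `y` and `omega` as in [edca_forward()].
#' @export
comparator_forward <- function(x, kind, params, gamma = 2, b = 1) {
  kind <- match.arg(kind, c("se", "eca", "srm"))
  d <- dims4(x)
  mod <- list(type = "attention", kind = kind, ch = d[1L],
              gamma = gamma, b = b, par = params)
  r <- attention_fwd(mod, x, FALSE)
  list(y = r$y, omega = r$cache$omega)
}

# -- attention as a trainable layer ----------------------------------------

layer_attention <- function(ch, kind = "edca", gamma = 2, b = 1, se_reduction = 16L) {
  kind <- match.arg(kind, c("edca", "eca", "se", "srm", "none"))
  mod <- list(type = "attention", kind = kind, ch = ch, gamma = gamma, b = b)
  if (kind %in% c("edca", "eca")) {
    K <- adaptive_kernel_size(ch, gamma, b)
    mod$K <- K
    if (kind == "edca")
      mod$par <- list(k1 = rnorm(K, sd = 1 / sqrt(K)), k2 = rnorm(K, sd = 1 / sqrt(K)))
    else
      mod$par <- list(k = rnorm(K, sd = 1 / sqrt(K)))
  } else if (kind == "se") {
    hidden <- max(1L, ch %/% se_reduction)
    mod$hidden <- hidden
    mod$par <- list(W1 = matrix(he_init(hidden * ch, ch), hidden, ch),
                    W2 = matrix(he_init(ch * hidden, hidden), ch, hidden))
  } else if (kind == "srm") {
    mod$par <- list(w1 = rnorm(ch, sd = 0.1), w2 = rnorm(ch, sd = 0.1))
  }
  mod
}

attention_fwd <- function(mod, x, training) {
  if (mod$kind == "none") return(list(y = x, cache = NULL, mod = mod))
  d <- dims4(x)
  if (d[1L] != mod$ch && !is.null(mod$ch)) {
    if (!identical(mod$ch, d[1L])) stop("attention: channel mismatch")
  }
  hw <- d[2L] * d[3L]
  st <- channel_stats(x)
  a <- st$avg; s <- st$std
  cache <- list(d = d, a = a, s = s, x = x)
  z <- switch(mod$kind,
    edca = {
      if (length(mod$par$k1) %% 2L == 0L) stop("kernel length must be odd")
      conv1d_cols(a, mod$par$k1) + conv1d_cols(s, mod$par$k2)
    },
    eca = {
      if (length(mod$par$k) %% 2L == 0L) stop("kernel length must be odd")
      conv1d_cols(a, mod$par$k)
    },
    se = {
      h1 <- mod$par$W1 %*% a
      m1 <- h1 > 0
      cache$h1 <- h1 * m1
      cache$m1 <- m1
      mod$par$W2 %*% cache$h1
    },
    srm = mod$par$w1 * a + mod$par$w2 * s,
    stop("unknown attention kind: ", mod$kind))
  omega <- sigmoid(z)
  cache$omega <- omega
  y <- array(matrix(x, d[1L]) * expand_cols(omega, hw), dim = d)
  list(y = y, cache = cache, mod = mod)
}

attention_bwd <- function(mod, cache, gy) {
  if (mod$kind == "none") return(list(gx = gy, gpar = NULL))
  d <- cache$d
  C <- d[1L]; hw <- d[2L] * d[3L]; N <- d[4L]
  gm <- matrix(gy, C)
  xm <- matrix(cache$x, C)
  om_exp <- expand_cols(cache$omega, hw)
  # direct path: y = omega * x
  gx <- gm * om_exp
  domega <- reduce_cols(gm * xm, C, hw, N)
  dz <- domega * cache$omega * (1 - cache$omega)
  a <- cache$a; s <- cache$s
  da <- NULL; ds <- NULL; gpar <- NULL
  if (mod$kind == "edca") {
    k1 <- mod$par$k1; k2 <- mod$par$k2
    da <- conv1d_cols(dz, rev(k1))
    ds <- conv1d_cols(dz, rev(k2))
    gpar <- list(k1 = conv1d_kernel_grad(dz, a, length(k1)),
                 k2 = conv1d_kernel_grad(dz, s, length(k2)))
  } else if (mod$kind == "eca") {
    k <- mod$par$k
    da <- conv1d_cols(dz, rev(k))
    gpar <- list(k = conv1d_kernel_grad(dz, a, length(k)))
  } else if (mod$kind == "se") {
    gW2 <- tcrossprod(dz, cache$h1)
    dh1 <- crossprod(mod$par$W2, dz) * cache$m1
    gW1 <- tcrossprod(dh1, a)
    da <- crossprod(mod$par$W1, dh1)
    gpar <- list(W1 = gW1, W2 = gW2)
  } else if (mod$kind == "srm") {
    gpar <- list(w1 = rowSums(dz * a), w2 = rowSums(dz * s))
    da <- dz * mod$par$w1
    ds <- dz * mod$par$w2
  }
  gx <- gx + expand_cols(da, hw) / hw
  if (!is.null(ds)) {
    s_safe <- pmax(s, 1e-12)
    gx <- gx + expand_cols(ds / (hw * s_safe), hw) * (xm - expand_cols(a, hw))
  }
  list(gx = array(gx, dim = d), gpar = list(par = gpar))
}

# gradient of a zero-padded 1-D channel convolution w.r.t. its kernel
conv1d_kernel_grad <- function(dz, y, K) {
  P <- K %/% 2L; C <- nrow(y)
  gk <- numeric(K)
  for (j in seq_len(K)) {
    off <- j - 1L - P
    lo <- max(1L, 1L - off); hi <- min(C, C - off)
    if (lo > hi) next
    rows <- lo:hi
    gk[j] <- sum(dz[rows, , drop = FALSE] * y[rows + off, , drop = FALSE])
  }
  gk
}
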