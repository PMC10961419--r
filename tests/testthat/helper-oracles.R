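# Independent oracles, written from the definitions with naive loops so they
# share no code path with the implementation they check.

# literal composition of the dual-pool attention equations: per-sample,
# per-channel loops over avg/std pooling, zero-padded 1-D convolution,
# sigmoid, broadcast multiply
edca_oracle <- function(x, k1, k2) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  K <- length(k1); P <- K %/% 2
  out <- array(0, dim = d)
  omega_all <- matrix(0, C, N)
  for (n in seq_len(N)) {
    avg <- numeric(C); std <- numeric(C)
    for (c in seq_len(C)) {
      v <- as.vector(x[c, , , n])
      avg[c] <- sum(v) / (H * W)
      std[c] <- sqrt(sum((v - avg[c])^2) / (H * W))
    }
    conv1 <- function(y, k) {
      z <- numeric(C)
      for (c in seq_len(C))
        for (j in seq_len(K)) {
          src <- c + j - 1 - P
          if (src >= 1 && src <= C) z[c] <- z[c] + k[j] * y[src]
        }
      z
    }
    omega <- 1 / (1 + exp(-(conv1(avg, k1) + conv1(std, k2))))
    omega_all[, n] <- omega
    for (c in seq_len(C)) out[c, , , n] <- x[c, , , n] * omega[c]
  }
  list(y = out, omega = omega_all)
}

# nearest-odd oracle for the adaptive kernel-size map (ties resolved upward)
nearest_odd_kernel <- function(C, gamma = 2, b = 1) {
  t <- abs(log2(C) / gamma + b / gamma)
  lo <- 2 * floor((t - 1) / 2) + 1   # largest odd <= t (odd grid)
  hi <- lo + 2
  K <- if (t - lo < hi - t) lo else hi
  max(1, K)
}

# brute-force per-sample metric tally for one-vs-rest P/R/F1 and accuracy
metrics_oracle <- function(y_true, y_pred, K) {
  P <- R <- F1 <- numeric(K)
  for (c in seq_len(K)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    P[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    F1[c] <- if (P[c] + R[c] == 0) 0 else 2 * P[c] * R[c] / (P[c] + R[c])
  }
  list(precision = mean(P), recall = mean(R), f1 = mean(F1),
       accuracy = mean(y_true == y_pred),
       per_class_P = P, per_class_R = R, per_class_F1 = F1)
}

# finite-difference gradient checker for a single module: checks dL/dx at
# sampled positions and dL/dpar on every parameter leaf, for the functional
# L = sum(forward(x) * W) with a fixed random W
fd_module_check <- function(mod, x, eps = 1e-5, n_pos = 4) {
  fw <- leafcnn:::nn_forward(mod, x, training = TRUE)
  Wr <- fw$y
  Wr[] <- rnorm(length(Wr))
  loss_fn <- function(mod, x) sum(leafcnn:::nn_forward(mod, x, training = TRUE)$y * Wr)
  bw <- leafcnn:::nn_backward(mod, fw$cache, Wr)
  pos <- sample(length(x), min(n_pos, length(x)))
  err_x <- max(vapply(pos, function(i) {
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    gn <- (loss_fn(mod, x2) - loss_fn(mod, x3)) / (2 * eps)
    abs(gn - bw$gx[i]) / max(1, abs(gn))
  }, numeric(1)))
  err_p <- 0
  if (!is.null(mod$par)) {
    for (nm in names(mod$par)) {
      idx <- sample(length(mod$par[[nm]]), min(3, length(mod$par[[nm]])))
      for (i in idx) {
        m2 <- mod; m2$par[[nm]][i] <- m2$par[[nm]][i] + eps
        m3 <- mod; m3$par[[nm]][i] <- m3$par[[nm]][i] - eps
        gn <- (loss_fn(m2, x) - loss_fn(m3, x)) / (2 * eps)
        err_p <- max(err_p, abs(gn - bw$gpar$par[[nm]][i]) / max(1, abs(gn)))
      }
    }
  }
  max(err_x, err_p)
}

# count parameter leaves and check the matching gradient leaves are defined
grad_matches_params <- function(ptree, gtree) {
  if (is.null(ptree)) return(TRUE)
  if (is.numeric(ptree)) {
    return(!is.null(gtree) && length(gtree) == length(ptree) &&
             all(is.finite(gtree)))
  }
  if (is.null(gtree) || length(ptree) == 0) return(length(ptree) == 0)
  all(vapply(seq_along(ptree), function(i) {
    nm <- names(ptree)[i]
    gt <- if (!is.null(nm) && nzchar(nm) && !is.null(gtree[[nm]])) gtree[[nm]] else gtree[[i]]
    grad_matches_params(ptree[[i]], gt)
  }, logical(1)))
}

tiny_4class_dataset <- function(n_train = 6, n_test = 4, size = 16, seed = 123) {
  spec <- synth_spec(n_classes = 4, n_train = n_train, n_test = n_test,
                     image_size = size, seed = seed)
  generate_dataset(spec)
}
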