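# Minimal neural-network primitives for the slice scorer: 2-D convolution
# via im2col + BLAS matrix multiplication, ReLU, global average pooling,
# dense layers, and an RMSprop optimizer. Feature maps are stored as
# matrices of shape (P * N, C): P spatial positions (column-major within a
# slice), N batch samples (position varies fastest), C channels.

# Precompute the gather indices for a K x K convolution over an H x W
# plane with the given stride and zero padding.
conv_plan <- function(H, W, kernel = 3L, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  H2 <- (Hp - kernel) %/% stride + 1L
  W2 <- (Wp - kernel) %/% stride + 1L
  P2 <- H2 * W2
  # linear index into the padded plane for output position (oy, ox) and
  # kernel offset (ky, kx); plane is column-major (y fastest)
  oy <- rep(seq_len(H2), times = W2)
  ox <- rep(seq_len(W2), each = H2)
  idx <- matrix(0L, P2, kernel * kernel)
  o <- 0L
  for (kx in seq_len(kernel)) for (ky in seq_len(kernel)) {
    o <- o + 1L
    y <- (oy - 1L) * stride + ky
    x <- (ox - 1L) * stride + kx
    idx[, o] <- y + (x - 1L) * Hp
  }
  yy <- rep(seq_len(H), times = W) + pad
  xx <- rep(seq_len(W), each = H) + pad
  inner <- yy + (xx - 1L) * Hp
  list(H = H, W = W, Hp = Hp, Wp = Wp, H2 = H2, W2 = W2,
       P = H * W, P2 = P2, K = kernel * kernel,
       idx = idx, inner = inner)
}

# X: (P*N, C) -> list(out = (P2*N, Co), cache)
conv_forward <- function(X, N, Wmat, bias, plan, keep_cache = FALSE) {
  C <- ncol(X)
  # padded planes, columns indexed by (n, c) with n fastest
  Xp <- matrix(0, plan$Hp * plan$Wp, N * C)
  Xp[plan$inner, ] <- matrix(X, plan$P, N * C)
  G <- Xp[as.vector(plan$idx), , drop = FALSE]          # (P2*K, N*C)
  B <- array(G, c(plan$P2, plan$K, N, C))
  B <- matrix(aperm(B, c(1, 3, 2, 4)), plan$P2 * N, plan$K * C)
  out <- B %*% Wmat
  out <- sweep(out, 2, bias, `+`)
  list(out = out, cache = if (keep_cache) list(B = B, C = C) else NULL)
}

# dOut: (P2*N, Co) -> gradients and (optionally) dX
conv_backward <- function(dOut, N, Wmat, plan, cache, need_dx = TRUE) {
  dW <- crossprod(cache$B, dOut)
  db <- colSums(dOut)
  dX <- NULL
  if (need_dx) {
    C <- cache$C
    dB <- dOut %*% t(Wmat)                              # (P2*N, K*C)
    arr <- array(dB, c(plan$P2, N, plan$K, C))
    dXp <- matrix(0, plan$Hp * plan$Wp, N * C)
    for (o in seq_len(plan$K)) {
      sl <- matrix(arr[, , o, ], plan$P2, N * C)
      tgt <- plan$idx[, o]
      dXp[tgt, ] <- dXp[tgt, ] + sl
    }
    dX <- matrix(dXp[plan$inner, ], plan$P * N, C)
  }
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# He-scaled Gaussian initialization (fan_in = rows of the weight matrix)
init_weight <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# RMSprop with optional momentum (the torch formulation):
#   v <- alpha v + (1 - alpha) g^2
#   b <- momentum b + g / (sqrt(v) + eps);  p <- p - lr b
rmsprop_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(v = zeros, buf = zeros)
}

rmsprop_step <- function(params, grads, state, lr, alpha = 0.99, eps = 1e-8,
                         momentum = 0) {
  for (group in names(params)) {
    for (nm in names(params[[group]])) {
      g <- grads[[group]][[nm]]
      v <- alpha * state$v[[group]][[nm]] + (1 - alpha) * g^2
      b <- momentum * state$buf[[group]][[nm]] + g / (sqrt(v) + eps)
      params[[group]][[nm]] <- params[[group]][[nm]] - lr * b
      state$v[[group]][[nm]] <- v
      state$buf[[group]][[nm]] <- b
    }
  }
  list(params = params, state = state)
}
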