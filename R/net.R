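# Internal multilayer perceptron with SELU activations and a softmax head.
#
# Two weight-sharing lobes are realized by running the same parameter set on
# the frame-at-t and frame-at-(t+tau) batches.  Written against BLAS matrix
# ops; gradients are exact (manual backprop), which the gradient module
# reuses to differentiate state probabilities with respect to the inputs.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(z) {
  SELU_LAMBDA * (pmax(z, 0) + SELU_ALPHA * (exp(pmin(z, 0)) - 1))
}
selu_grad <- function(z) {
  pos <- z > 0
  SELU_LAMBDA * (pos + (!pos) * (SELU_ALPHA * exp(pmin(z, 0))))
}

# Lecun-normal initialization (paired with SELU).  The output layer starts
# near zero so training begins from almost-uniform state probabilities: no
# output node can start saturated-off (a dead softmax node never recovers,
# which is how state-collapsed local optima arise), while the small noise
# still breaks the state symmetry deterministically.
net_init <- function(dims, seed, out_scale = 0.01) {
  with_seed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- base::matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                          sd = 1 / sqrt(dims[l])),
                             dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    W[[length(W)]] <- W[[length(W)]] * out_scale
    list(W = W, b = b, dims = dims)
  })
}

softmax_rows <- function(Z) {
  mx <- Z[, 1]
  for (j in seq_len(ncol(Z))[-1]) mx <- pmax(mx, Z[, j])
  E <- exp(Z - mx)
  E / rowSums(E)
}

# Forward pass; keeps pre-activations for backprop when cache = TRUE.
net_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  zs <- if (cache) vector("list", L) else NULL
  hs <- if (cache) vector("list", L) else NULL
  h <- X
  for (l in seq_len(L - 1L)) {
    z <- sweep(h %*% net$W[[l]], 2, net$b[[l]], `+`)
    if (cache) { zs[[l]] <- z; hs[[l]] <- h }
    h <- selu(z)
  }
  z <- sweep(h %*% net$W[[L]], 2, net$b[[L]], `+`)
  if (cache) { zs[[L]] <- z; hs[[L]] <- h }
  P <- softmax_rows(z)
  if (cache) list(P = P, zs = zs, hs = hs) else P
}

# Backprop of an upstream gradient dP (n x M, w.r.t. the softmax output),
# or directly of a logit gradient dZ (e.g. cross-entropy: (P - Y) / n).
# Returns parameter gradients and, if want_input, the gradient w.r.t. X.
net_backward <- function(net, fwd, dP = NULL, want_input = FALSE, dZ = NULL) {
  L <- length(net$W)
  P <- fwd$P
  dz <- if (is.null(dZ)) {
    P * (dP - rowSums(dP * P))  # softmax Jacobian applied row-wise
  } else dZ
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$hs[[l]], dz)
    gb[[l]] <- colSums(dz)
    if (l > 1L) {
      dz <- (dz %*% t(net$W[[l]])) * selu_grad(fwd$zs[[l - 1L]])
    } else if (want_input) {
      dX <- dz %*% t(net$W[[1L]])
    }
  }
  list(gW = gW, gb = gb, dX = if (want_input) dX else NULL)
}

# Gradient of output probability of one state w.r.t. the (standardized)
# inputs, for every row of X.  Exact, via backprop with dP = e_state.
net_input_gradient <- function(net, X, state) {
  fwd <- net_forward(net, X, cache = TRUE)
  dP <- base::matrix(0, nrow(X), ncol(fwd$P))
  dP[, state] <- 1
  net_backward(net, fwd, dP, want_input = TRUE)$dX
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / c1) /
      (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / c1) /
      (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
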