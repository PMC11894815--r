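## Minimal dense MLP with ReLU activations, manual backprop, and Adam.
## Kept internal: the user-facing surface is fit_inr() and its methods.

## sizes: c(d_in, hidden..., d_out); returns list of W (in x out) and b
mlp_init <- function(sizes, seed = 0L) {
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    bound <- 1 / sqrt(sizes[i])   # fan-in uniform init
    W[[i]] <- matrix(stats::runif(sizes[i] * sizes[i + 1L], -bound, bound),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- stats::runif(sizes[i + 1L], -bound, bound)
  }
  list(W = W, b = b, sizes = sizes)
}

## forward pass; keep = TRUE retains pre-activations for backprop.
## ReLU on all layers except the last (linear output).
mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  H <- X
  Zs <- if (keep) vector("list", L) else NULL
  Hs <- if (keep) vector("list", L) else NULL  # inputs to each layer
  for (i in seq_len(L)) {
    if (keep) Hs[[i]] <- H
    Z <- H %*% net$W[[i]]
    Z <- sweep(Z, 2L, net$b[[i]], "+")
    if (i < L) {
      H <- pmax(Z, 0)
      if (keep) Zs[[i]] <- Z
    } else H <- Z
  }
  if (keep) list(out = H, Zs = Zs, Hs = Hs) else H
}

## backprop from dOut (gradient wrt linear output); returns grads
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  G <- dOut
  for (i in rev(seq_len(L))) {
    dW[[i]] <- crossprod(fw$Hs[[i]], G)
    db[[i]] <- colSums(G)
    if (i > 1L) {
      G <- tcrossprod(G, net$W[[i]])
      G <- G * (fw$Zs[[i - 1L]] > 0)
    }
  }
  list(dW = dW, db = db)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$dW[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$dW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$db[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$db[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(net = net, state = state)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
dsoftplus <- function(x) 1 / (1 + exp(-x))
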