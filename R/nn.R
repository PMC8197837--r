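## Minimal dense network machinery for the conditional GAN: fully connected
## layers with ReLU hidden activations, trained with Adam on binary
## cross-entropy. Kept internal; the data are 10-dimensional and the training
## sets tiny, so plain R matrix algebra is ample.

.nnInit <- function(sizes) {
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))  # Glorot uniform
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## Forward pass. out = "linear" leaves the top layer as logits (used by the
## discriminator with BCE-with-logits); out = "sigmoid" bounds outputs in
## (0,1) (generator, matching min-max scaled features).
.nnForward <- function(net, X, out = c("linear", "sigmoid")) {
  out <- match.arg(out)
  nl <- length(net$W)
  A <- vector("list", nl + 1L)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) pmax(Z, 0) else switch(out, linear = Z,
                                                      sigmoid = .sigmoid(Z))
  }
  list(A = A, out = A[[nl + 1L]])
}

## Backward pass from the gradient w.r.t. the top layer's pre-activation.
## Returns weight/bias gradients and the gradient w.r.t. the network input
## (needed to chain the discriminator into the generator).
.nnBackward <- function(net, fw, dZ) {
  nl <- length(net$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(net$W[[l]])
    if (l > 1L) dZ <- dA * (fw$A[[l]] > 0)  # ReLU mask
  }
  list(gW = gW, gb = gb, dX = dA)
}

.adamInit <- function(net) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

.adamStep <- function(net, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

## Numerically stable binary cross-entropy from logits.
.bceFromLogits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}
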