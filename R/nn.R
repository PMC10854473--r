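# Minimal dense-network machinery: seeded initialization, softmax
# cross-entropy, hand-rolled Adam. Kept deliberately small — desk-scale
# backbones need seconds of CPU, full determinism, and an explicit
# body/head split for the freeze-and-replace transfer contract.

nn_init <- function(sizes, seed) {
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  layers
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass; ReLU on all but the last layer. Returns per-layer inputs
# (for backprop), the penultimate activation, and softmax probabilities.
nn_forward <- function(layers, X) {
  acts <- vector("list", length(layers))
  A <- X
  for (l in seq_along(layers)) {
    acts[[l]] <- A
    Z <- sweep(A %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    A <- if (l < length(layers)) pmax(Z, 0) else Z
  }
  list(inputs = acts, penultimate = acts[[length(layers)]],
       probs = softmax_rows(A))
}

nn_loss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

# Train with Adam on softmax cross-entropy. `trainable` is a logical per
# layer; frozen layers receive no updates (their parameters stay
# bit-identical). Mini-batches are drawn from a seeded permutation per
# epoch, so training is fully reproducible.
nn_train <- function(layers, X, Y, epochs, batch_size, lr, seed,
                     trainable = rep(TRUE, length(layers))) {
  n <- nrow(X)
  L <- length(layers)
  m <- v <- lapply(layers, function(ly)
    list(W = ly$W * 0, b = ly$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    set.seed(seed + 7919L * ep)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fw <- nn_forward(layers, Xb)
      delta <- (fw$probs - Yb) / nrow(Xb)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$inputs[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          back <- delta %*% t(layers[[l]]$W)
          delta <- back * (fw$inputs[[l]] > 0)
        }
        if (!trainable[l]) next
        m[[l]]$W <- beta1 * m[[l]]$W + (1 - beta1) * gW
        m[[l]]$b <- beta1 * m[[l]]$b + (1 - beta1) * gb
        v[[l]]$W <- beta2 * v[[l]]$W + (1 - beta2) * gW^2
        v[[l]]$b <- beta2 * v[[l]]$b + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        layers[[l]]$W <- layers[[l]]$W -
          lr * (m[[l]]$W / corr1) / (sqrt(v[[l]]$W / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (m[[l]]$b / corr1) / (sqrt(v[[l]]$b / corr2) + eps)
      }
    }
    losses[ep] <- nn_loss(nn_forward(layers, X)$probs, Y)
  }
  list(layers = layers, losses = losses)
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}
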