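## Internal fully connected network: input -> 256 -> 128 -> classes, ReLU
## hidden units, softmax output, weighted cross-entropy loss, Adam updates.
## Written with plain matrix algebra; at these sizes (a few hundred inputs,
## two small hidden layers) BLAS-backed R is entirely adequate and the
## training is deterministic given the seed.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # He initialization for ReLU layers
    sd <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

mlp_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# One Adam step on a minibatch.  y is an integer class index vector
# (1-based); w is a per-sample weight vector.
mlp_step <- function(net, opt, X, y, w, lr, t) {
  L <- length(net$W)
  A <- mlp_forward(net, X)
  P <- mlp_softmax(A[[L + 1L]])
  n <- nrow(X)
  D <- P
  D[cbind(seq_len(n), y)] <- D[cbind(seq_len(n), y)] - 1
  D <- D * (w / sum(w))            # weighted mean gradient
  for (l in rev(seq_len(L))) {
    gW <- crossprod(A[[l]], D)
    gb <- colSums(D)
    if (l > 1L) {
      D <- (D %*% t(net$W[[l]])) * (A[[l]] > 0)
    }
    # Adam moments
    opt$mW[[l]] <- 0.9 * opt$mW[[l]] + 0.1 * gW
    opt$vW[[l]] <- 0.999 * opt$vW[[l]] + 0.001 * gW^2
    opt$mb[[l]] <- 0.9 * opt$mb[[l]] + 0.1 * gb
    opt$vb[[l]] <- 0.999 * opt$vb[[l]] + 0.001 * gb^2
    mh <- opt$mW[[l]] / (1 - 0.9^t); vh <- opt$vW[[l]] / (1 - 0.999^t)
    net$W[[l]] <- net$W[[l]] - lr * mh / (sqrt(vh) + 1e-8)
    mh <- opt$mb[[l]] / (1 - 0.9^t); vh <- opt$vb[[l]] / (1 - 0.999^t)
    net$b[[l]] <- net$b[[l]] - lr * mh / (sqrt(vh) + 1e-8)
  }
  list(net = net, opt = opt)
}

mlp_train <- function(X, y, n_classes, hidden = c(256L, 128L),
                      class_weights = rep(1, n_classes),
                      epochs = 30L, batch_size = 128L, lr = 1e-3,
                      seed = 1L, verbose = FALSE) {
  with_seed(seed, {
    net <- mlp_init(ncol(X), hidden, n_classes)
    zeros <- function(m) lapply(m, function(z) z * 0)
    opt <- list(mW = zeros(net$W), vW = zeros(net$W),
                mb = zeros(net$b), vb = zeros(net$b))
    n <- nrow(X)
    w_sample <- class_weights[y]
    t <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        t <- t + 1L
        st <- mlp_step(net, opt, X[idx, , drop = FALSE], y[idx],
                       w_sample[idx], lr, t)
        net <- st$net; opt <- st$opt
      }
      if (verbose) {
        acc <- mean(mlp_predict_class(net, X) == y)
        message(sprintf("epoch %d: train accuracy %.4f", ep, acc))
      }
    }
    net
  })
}

mlp_predict_prob <- function(net, X) {
  A <- mlp_forward(net, X)
  mlp_softmax(A[[length(A)]])
}

mlp_predict_class <- function(net, X) {
  max.col(mlp_predict_prob(net, X), ties.method = "first")
}
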