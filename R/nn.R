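# Minimal 1-D convolutional network engine.
#
# Everything is dense matrix algebra: convolutions are im2col gathers
# followed by a single matrix multiply, so the whole simulator runs on BLAS
# without a deep-learning framework. Layers are described by specs with
# precomputed gather indices; parameters live in a flat named list so the
# split-learning bookkeeping (section maps, flattening, shared-layer
# injection) is trivial and bitwise-reproducible.

relu <- function(x) relu_cpp(x)

# He-scaled normal initialisation, consumed from the current RNG stream.
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Build layer geometry for a stack of conv blocks + global average pool +
# dense head, given the input length/channels.
conv_stack_arch <- function(input_len, in_ch, n_classes, blocks) {
  layers <- list()
  L <- input_len; C <- in_ch
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    P <- floor((L - b$k) / b$stride) + 1L
    if (P < 1) stop("sequence too short for conv block ", i)
    layers[[length(layers) + 1L]] <- list(
      type = "conv", name = b$name, k = b$k, stride = b$stride,
      in_ch = C, out_ch = b$f, in_len = L, out_len = P)
    L <- P; C <- b$f
  }
  layers[[length(layers) + 1L]] <- list(type = "gap", in_len = L, in_ch = C)
  layers[[length(layers) + 1L]] <- list(type = "dense", name = "head",
                                        in_dim = C, out_dim = n_classes)
  layers
}

init_params <- function(layers) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      fan_in <- ly$k * ly$in_ch
      params[[paste0(ly$name, "_W")]] <- init_mat(fan_in, ly$out_ch, fan_in)
      params[[paste0(ly$name, "_b")]] <- numeric(ly$out_ch)
    } else if (ly$type == "dense") {
      params[[paste0(ly$name, "_W")]] <- init_mat(ly$in_dim, ly$out_dim, ly$in_dim)
      params[[paste0(ly$name, "_b")]] <- numeric(ly$out_dim)
    }
  }
  params
}

# im2col gather: X array (B, L, C) -> matrix (B*P) x (k*C); the gather
# and its scatter-add inverse are compiled (src/conv.cpp) since they
# dominate the training profile.
im2col <- function(X, ly) {
  im2col_cpp(X, dim(X)[1], ly$in_len, ly$in_ch, ly$k, ly$stride, ly$out_len)
}

col2im <- function(dY, ly, B) {
  col2im_cpp(dY, B, ly$in_len, ly$in_ch, ly$k, ly$stride, ly$out_len)
}

# Forward pass. Returns class probabilities; with cache = TRUE also the
# per-layer activations needed for backprop.
net_forward <- function(net, X, cache = FALSE) {
  B <- dim(X)[1]
  caches <- if (cache) vector("list", length(net$layers)) else NULL
  A <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      Xc <- im2col(A, ly)
      W <- net$params[[paste0(ly$name, "_W")]]
      b <- net$params[[paste0(ly$name, "_b")]]
      Z <- Xc %*% W
      Z <- sweep(Z, 2, b, "+")
      H <- relu(Z)
      if (cache) caches[[i]] <- list(Xc = Xc, mask = Z > 0)
      A <- H
      dim(A) <- c(B, ly$out_len, ly$out_ch)
    } else if (ly$type == "gap") {
      if (cache) caches[[i]] <- list(P = dim(A)[2])
      A <- colSums(aperm(A, c(2, 1, 3)), dims = 1) / dim(A)[2]
    } else if (ly$type == "dense") {
      W <- net$params[[paste0(ly$name, "_W")]]
      b <- net$params[[paste0(ly$name, "_b")]]
      if (cache) caches[[i]] <- list(Xin = A)
      A <- sweep(A %*% W, 2, b, "+")
    }
  }
  # softmax with max-shift for stability
  Z <- A - apply(A, 1, max)
  E <- exp(Z)
  probs <- E / rowSums(E)
  list(probs = probs, logits = A, caches = caches)
}

# Backward pass from dlogits; returns named list of parameter gradients.
net_backward <- function(net, dlogits, caches, B) {
  grads <- list()
  dA <- dlogits
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      Xin <- caches[[i]]$Xin
      W <- net$params[[paste0(ly$name, "_W")]]
      grads[[paste0(ly$name, "_W")]] <- crossprod(Xin, dA)
      grads[[paste0(ly$name, "_b")]] <- colSums(dA)
      dA <- dA %*% t(W)
    } else if (ly$type == "gap") {
      P <- caches[[i]]$P
      dX <- array(0, c(B, P, ncol(dA)))
      dAp <- dA / P
      for (p in seq_len(P)) dX[, p, ] <- dAp
      dA <- dX
    } else if (ly$type == "conv") {
      ca <- caches[[i]]
      dH <- dA
      dim(dH) <- c(B * ly$out_len, ly$out_ch)
      dZ <- dH * ca$mask
      W <- net$params[[paste0(ly$name, "_W")]]
      grads[[paste0(ly$name, "_W")]] <- crossprod(ca$Xc, dZ)
      grads[[paste0(ly$name, "_b")]] <- colSums(dZ)
      dXc <- dZ %*% t(W)
      dA <- col2im(dXc, ly, B)
    }
  }
  grads
}

# Weighted softmax cross-entropy; returns loss and dlogits.
weighted_ce <- function(probs, logits, y, class_w) {
  n <- nrow(probs); K <- ncol(probs)
  w <- class_w[y + 1L]
  sw <- sum(w)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- -sum(w * log(pmax(probs[pick], 1e-12))) / sw
  Y <- matrix(0, n, K); Y[pick] <- 1
  dlogits <- (probs - Y) * (w / sw)
  list(loss = loss, dlogits = dlogits)
}

# One Adam update over all parameters, in place on the net object.
adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$opt_t <- net$opt_t + 1L
  t <- net$opt_t
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(net$opt[[nm]]))
      net$opt[[nm]] <- list(m = g * 0, v = g * 0)
    st <- net$opt[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    net$opt[[nm]] <- st
  }
  net
}

# Per-record per-channel z-scoring of an (n, L, C) array.
prep_inputs <- function(X) {
  for (c in seq_len(dim(X)[3])) {
    M <- X[, , c]
    if (is.null(dim(M))) M <- matrix(M, nrow = dim(X)[1])
    mu <- rowMeans(M)
    sd <- sqrt(pmax(rowMeans(M * M) - mu * mu, 0))
    sd[sd == 0 | !is.finite(sd)] <- 1
    X[, , c] <- (M - mu) / sd
  }
  X
}

# Mini-batch training loop shared by classifier and baseline arms.
# Consumes the current RNG stream for shuffling; returns updated net and
# the first/last epoch mean losses.
net_train_epochs <- function(net, X, y, class_w, epochs, batch_size, lr) {
  n <- dim(X)[1]
  first_loss <- NA_real_; last_loss <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      fw <- net_forward(net, Xb, cache = TRUE)
      lw <- weighted_ce(fw$probs, fw$logits, y[idx], class_w)
      if (!is.finite(lw$loss)) stop("NaN loss during local training")
      grads <- net_backward(net, lw$dlogits, fw$caches, length(idx))
      net <- adam_step(net, grads, lr)
      losses <- c(losses, lw$loss)
    }
    if (ep == 1) first_loss <- mean(losses)
    last_loss <- mean(losses)
  }
  list(net = net, first_loss = first_loss, last_loss = last_loss)
}
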