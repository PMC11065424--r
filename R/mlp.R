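# Multi-label feed-forward network: ReLU hidden layers, sigmoid outputs,
# binary cross-entropy loss, Adam optimizer, inverted dropout on hidden
# activations, he_uniform initialization, L2 penalty on hidden-layer
# weights, early stopping on validation loss.  Base-R matrix code;
# gradients are verified against numerical differentiation in the tests.

sigmoid <- function(z) 1 / (1 + exp(-z))

he_uniform_init <- function(fan_in, fan_out) {
  limit <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

mlp_init <- function(n_in, n_out, hidden_layers, hidden_units) {
  dims <- c(n_in, rep(hidden_units, hidden_layers), n_out)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- he_uniform_init(dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b, dims = dims)
}

# forward pass; returns activations of every layer.  During training,
# inverted dropout masks are applied to hidden activations (never to the
# output layer).
mlp_forward <- function(net, x, dropout = 0, train = FALSE) {
  L <- length(net$W)
  a <- vector("list", L + 1L)
  masks <- vector("list", L)
  a[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      h <- pmax(z, 0)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(h), 1L, 1 - dropout) /
                         (1 - dropout),
                       nrow(h), ncol(h))
        h <- h * mask
        masks[[l]] <- mask
      }
      a[[l + 1L]] <- h
    } else {
      a[[l + 1L]] <- sigmoid(z)
    }
  }
  list(a = a, masks = masks)
}

# mean binary cross-entropy over all (row, label) cells, plus the L2 term
mlp_loss <- function(p, y, net = NULL, l2 = 0) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (l2 > 0 && !is.null(net) && length(net$W) > 1L) {
    hidden <- seq_len(length(net$W) - 1L)
    bce <- bce + l2 * sum(vapply(net$W[hidden],
                                 function(w) sum(w^2), 0))
  }
  bce
}

# gradients of the mean-BCE + L2 objective; fw is an mlp_forward() result
mlp_backward <- function(net, fw, y, l2 = 0) {
  L <- length(net$W)
  n_cells <- length(y)
  gW <- vector("list", L)
  gb <- vector("list", L)
  # d(loss)/d(z_out) for sigmoid + BCE mean over all cells
  delta <- (fw$a[[L + 1L]] - y) / n_cells
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * (fw$a[[l]] > 0)
    }
  }
  if (l2 > 0 && L > 1L) {
    for (l in seq_len(L - 1L)) gW[[l]] <- gW[[l]] + 2 * l2 * net$W[[l]]
  }
  list(W = gW, b = gb)
}

adam_state <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# Fit the network.  x: n x p features, y: n x k 0/1 labels.
mlp_fit <- function(x, y,
                    hidden_layers = 5L, hidden_units = 2048L,
                    dropout = 0.10, l2 = 1e-4, lr = 1e-3,
                    epochs = 50L, batch_size = 256L, patience = 5L,
                    validation_split = 0.2, seed = 1L, verbose = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == nrow(y))
  y <- as.matrix(y)
  with_seed(seed, {
    n <- nrow(x)
    # stratified internal validation split on the label matrix
    if (validation_split > 0 && n >= 10L) {
      sp <- stratified_multilabel_split(y, test_fraction = validation_split,
                                        seed = seed + 1L)
      idx_tr <- sp$train; idx_va <- sp$test
    } else {
      idx_tr <- seq_len(n); idx_va <- integer(0)
    }
    xt <- x[idx_tr, , drop = FALSE]; yt <- y[idx_tr, , drop = FALSE]
    xv <- x[idx_va, , drop = FALSE]; yv <- y[idx_va, , drop = FALSE]

    net <- mlp_init(ncol(x), ncol(y), hidden_layers, hidden_units)
    st <- adam_state(net)
    best <- list(net = net, loss = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    since_best <- 0L

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(nrow(xt))
      nb <- ceiling(nrow(xt) / batch_size)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * batch_size + 1L):
                      min(bi * batch_size, nrow(xt))]
        fw <- mlp_forward(net, xt[rows, , drop = FALSE],
                          dropout = dropout, train = TRUE)
        gr <- mlp_backward(net, fw, yt[rows, , drop = FALSE], l2 = l2)
        up <- adam_step(net, gr, st, lr)
        net <- up$net; st <- up$st
      }
      p_tr <- mlp_forward(net, xt)$a[[length(net$W) + 1L]]
      train_loss <- mlp_loss(p_tr, yt, net, l2)
      val_loss <- if (length(idx_va)) {
        p_va <- mlp_forward(net, xv)$a[[length(net$W) + 1L]]
        mlp_loss(p_va, yv, net, l2)
      } else train_loss
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop(sprintf(
          "training diverged at epoch %d: loss is not finite (lr=%g)",
          epoch, lr), call. = FALSE)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f",
                        epoch, train_loss, val_loss))
      }
      if (val_loss < best$loss - 1e-9) {
        best <- list(net = net, loss = val_loss, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
    }
    list(net = best$net, history = history, best_epoch = best$epoch,
         labels = colnames(y),
         config = list(hidden_layers = hidden_layers,
                       hidden_units = hidden_units, dropout = dropout,
                       l2 = l2, lr = lr, epochs = epochs,
                       batch_size = batch_size, patience = patience,
                       seed = seed))
  })
}

# predicted probabilities, dropout disabled
mlp_predict <- function(model, x) {
  p <- mlp_forward(model$net, x)$a[[length(model$net$W) + 1L]]
  colnames(p) <- model$labels
  rownames(p) <- rownames(x)
  p
}
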