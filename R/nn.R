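# Minimal feed-forward network engine: dense layers, gene-axis convolutions
# with max pooling, mean-absolute-error loss, L1 activity regularization and
# Adam.  All shapes are static (fixed at build time), which keeps the
# implementation to plain matrix algebra; the convolution is an im2col
# gather followed by a matrix product, with a precomputed sparse scatter
# matrix for the backward pass.
#
# Conventions: a batch of flat-encoded instances is a matrix X (n x G*T),
# gene-major with time fastest (flat entry (g-1)*T + t).  Inside the
# convolutional stack the time columns are folded into the batch dimension
# (N = n*T rows), activations are (N, G*C) matrices with gene fastest
# within channel, and kernels slide along the gene axis only.

.act_forward <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation: ", activation))
}

# derivative of activation expressed through the activation value a
.act_backward <- function(da, a, activation) {
  switch(activation,
         relu = da * (a > 0),
         sigmoid = da * a * (1 - a),
         linear = da,
         stop("unknown activation: ", activation))
}

.layer_dense <- function(n_in, n_out, activation = "relu", l1 = 0)
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       l1 = l1, W = NULL, b = NULL)

# Fold (n, G*T) flat input into (n*T, G) single-channel conv input.
.layer_fold_time <- function(n_genes, n_times)
  list(type = "fold_time", n_genes = n_genes, n_times = n_times)

# Unfold (n*T, G*C) conv activations into (n, T*G*C) for the dense head.
.layer_flatten <- function(n_genes, n_channels, n_times)
  list(type = "flatten", n_genes = n_genes, n_channels = n_channels,
       n_times = n_times, n_out = n_genes * n_channels * n_times)

# Same-padding convolution along the gene axis.  colmap gathers the im2col
# patches (index G*Cin + 1 addresses an all-zero padding column); scatter is
# its transpose as a sparse 0/1 matrix, used to push patch gradients back.
.layer_conv <- function(n_genes, in_ch, out_ch, kernel, activation = "relu") {
  pad_left <- (kernel - 1L) %/% 2L
  ncols <- n_genes * in_ch
  colmap <- integer(n_genes * kernel * in_ch)
  m <- 0L
  for (c in seq_len(in_ch)) {
    for (j in seq_len(kernel)) {
      for (g in seq_len(n_genes)) {
        gg <- g + j - 1L - pad_left
        m <- m + 1L
        colmap[m] <- if (gg >= 1L && gg <= n_genes)
          gg + n_genes * (c - 1L) else ncols + 1L
      }
    }
  }
  real <- colmap <= ncols
  scatter <- Matrix::sparseMatrix(i = which(real), j = colmap[real],
                                  x = 1, dims = c(length(colmap), ncols))
  list(type = "conv", n_genes = n_genes, in_ch = in_ch, out_ch = out_ch,
       kernel = kernel, activation = activation, colmap = colmap,
       scatter = scatter, W = NULL, b = NULL)
}

# Max pooling of size 2 along the gene axis, floor division (an odd last
# gene is dropped).
.layer_pool <- function(n_genes, n_channels) {
  gp <- n_genes %/% 2L
  if (gp < 1L) stop("gene axis too short to pool")
  g_out <- rep(seq_len(gp), n_channels)
  c_out <- rep(seq_len(n_channels), each = gp)
  list(type = "pool", n_genes = n_genes, n_channels = n_channels,
       n_out_genes = gp,
       idx1 = (c_out - 1L) * n_genes + 2L * g_out - 1L,
       idx2 = (c_out - 1L) * n_genes + 2L * g_out)
}

.glorot <- function(n_in, n_out, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

# Fill in weights using the current RNG stream.
.net_init <- function(net) {
  net$layers <- lapply(net$layers, function(ly) {
    if (ly$type == "dense") {
      ly$W <- .glorot(ly$n_in, ly$n_out, ly$n_in, ly$n_out)
      ly$b <- numeric(ly$n_out)
    } else if (ly$type == "conv") {
      n_in <- ly$kernel * ly$in_ch
      ly$W <- .glorot(n_in, ly$out_ch, n_in, ly$kernel * ly$out_ch)
      ly$b <- numeric(ly$out_ch)
    }
    ly
  })
  net
}

# Allocate zero-filled parameters (no RNG use); shapes only.
.net_alloc <- function(net) {
  net$layers <- lapply(net$layers, function(ly) {
    if (ly$type == "dense") {
      ly$W <- matrix(0, ly$n_in, ly$n_out); ly$b <- numeric(ly$n_out)
    } else if (ly$type == "conv") {
      ly$W <- matrix(0, ly$kernel * ly$in_ch, ly$out_ch)
      ly$b <- numeric(ly$out_ch)
    }
    ly
  })
  net
}

# Forward pass; returns the output and per-layer caches for backprop.
.net_forward <- function(net, X) {
  n <- nrow(X)
  a <- X
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      z <- a %*% ly$W + rep(ly$b, each = nrow(a))
      out <- .act_forward(z, ly$activation)
      caches[[i]] <- list(input = a, a = out)
      a <- out
    } else if (ly$type == "fold_time") {
      dim(a) <- c(n, ly$n_times, ly$n_genes)
      dim(a) <- c(n * ly$n_times, ly$n_genes)
      caches[[i]] <- list(n = n)
    } else if (ly$type == "conv") {
      apad <- cbind(a, 0)
      B <- apad[, ly$colmap, drop = FALSE]
      dim(B) <- c(nrow(a) * ly$n_genes, ly$kernel * ly$in_ch)
      z <- B %*% ly$W + rep(ly$b, each = nrow(B))
      zc <- .act_forward(z, ly$activation)
      caches[[i]] <- list(B = B, a = zc, nrows = nrow(a))
      dim(zc) <- c(nrow(a), ly$n_genes * ly$out_ch)
      a <- zc
    } else if (ly$type == "pool") {
      a1 <- a[, ly$idx1, drop = FALSE]
      a2 <- a[, ly$idx2, drop = FALSE]
      mask <- a1 >= a2
      caches[[i]] <- list(mask = mask, n_in_cols = ncol(a))
      a <- pmax(a1, a2)
    } else if (ly$type == "flatten") {
      dim(a) <- c(nrow(a) / ly$n_times, ly$n_times * ncol(a))
      caches[[i]] <- NULL
    } else stop("unknown layer type")
  }
  list(output = a, caches = caches)
}

# Loss (MAE + L1 activity penalties, both averaged over the batch) and its
# gradients with respect to every weight and bias.
.net_backward <- function(net, X, Y) {
  fw <- .net_forward(net, X)
  n <- nrow(X)
  pred <- fw$output
  resid <- pred - Y
  loss <- mean(abs(resid))
  grads <- vector("list", length(net$layers))
  da <- sign(resid) / length(resid)
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cache <- fw$caches[[i]]
    if (ly$type == "dense") {
      a <- cache$a
      if (isTRUE(ly$l1 > 0)) {
        loss <- loss + ly$l1 * sum(abs(a)) / n
        da <- da + ly$l1 * sign(a) / n
      }
      dz <- .act_backward(da, a, ly$activation)
      grads[[i]] <- list(W = crossprod(cache$input, dz), b = colSums(dz))
      da <- dz %*% t(ly$W)
    } else if (ly$type == "flatten") {
      dim(da) <- c(nrow(da) * ly$n_times, ly$n_genes * ly$n_channels)
    } else if (ly$type == "pool") {
      dup <- matrix(0, nrow(da), cache$n_in_cols)
      dup[, ly$idx1] <- da * cache$mask
      dup[, ly$idx2] <- dup[, ly$idx2] + da * !cache$mask
      da <- dup
    } else if (ly$type == "conv") {
      a <- cache$a
      dz <- da
      dim(dz) <- dim(a)
      dz <- .act_backward(dz, a, ly$activation)
      grads[[i]] <- list(W = crossprod(cache$B, dz), b = colSums(dz))
      dB <- dz %*% t(ly$W)
      dim(dB) <- c(cache$nrows, ly$n_genes * ly$kernel * ly$in_ch)
      da <- as.matrix(dB %*% ly$scatter)
    } else if (ly$type == "fold_time") {
      dim(da) <- c(cache$n, ly$n_times * ncol(da))
    }
  }
  list(loss = loss, grads = grads)
}

.net_loss <- function(net, X, Y) .net_backward(net, X, Y)$loss

.net_predict <- function(net, X) .net_forward(net, X)$output

# -- Adam ------------------------------------------------------------------

.adam_init <- function(net) {
  list(t = 0L,
       m = lapply(net$layers, function(ly)
         if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0)),
       v = lapply(net$layers, function(ly)
         if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0)))
}

.adam_step <- function(net, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$W)) next
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- b1 * state$m[[i]][[p]] + (1 - b1) * g
      state$v[[i]][[p]] <- b2 * state$v[[i]][[p]] + (1 - b2) * g^2
      mhat <- state$m[[i]][[p]] / corr1
      vhat <- state$v[[i]][[p]] / corr2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon)
    }
  }
  list(net = net, state = state)
}

# Mini-batch Adam training.  init = FALSE keeps the supplied weights (used
# after grafting); epochs = 0 returns the (possibly freshly initialised)
# untouched network.
.net_train <- function(net, X, Y, cfg, init = TRUE) {
  set.seed(cfg$seed)
  if (init) net <- .net_init(net)
  if (cfg$epochs == 0L)
    return(list(net = net, history = numeric(0)))
  state <- .adam_init(net)
  n <- nrow(X)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      bg <- .net_backward(net, X[bi, , drop = FALSE], Y[bi, , drop = FALSE])
      upd <- .adam_step(net, bg$grads, state, cfg)
      net <- upd$net; state <- upd$state
      ep_loss <- ep_loss + bg$loss * length(bi)
    }
    history[ep] <- ep_loss / n
  }
  list(net = net, history = history)
}

# Flattened parameter access (used by the save/load bundle and by the
# finite-difference gradient tests).
.net_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly)
    if (!is.null(ly$W)) c(as.vector(ly$W), ly$b) else numeric(0)))
}

.net_set_params <- function(net, theta) {
  pos <- 0L
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (is.null(ly$W)) next
    nw <- length(ly$W); nb <- length(ly$b)
    net$layers[[i]]$W <- matrix(theta[pos + seq_len(nw)], nrow(ly$W), ncol(ly$W))
    pos <- pos + nw
    net$layers[[i]]$b <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  stopifnot(pos == length(theta))
  net
}

.net_n_params <- function(net) length(.net_get_params(net))
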