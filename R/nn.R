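# Compact CNN engine: im2col convolutions over BLAS, batch normalization,
# ReLU, residual adds, global average pooling, fully connected head, with
# full backpropagation. Feature maps are arrays of dim (S, C, N) where
# S = H*W spatial positions in column-major [H, W] order, C channels and
# N batch images.

.im2col_cache <- new.env(parent = emptyenv())

# Spatial gather indices for an im2col convolution lowering: a (P, K2)
# integer matrix of input positions (column-major [H, W] order), with 0
# marking zero padding. Batch- and channel-independent, so cached per
# layer geometry.
im2col_index <- function(H, W, K, stride, pad) {
  key <- paste(H, W, K, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2 * pad - K) %/% stride + 1
  Wo <- (W + 2 * pad - K) %/% stride + 1
  P <- Ho * Wo
  K2 <- K * K
  yo <- rep(seq_len(Ho) - 1L, times = Wo)
  xo <- rep(seq_len(Wo) - 1L, each = Ho)
  ky <- rep(seq_len(K) - 1L, times = K)     # kernel offsets, ky fastest
  kx <- rep(seq_len(K) - 1L, each = K)
  iy <- outer(yo * stride - pad, ky, "+")   # P x K2 input rows
  ix <- outer(xo * stride - pad, kx, "+")
  sp <- iy + 1L + ix * H                    # spatial linear index
  sp[iy < 0 | iy >= H | ix < 0 | ix >= W] <- 0L
  storage.mode(sp) <- "integer"
  out <- list(spi = sp, P = P, Ho = Ho, Wo = Wo, K2 = K2)
  .im2col_cache[[key]] <- out
  out
}

conv_forward <- function(X, H, W, layer, N) {
  ii <- im2col_index(H, W, layer$K, layer$stride, layer$pad)
  C <- dim(X)[2]
  M <- im2col_gather(X, ii$spi, H * W, C, N)    # (P*N, K2*C)
  Z <- M %*% layer$W                            # (P*N, Cout)
  if (!is.null(layer$b)) Z <- Z + rep(layer$b, each = nrow(Z))
  out <- reshape_pnc(Z, ii$P, N)                # (P, Cout, N)
  list(out = out, M = M, ii = ii, Hin = H, Win = W, cin = C)
}

conv_backward <- function(dOut, layer, cache, N, need_dx = TRUE) {
  ii <- cache$ii
  cout <- dim(dOut)[2]
  dZ <- reshape_pcn(dOut, ii$P, cout, N)        # (P*N, Cout)
  dW <- crossprod(cache$M, dZ)
  db <- if (!is.null(layer$b)) colSums(dZ) else NULL
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  dM <- dZ %*% t(layer$W)                       # (P*N, K2*C)
  dX <- col2im_scatter(dM, ii$spi, cache$Hin * cache$Win, cache$cin, N)
  list(dX = dX, dW = dW, db = db)
}

# Per-channel batch statistics over spatial and batch dimensions.
# Exposed because adaptive-BN recalibration is defined in terms of the
# batch mean and the unbiased (n - 1 denominator) variance.
bn_batch_stats <- function(X) {
  d <- dim(X)
  n <- d[1] * d[3]
  mom <- bn_moments(X, d[1], d[2], d[3])
  mu <- mom$s1 / n
  var_b <- pmax(mom$s2 / n - mu^2, 0)
  var_u <- if (n > 1) var_b * n / (n - 1) else var_b
  list(mean = mu, var = var_u, var_biased = var_b, n = n)
}

bn_forward <- function(X, layer, training, eps = 1e-5) {
  d <- dim(X)
  if (training) {
    st <- bn_batch_stats(X)
    mu <- st$mean; v <- st$var_biased
  } else {
    st <- NULL
    mu <- layer$run_mean; v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  f <- bn_fwd(X, mu, invstd, layer$gamma, layer$beta, d[1], d[2], d[3])
  list(out = f$out, Xhat = f$Xhat, invstd = invstd, stats = st)
}

bn_backward <- function(dOut, layer, cache) {
  d <- dim(dOut)
  bn_bwd(dOut, cache$Xhat, cache$invstd, layer$gamma, d[1], d[2], d[3])
}

relu_forward <- function(X) {
  out <- relu_fwd(X)
  list(out = out)
}

gap_forward <- function(X) {
  S <- dim(X)[1]
  list(out = colSums(X, dims = 1) / S, S = S)   # (C, N)
}

fc_forward <- function(Xp, layer) {
  t(Xp) %*% layer$W + rep(layer$b, each = dim(Xp)[2])   # (N, classes)
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass. Returns logits plus (optionally) the caches needed
# for backpropagation, the Grad-CAM target activations, and per-BN batch
# statistics when `collect_bn` is TRUE.
net_forward <- function(net, X, training = FALSE, keep_cache = FALSE,
                        collect_bn = FALSE) {
  N <- dim(X)[3]
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  bn_stats <- if (collect_bn) list() else NULL
  saved <- list()
  H <- net$input_side; W <- net$input_side
  A <- X
  cam <- NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(A, H, W, ly, N)
      A <- cf$out; H <- cf$ii$Ho; W <- cf$ii$Wo
      if (keep_cache) caches[[i]] <- cf[c("M", "ii", "Hin", "Win", "cin")]
    } else if (ly$type == "bn") {
      bf <- bn_forward(A, ly, training)
      A <- bf$out
      if (collect_bn) bn_stats[[ly$name]] <- bf$stats
      if (keep_cache) caches[[i]] <- bf[c("Xhat", "invstd")]
    } else if (ly$type == "relu") {
      A <- relu_forward(A)$out
      if (keep_cache) caches[[i]] <- list(out = A)
    } else if (ly$type == "add") {
      A <- A + saved[[ly$from]]
      if (keep_cache) caches[[i]] <- list(from = ly$from)
    } else if (ly$type == "save") {
      saved[[ly$tag]] <- A
    } else if (ly$type == "gap") {
      gf <- gap_forward(A)
      if (keep_cache) caches[[i]] <- list(S = gf$S, Hin = H, Win = W)
      cam_dims <- c(H, W)
      A <- gf$out
    } else if (ly$type == "fc") {
      fc_input <- A
      A <- fc_forward(A, ly)
    } else stop("unknown layer type: ", ly$type)
    if (!is.null(ly$cam_target) && ly$cam_target) {
      cam <- list(act = A, H = H, W = W)
    }
  }
  list(logits = A, caches = caches, cam = cam, bn_stats = bn_stats,
       fc_input = if (keep_cache) fc_input else NULL)
}

# Backward pass from d(loss)/d(logits); returns gradients aligned with the
# layer list (same structure as net_forward's caches).
net_backward <- function(net, fwd, dlogits) {
  n_l <- length(net$layers)
  grads <- vector("list", n_l)
  dA <- dlogits
  d_saved <- list()
  for (i in rev(seq_len(n_l))) {
    ly <- net$layers[[i]]
    ch <- fwd$caches[[i]]
    if (ly$type == "fc") {
      # dA: (N, classes); activations into fc were (C, N)
      Xp <- fwd$fc_input
      grads[[i]] <- list(dW = Xp %*% dA, db = colSums(dA))
      dA <- ly$W %*% t(dA)                      # (C, N)
    } else if (ly$type == "gap") {
      C <- dim(dA)[1]; N <- dim(dA)[2]
      dA <- array(rep(dA, each = ch$S) / ch$S, c(ch$S, C, N))
    } else if (ly$type == "relu") {
      dA <- relu_bwd(dA, ch$out)
    } else if (ly$type == "add") {
      d_saved[[ch$from]] <- (d_saved[[ch$from]] %||% 0) + dA
    } else if (ly$type == "save") {
      extra <- d_saved[[ly$tag]]
      if (!is.null(extra)) dA <- dA + extra
      d_saved[[ly$tag]] <- NULL
    } else if (ly$type == "bn") {
      bb <- bn_backward(dA, ly, ch)
      grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      dA <- bb$dX
    } else if (ly$type == "conv") {
      N <- dim(dA)[3]
      cb <- conv_backward(dA, ly, ch, N, need_dx = i > 1)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dX
    }
  }
  grads
}

trainable_names <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    ps <- switch(ly$type,
                 conv = c("W", if (!is.null(ly$b)) "b"),
                 bn = c("gamma", "beta"),
                 fc = c("W", "b"),
                 NULL)
    for (p in ps) out[[length(out) + 1]] <- c(i, p)
  }
  out
}

grad_field <- function(g, p) {
  switch(p, W = g$dW, b = g$db, gamma = g$dgamma, beta = g$dbeta)
}

sgd_step <- function(net, grads, vel, lr, momentum) {
  for (tp in trainable_names(net)) {
    i <- as.integer(tp[1]); p <- tp[2]
    g <- grad_field(grads[[i]], p)
    key <- paste0(i, ".", p)
    v <- momentum * (vel[[key]] %||% 0) - lr * g
    vel[[key]] <- v
    net$layers[[i]][[p]] <- net$layers[[i]][[p]] + v
  }
  list(net = net, vel = vel)
}

update_running_bn <- function(net, fwd, momentum = 0.1) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "bn") {
      st <- fwd$bn_stats[[ly$name]]
      if (!is.null(st)) {
        net$layers[[i]]$run_mean <- (1 - momentum) * ly$run_mean +
          momentum * st$mean
        net$layers[[i]]$run_var <- (1 - momentum) * ly$run_var +
          momentum * st$var
      }
    }
  }
  net
}

count_net_params <- function(net) {
  tot <- 0
  for (tp in trainable_names(net)) {
    i <- as.integer(tp[1])
    tot <- tot + length(net$layers[[i]][[tp[2]]])
  }
  tot
}
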