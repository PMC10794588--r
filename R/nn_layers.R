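# Internal neural-network primitives: a small feed-forward engine with
# hand-written backpropagation, plus the adaptive-moment optimizer.
#
# A network is list(layers = list(...)). Each layer is one of
#   list(type = "linear", par = list(W, b))
#   list(type = "bn", par = list(gamma, beta),
#        buf = list(mean, var), momentum, eps)
#   list(type = "tanh") / list(type = "relu")
# Parameter leaves always live under $par so the optimizer can walk the
# tree; normalization buffers live under $buf and are not optimized.

.bnMomentum <- 0.1
.bnEps <- 1e-5

initLinear <- function(fanIn, fanOut) {
  # Uniform fan-in scaling, the convention used by mainstream deep-learning
  # frameworks for linear layers.
  bound <- 1 / sqrt(fanIn)
  list(type = "linear",
       par = list(W = matrix(stats::runif(fanIn * fanOut, -bound, bound),
                             fanIn, fanOut),
                  b = stats::runif(fanOut, -bound, bound)))
}

initBN <- function(width) {
  list(type = "bn",
       par = list(gamma = rep(1, width), beta = rep(0, width)),
       buf = list(mean = rep(0, width), var = rep(1, width)),
       momentum = .bnMomentum, eps = .bnEps)
}

# Forward pass through the layer list. X is a B x d matrix. Returns the
# output, per-layer caches for the backward pass, and the network with
# updated batch-norm running statistics (training mode only).
mlpForward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "linear") {
      caches[[li]] <- list(X = X)
      X <- X %*% layer$par$W
      X <- X + rep(layer$par$b, each = nrow(X))
    } else if (layer$type == "bn") {
      if (training) {
        if (nrow(X) < 2L)
          stop("batch normalization needs a batch of at least 2",
               call. = FALSE)
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        v <- pmax(v, 0)
        layer$buf$mean <- (1 - layer$momentum) * layer$buf$mean +
          layer$momentum * mu
        layer$buf$var <- (1 - layer$momentum) * layer$buf$var +
          layer$momentum * v
        net$layers[[li]] <- layer
      } else {
        mu <- layer$buf$mean
        v <- layer$buf$var
      }
      invStd <- 1 / sqrt(v + layer$eps)
      n <- nrow(X)
      # column-recycled arithmetic (rep each = n) instead of sweep: same
      # result, far fewer intermediate copies
      xhat <- (X - rep(mu, each = n)) * rep(invStd, each = n)
      caches[[li]] <- list(xhat = xhat, invStd = invStd)
      X <- xhat * rep(layer$par$gamma, each = n) +
        rep(layer$par$beta, each = n)
    } else if (layer$type == "tanh") {
      X <- tanh(X)
      caches[[li]] <- list(Y = X)
    } else if (layer$type == "relu") {
      X <- pmax(X, 0)
      caches[[li]] <- list(Y = X)
    } else stop("unknown layer type: ", layer$type)
  }
  list(out = X, caches = caches, net = net)
}

# Backward pass. dOut is the gradient w.r.t. the network output (same shape).
# Returns gradients shaped like each layer's $par and the gradient w.r.t.
# the input. Batch-norm gradients use training-mode (batch statistics)
# semantics, matching the forward pass used during optimization.
mlpBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    cache <- caches[[li]]
    if (layer$type == "linear") {
      grads[[li]] <- list(par = list(W = crossprod(cache$X, dOut),
                                     b = colSums(dOut)))
      dOut <- tcrossprod(dOut, layer$par$W)
    } else if (layer$type == "bn") {
      xhat <- cache$xhat
      n <- nrow(xhat)
      dgamma <- colSums(dOut * xhat)
      dbeta <- colSums(dOut)
      dxhat <- dOut * rep(layer$par$gamma, each = n)
      dOut <- (dxhat - rep(colMeans(dxhat), each = n) -
                 xhat * rep(colMeans(dxhat * xhat), each = n)) *
        rep(cache$invStd, each = n)
      grads[[li]] <- list(par = list(gamma = dgamma, beta = dbeta))
    } else if (layer$type == "tanh") {
      dOut <- dOut * (1 - cache$Y^2)
    } else if (layer$type == "relu") {
      dOut <- dOut * (cache$Y > 0)
    }
  }
  list(grads = grads, dX = dOut)
}

# ---- adaptive-moment optimizer over nested parameter trees ----------------

adamInit <- function(par) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) x * 0
    else NULL
  }
  list(m = walk(par), v = walk(par), t = 0L)
}

# One optimizer step over a nested parameter tree. The gradient tree must be
# shape-aligned with the parameter tree; NULL gradients (frozen or unused
# parameters, non-numeric leaves) leave the parameter and its moments
# untouched. The walk is positional so unnamed layer lists work.
adamStep <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.list(g)) return(list(p = p, m = m, v = v))
      if (!is.null(names(g)) && !is.null(names(p))) {
        for (nm in names(g)) {
          if (is.null(g[[nm]]) || !nm %in% names(p)) next
          res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
          p[[nm]] <- res$p
          m[[nm]] <- res$m
          v[[nm]] <- res$v
        }
        return(list(p = p, m = m, v = v))
      }
      for (ii in seq_along(g)) {
        gi <- g[[ii]]
        if (is.null(gi)) next
        res <- walk(p[[ii]], gi, m[[ii]], v[[ii]])
        p[[ii]] <- res$p
        m[[ii]] <- res$m
        v[[ii]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (!is.numeric(p)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- walk(par, grad, state$m, state$v)
  list(par = res$p, state = list(m = res$m, v = res$v, t = t))
}
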