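#' @include utils.R
NULL

# Minimal convolutional-network core used by the cGAN models. Tensors are
# numeric arrays with dim = c(H, W, C, N). Convolutions run through the
# compiled im2col/GEMM kernels; normalization, activations and the Adam
# optimizer live here. Every layer exposes a forward returning (out, cache)
# and a backward mapping (cache, grad_out) -> (grad_in, parameter grads);
# gradients are verified against finite differences in the test suite.

# ---- layer constructors ----------------------------------------------------

newConvLayer <- function(k, cin, cout, stride = 2L, pad = 1L) {
  w <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(type = "conv", k = k, stride = as.integer(stride),
       pad = as.integer(pad),
       params = list(W = w, b = numeric(cout)))
}

newBINLayer <- function(c) {
  list(type = "bin",
       params = list(gamma = rep(1, c), beta = rep(0, c), rho = rep(0.5, c)),
       stats = list(mean = rep(0, c), var = rep(1, c), momentum = 0.1))
}

newBNLayer <- function(c) {
  list(type = "bn", params = list(gamma = rep(1, c), beta = rep(0, c)),
       stats = list(mean = rep(0, c), var = rep(1, c), momentum = 0.1))
}

newFCLayer <- function(din, dout = 1L) {
  list(type = "fc",
       params = list(W = matrix(rnorm(dout * din, 0, sqrt(1 / din)),
                                dout, din),
                     b = numeric(dout)))
}

# ---- conv ------------------------------------------------------------------

convForward <- function(layer, x) {
  out <- .conv2dForward(x, layer$params$W, layer$params$b, layer$stride,
                        layer$pad)
  list(out = out, cache = x)
}

convBackward <- function(layer, cache, gout) {
  g <- .conv2dBackward(cache, layer$params$W, gout, layer$stride, layer$pad)
  list(dx = g$dx, grads = list(W = g$dw, b = g$db))
}

# ---- normalization ---------------------------------------------------------

# Batch-instance normalization: a per-channel learnable mix rho between
# batch normalization (statistics over batch and space) and instance
# normalization (statistics over space, per sample), followed by the usual
# affine scale/shift: y = gamma * (rho * BN(x) + (1 - rho) * IN(x)) + beta.
# The heavy lifting runs in the compiled kernels. In training mode the BN
# component uses minibatch statistics and updates the layer's running
# mean/variance; in evaluation mode it uses the running statistics, so a
# single patch is normalized consistently with training. The IN component
# always uses per-sample instance statistics.
binForward <- function(layer, x, training = TRUE, eps = 1e-5) {
  p <- layer$params
  if (!training)
    return(list(out = .binEvalC(x, p$gamma, p$beta, p$rho,
                                layer$stats$mean, layer$stats$var, eps),
                cache = NULL, stats = layer$stats))
  f <- .binForwardC(x, p$gamma, p$beta, p$rho, eps)
  m <- layer$stats$momentum
  stats <- layer$stats
  stats$mean <- (1 - m) * stats$mean + m * f$mB
  stats$var <- (1 - m) * stats$var + m * f$vB
  list(out = f$out,
       cache = list(xhatB = f$xhatB, xhatI = f$xhatI, sI = f$sI, sB = f$sB),
       stats = stats)
}

binBackward <- function(layer, cache, gout) {
  p <- layer$params
  b <- .binBackwardC(gout, cache$xhatB, cache$xhatI, cache$sI, cache$sB,
                     p$gamma, p$rho)
  list(dx = b$dx,
       grads = list(gamma = b$dgamma, beta = b$dbeta, rho = b$drho))
}

# Plain batch normalization (discriminator layers), with the same
# training / evaluation statistic handling as the BIN layers.
bnForward <- function(layer, x, training = TRUE, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  p <- layer$params
  xm <- matrix(x, HW, C * N)
  if (!training) {
    mB <- layer$stats$mean; sB <- sqrt(pmax(layer$stats$var, 0) + eps)
    xhat <- (xm - rep(rep(mB, N), each = HW)) / rep(rep(sB, N), each = HW)
    y <- rep(rep(p$gamma, N), each = HW) * xhat +
      rep(rep(p$beta, N), each = HW)
    return(list(out = array(y, dim = d), cache = NULL,
                stats = layer$stats))
  }
  mI <- .colMeans(xm, HW, C * N)
  eI2 <- .colMeans(xm * xm, HW, C * N)
  mB <- .rowMeans(matrix(mI, C, N), C, N)
  vB <- pmax(.rowMeans(matrix(eI2, C, N), C, N) - mB^2, 0)
  sB <- sqrt(vB + eps)
  xhat <- (xm - rep(rep(mB, N), each = HW)) / rep(rep(sB, N), each = HW)
  y <- rep(rep(p$gamma, N), each = HW) * xhat + rep(rep(p$beta, N), each = HW)
  m <- layer$stats$momentum
  stats <- layer$stats
  stats$mean <- (1 - m) * stats$mean + m * mB
  stats$var <- (1 - m) * stats$var + m * vB
  list(out = array(y, dim = d), cache = list(xhat = xhat, sB = sB, d = d),
       stats = stats)
}

bnBackward <- function(layer, cache, gout) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  p <- layer$params
  gy <- matrix(gout, HW, C * N)
  xhat <- cache$xhat
  per_channel <- function(v_cn) .rowSums(matrix(v_cn, C, N), C, N)
  dgamma <- per_channel(.colSums(gy * xhat, HW, C * N))
  dbeta <- per_channel(.colSums(gy, HW, C * N))
  dxhat <- gy * rep(rep(p$gamma, N), each = HW)
  m1 <- per_channel(.colMeans(dxhat, HW, C * N)) / N
  m2 <- per_channel(.colMeans(dxhat * xhat, HW, C * N)) / N
  dx <- (dxhat - rep(rep(m1, N), each = HW) -
           xhat * rep(rep(m2, N), each = HW)) /
    rep(rep(cache$sB, N), each = HW)
  list(dx = array(dx, dim = d), grads = list(gamma = dgamma, beta = dbeta))
}

#' Batch-instance normalization of a tensor
#'
#' Functional form of the normalization used by the generator's
#' convolutional layers: a per-channel convex mix between batch
#' normalization (statistics pooled over batch and space) and instance
#' normalization (statistics per sample over space), then an affine
#' scale/shift. `rho = 1` reduces to batch normalization, `rho = 0` to
#' instance normalization.
#'
#' @param x numeric array, dim (H, W, C, N).
#' @param rho per-channel mix weights in \[0, 1\] (recycled to C).
#' @param scale,shift per-channel affine parameters (recycled to C).
#' @param eps variance stabilizer.
#' @return normalized array of the same shape.
#' @export
batchInstanceNorm <- function(x, rho = 0.5, scale = 1, shift = 0,
                              eps = 1e-5) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  C <- dim(x)[3]
  layer <- list(type = "bin",
                params = list(gamma = rep(scale, length.out = C),
                              beta = rep(shift, length.out = C),
                              rho = rep(rho, length.out = C)))
  binForward(layer, x, eps = eps)$out
}

# ---- activations -----------------------------------------------------------

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(cache, gout) gout * cache

lreluForward <- function(x, slope) {
  neg <- x < 0
  out <- x
  out[neg] <- slope * x[neg]
  list(out = out, cache = neg)
}
lreluBackward <- function(cache, gout, slope) {
  gout[cache] <- slope * gout[cache]
  gout
}

tanhForward <- function(x) { y <- tanh(x); list(out = y, cache = y) }
tanhBackward <- function(cache, gout) gout * (1 - cache^2)

# ---- fully connected -------------------------------------------------------

fcForward <- function(layer, x) {
  d <- dim(x)
  xf <- matrix(x, prod(d[1:3]), d[4])
  list(out = layer$params$W %*% xf + layer$params$b, cache = list(xf = xf,
                                                                 d = d))
}

fcBackward <- function(layer, cache, gout) {
  dW <- gout %*% t(cache$xf)
  db <- rowSums(gout)
  dx <- array(t(layer$params$W) %*% gout, dim = cache$d)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- channel plumbing ------------------------------------------------------

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

splitChannels <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- optimizer -------------------------------------------------------------

newAdamState <- function() list(t = 0L, m = list(), v = list())

# Global-norm gradient clipping over a nested grads list.
clipGradients <- function(grads, clip_norm) {
  ss <- 0
  for (lg in grads) for (g in lg) ss <- ss + sum(g * g)
  gn <- sqrt(ss)
  if (is.finite(gn) && gn > clip_norm) {
    sc <- clip_norm / gn
    grads <- lapply(grads, function(lg) lapply(lg, function(g) g * sc))
  }
  attr(grads, "norm") <- gn
  grads
}

# One Adam step over a network's layers; returns the updated network and
# optimizer state. rho mix weights are clamped to [0, 1] after the update.
adamStep <- function(layers, grads, opt, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      g <- grads[[ln]][[pn]]
      key <- paste0(ln, ".", pn)
      m <- opt$m[[key]]; v <- opt$v[[key]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      opt$m[[key]] <- m; opt$v[[key]] <- v
      step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      layers[[ln]]$params[[pn]] <- layers[[ln]]$params[[pn]] - step
      if (pn == "rho")
        layers[[ln]]$params[[pn]] <- clampRange(layers[[ln]]$params[[pn]],
                                                0, 1)
    }
  }
  list(layers = layers, opt = opt)
}
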