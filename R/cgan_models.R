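#' @include AllClasses.R nn_core.R
NULL

# Generator and discriminator construction plus forward/backward passes for
# the three conditioning variants. The generator is a backbone of four
# stride-2 convolutions (kernel 4, padding 1) reducing the fine cyto grid
# onto the receptor grid with 64 output channels, followed by a three-level
# U-Net head; batch-instance norm + ReLU after every convolution, tanh on
# the output. The discriminator stacks kernel-4/stride-2/padding-1
# convolutions with batch norm + LeakyReLU(0.2) and a terminal fully
# connected layer producing one logit per patch.

nInputChannels <- function(variant) {
  # cyto + noise Z, plus one constant area channel for the conditional
  # multi-area variant only
  if (variant == "cond_multi_area") 3L else 2L
}

conditionValue <- function(condition) {
  if (is.null(condition)) stop("condition label required for this variant")
  v <- c(V1 = 0, M1 = 1)[as.character(condition)]
  if (anyNA(v)) stop("condition must be 'V1' or 'M1'")
  unname(v)
}

#' Build a generator instance
#'
#' Instantiates the generator network described by a [GeneratorSpec-class]
#' with deterministic, seed-controlled weight initialization.
#'
#' @param spec a [GeneratorSpec-class].
#' @param seed initialization seed.
#' @return a `cganGenerator` object (opaque parameter container).
#' @examples
#' gen <- buildGenerator(generatorSpec(input_side_px = 256,
#'                                    output_side_px = 16), seed = 1)
#' @export
buildGenerator <- function(spec, seed = 1L) {
  validObject(spec)
  fac <- spec@input_side_px / spec@output_side_px
  if (fac != round(fac) || bitwAnd(as.integer(fac), as.integer(fac) - 1L))
    stop("input/output reduction factor must be a power of 2")
  bb <- spec@backbone_channels
  un <- spec@unet_channels
  cin <- nInputChannels(spec@variant)
  layers <- withSeed(seed, {
    L <- list()
    prev <- cin
    for (i in seq_along(bb)) {
      L[[paste0("bb_conv", i)]] <- newConvLayer(4L, prev, bb[i], 2L, 1L)
      L[[paste0("bb_bin", i)]] <- newBINLayer(bb[i])
      prev <- bb[i]
    }
    c1 <- un[1]; c2 <- un[2]; c3 <- un[3]
    L$e1c <- newConvLayer(3L, prev, c1, 1L, 1L); L$e1n <- newBINLayer(c1)
    L$d1c <- newConvLayer(4L, c1, c2, 2L, 1L);   L$d1n <- newBINLayer(c2)
    L$e2c <- newConvLayer(3L, c2, c2, 1L, 1L);   L$e2n <- newBINLayer(c2)
    L$d2c <- newConvLayer(4L, c2, c3, 2L, 1L);   L$d2n <- newBINLayer(c3)
    L$bc <- newConvLayer(3L, c3, c3, 1L, 1L);    L$bn <- newBINLayer(c3)
    L$u2c <- newConvLayer(3L, c3, c2, 1L, 1L);   L$u2n <- newBINLayer(c2)
    L$m2c <- newConvLayer(3L, 2L * c2, c2, 1L, 1L); L$m2n <- newBINLayer(c2)
    L$u1c <- newConvLayer(3L, c2, c1, 1L, 1L);   L$u1n <- newBINLayer(c1)
    L$m1c <- newConvLayer(3L, 2L * c1, c1, 1L, 1L); L$m1n <- newBINLayer(c1)
    L$oc <- newConvLayer(3L, c1, 1L, 1L, 1L)
    L
  })
  structure(list(spec = spec, layers = layers, seed = seed),
            class = "cganGenerator")
}

#' @export
print.cganGenerator <- function(x, ...) {
  np <- sum(vapply(x$layers,
                   function(l) sum(lengths(lapply(l$params, length))),
                   numeric(1)))
  cat(sprintf("cganGenerator [%s] %d^2 -> %d^2, %d parameters\n",
              x$spec@variant, x$spec@input_side_px, x$spec@output_side_px,
              np))
  invisible(x)
}

#' Build a discriminator instance
#'
#' @param spec a [DiscriminatorSpec-class].
#' @param seed initialization seed.
#' @return a `cganDiscriminator` object.
#' @export
buildDiscriminator <- function(spec, seed = 1L) {
  validObject(spec)
  side <- spec@input_side_px
  cin <- if (spec@conditional) 2L else 1L
  layers <- withSeed(seed, {
    L <- list()
    prev <- cin
    for (i in seq_len(spec@n_layers)) {
      L[[paste0("conv", i)]] <- newConvLayer(4L, prev, spec@channels[i],
                                             2L, 1L)
      L[[paste0("bn", i)]] <- newBNLayer(spec@channels[i])
      prev <- spec@channels[i]
      side <- side %/% 2L
    }
    L$fc <- newFCLayer(side * side * prev, 1L)
    L
  })
  structure(list(spec = spec, layers = layers, seed = seed),
            class = "cganDiscriminator")
}

#' @export
print.cganDiscriminator <- function(x, ...) {
  cat(sprintf("cganDiscriminator %d^2 input, %d conv layers%s\n",
              x$spec@input_side_px, x$spec@n_layers,
              if (x$spec@conditional) " (conditional)" else ""))
  invisible(x)
}

# ---- generator forward / backward (training internals) ---------------------

# Full forward pass on an assembled input tensor (H, W, Cin, N); returns
# the output in (-1, 1) plus every cache needed for backpropagation, the
# backbone feature map, and (in training mode) the network with updated
# normalization running statistics.
genForwardCore <- function(gen, xin, training = TRUE) {
  L <- gen$layers
  cc <- list()
  x <- xin
  nb <- length(gen$spec@backbone_channels)
  for (i in seq_len(nb)) {
    f <- convForward(L[[paste0("bb_conv", i)]], x)
    cc[[paste0("bb_conv", i)]] <- f$cache
    n <- binForward(L[[paste0("bb_bin", i)]], f$out, training)
    cc[[paste0("bb_bin", i)]] <- n$cache
    L[[paste0("bb_bin", i)]]$stats <- n$stats
    r <- reluForward(n$out)
    cc[[paste0("bb_relu", i)]] <- r$cache
    x <- r$out
  }
  backbone <- x
  blk <- function(conv, norm, x, tag) {
    f <- convForward(L[[conv]], x); cc[[conv]] <<- f$cache
    n <- binForward(L[[norm]], f$out, training); cc[[norm]] <<- n$cache
    L[[norm]]$stats <<- n$stats
    r <- reluForward(n$out); cc[[paste0(tag, "_relu")]] <<- r$cache
    r$out
  }
  e1 <- blk("e1c", "e1n", x, "e1")
  t <- blk("d1c", "d1n", e1, "d1")
  e2 <- blk("e2c", "e2n", t, "e2")
  t <- blk("d2c", "d2n", e2, "d2")
  b <- blk("bc", "bn", t, "b")
  t <- .upsample2Forward(b)
  t <- blk("u2c", "u2n", t, "u2")
  t <- concatChannels(t, e2)
  t <- blk("m2c", "m2n", t, "m2")
  t <- .upsample2Forward(t)
  t <- blk("u1c", "u1n", t, "u1")
  t <- concatChannels(t, e1)
  t <- blk("m1c", "m1n", t, "m1")
  f <- convForward(L$oc, t); cc$oc <- f$cache
  th <- tanhForward(f$out); cc$tanh <- th$cache
  gen$layers <- L
  list(out = th$out, caches = cc, backbone = backbone, gen = gen)
}

genBackwardCore <- function(gen, caches, gout) {
  L <- gen$layers
  G <- list()
  blkBack <- function(conv, norm, tag, g) {
    g <- reluBackward(caches[[paste0(tag, "_relu")]], g)
    nb <- binBackward(L[[norm]], caches[[norm]], g)
    G[[norm]] <<- nb$grads
    cb <- convBackward(L[[conv]], caches[[conv]], nb$dx)
    G[[conv]] <<- cb$grads
    cb$dx
  }
  g <- tanhBackward(caches$tanh, gout)
  cb <- convBackward(L$oc, caches$oc, g)
  G$oc <- cb$grads
  g <- blkBack("m1c", "m1n", "m1", cb$dx)
  sp <- splitChannels(g, dim(g)[3] %/% 2L)
  g_e1_skip <- sp$b
  g <- blkBack("u1c", "u1n", "u1", sp$a)
  g <- .upsample2Backward(g)
  g <- blkBack("m2c", "m2n", "m2", g)
  sp <- splitChannels(g, dim(g)[3] %/% 2L)
  g_e2_skip <- sp$b
  g <- blkBack("u2c", "u2n", "u2", sp$a)
  g <- .upsample2Backward(g)
  g <- blkBack("bc", "bn", "b", g)
  g <- blkBack("d2c", "d2n", "d2", g)
  g <- blkBack("e2c", "e2n", "e2", g + g_e2_skip)
  g <- blkBack("d1c", "d1n", "d1", g)
  g <- blkBack("e1c", "e1n", "e1", g + g_e1_skip)
  nb <- length(gen$spec@backbone_channels)
  for (i in rev(seq_len(nb))) {
    g <- reluBackward(caches[[paste0("bb_relu", i)]], g)
    nbk <- binBackward(L[[paste0("bb_bin", i)]],
                       caches[[paste0("bb_bin", i)]], g)
    G[[paste0("bb_bin", i)]] <- nbk$grads
    cbk <- convBackward(L[[paste0("bb_conv", i)]],
                        caches[[paste0("bb_conv", i)]], nbk$dx)
    G[[paste0("bb_conv", i)]] <- cbk$grads
    g <- cbk$dx
  }
  list(grads = G, dx = g)
}

# Assemble the generator input tensor from cyto patches (already scaled to
# [-1, 1]), a noise tensor and an optional condition value.
assembleGenInput <- function(gen, cyto, z, condition = NULL) {
  d <- dim(cyto)
  variant <- gen$spec@variant
  if (variant == "cond_multi_area") {
    if (is.null(condition) || length(condition) == 0)
      stop("condition label required for the conditional variant")
    cv <- vapply(condition, conditionValue, numeric(1))
    cch <- array(rep(cv, each = d[1] * d[2]), dim = c(d[1], d[2], 1, d[4]))
    xin <- array(0, dim = c(d[1], d[2], 3, d[4]))
    xin[, , 1, ] <- cyto; xin[, , 2, ] <- z; xin[, , 3, ] <- cch
  } else {
    if (!is.null(condition))
      stop("condition supplied to a non-conditional variant")
    xin <- array(0, dim = c(d[1], d[2], 2, d[4]))
    xin[, , 1, ] <- cyto; xin[, , 2, ] <- z
  }
  xin
}

#' Generator forward pass
#'
#' Runs one or more cyto patches through the generator: the input tensor
#' concatenates the cyto patch (rescaled from \[0, 1\] to \[-1, 1\]), a
#' per-pixel standard-normal noise channel drawn from `noise_seed`, and --
#' for the conditional multi-area variant only -- a constant area channel
#' (V1 = 0, M1 = 1). Output values are mapped back to \[0, 1\] unless
#' `rescale = FALSE`, in which case the raw tanh range (-1, 1) is
#' returned.
#'
#' @param gen a generator from [buildGenerator()].
#' @param cyto_patch numeric matrix (one patch) or array (H, W, N).
#' @param noise_seed seed for the noise tensor; the forward pass is a pure
#'   function of (parameters, inputs, seed).
#' @param condition area label(s), required iff the variant is
#'   `cond_multi_area`.
#' @param rescale return intensities on \[0, 1\] (default TRUE).
#' @return predicted receptor patch matrix (or (H, W, N) array for N > 1).
#' @export
generatorForward <- function(gen, cyto_patch, noise_seed = 1L,
                             condition = NULL, rescale = TRUE) {
  x <- patchArray(cyto_patch, gen$spec@input_side_px)
  d <- dim(x)
  z <- withSeed(noise_seed,
                array(rnorm(prod(d)), dim = d))
  xin <- assembleGenInput(gen, 2 * x - 1, z, condition)
  out <- genForwardCore(gen, xin, training = FALSE)$out
  y <- out[, , 1, , drop = TRUE]
  if (rescale) y <- (y + 1) / 2
  y
}

#' Backbone feature map of the generator
#'
#' Runs only the four-layer backbone and returns its feature map, the
#' (channels x side x side) tensor handed to the U-Net head -- 64 channels
#' at 128 x 128 for the default spec.
#'
#' @inheritParams generatorForward
#' @return array with dim (side, side, channels).
#' @export
generatorBackbone <- function(gen, cyto_patch, noise_seed = 1L,
                              condition = NULL) {
  x <- patchArray(cyto_patch, gen$spec@input_side_px)
  d <- dim(x)
  z <- withSeed(noise_seed, array(rnorm(prod(d)), dim = d))
  xin <- assembleGenInput(gen, 2 * x - 1, z, condition)
  L <- gen$layers
  t <- xin
  for (i in seq_along(gen$spec@backbone_channels)) {
    t <- convForward(L[[paste0("bb_conv", i)]], t)$out
    t <- binForward(L[[paste0("bb_bin", i)]], t, training = FALSE)$out
    t <- reluForward(t)$out
  }
  t[, , , 1, drop = TRUE]
}

patchArray <- function(x, expect_side) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  if (dim(x)[1] != expect_side || dim(x)[2] != expect_side)
    stop(sprintf("patch side %d does not match the spec input side %d",
                 dim(x)[1], expect_side))
  array(x, dim = c(dim(x)[1], dim(x)[2], 1, dim(x)[3]))
}

# ---- discriminator ---------------------------------------------------------

discForwardCore <- function(disc, xin, training = TRUE) {
  L <- disc$layers
  cc <- list()
  x <- xin
  for (i in seq_len(disc$spec@n_layers)) {
    f <- convForward(L[[paste0("conv", i)]], x)
    cc[[paste0("conv", i)]] <- f$cache
    n <- bnForward(L[[paste0("bn", i)]], f$out, training)
    cc[[paste0("bn", i)]] <- n$cache
    L[[paste0("bn", i)]]$stats <- n$stats
    r <- lreluForward(n$out, disc$spec@leaky_slope)
    cc[[paste0("lrelu", i)]] <- r$cache
    x <- r$out
  }
  f <- fcForward(L$fc, x)
  cc$fc <- f$cache
  disc$layers <- L
  list(logits = as.numeric(f$out), caches = cc, disc = disc)
}

discBackwardCore <- function(disc, caches, glogits) {
  L <- disc$layers
  G <- list()
  fb <- fcBackward(L$fc, caches$fc, matrix(glogits, nrow = 1))
  G$fc <- fb$grads
  g <- fb$dx
  for (i in rev(seq_len(disc$spec@n_layers))) {
    g <- lreluBackward(caches[[paste0("lrelu", i)]], g,
                       disc$spec@leaky_slope)
    nb <- bnBackward(L[[paste0("bn", i)]], caches[[paste0("bn", i)]], g)
    G[[paste0("bn", i)]] <- nb$grads
    cb <- convBackward(L[[paste0("conv", i)]], caches[[paste0("conv", i)]],
                       nb$dx)
    G[[paste0("conv", i)]] <- cb$grads
    g <- cb$dx
  }
  list(grads = G, dx = g)
}

assembleDiscInput <- function(disc, patches, condition = NULL) {
  d <- dim(patches)
  if (disc$spec@conditional) {
    if (is.null(condition) || length(condition) == 0)
      stop("condition label required for the conditional discriminator")
    cv <- vapply(condition, conditionValue, numeric(1))
    xin <- array(0, dim = c(d[1], d[2], 2, d[4]))
    xin[, , 1, ] <- patches
    xin[, , 2, ] <- array(rep(cv, each = d[1] * d[2]),
                          dim = c(d[1], d[2], 1, d[4]))
  } else {
    if (!is.null(condition))
      stop("condition supplied to a non-conditional discriminator")
    xin <- array(patches, dim = c(d[1], d[2], 1, d[4]))
  }
  xin
}

#' Discriminator forward pass
#'
#' Scores receptor-modality patches (intensities on \[0, 1\], internally
#' rescaled to the tanh range) with one scalar logit per patch.
#'
#' @param disc a discriminator from [buildDiscriminator()].
#' @param receptor_patch matrix (one patch) or (H, W, N) array.
#' @param condition area label(s) iff the discriminator is conditional.
#' @return numeric vector of logits, one per patch.
#' @export
discriminatorForward <- function(disc, receptor_patch, condition = NULL) {
  x <- patchArray(receptor_patch, disc$spec@input_side_px)
  xin <- assembleDiscInput(disc, 2 * x - 1, condition)
  discForwardCore(disc, xin, training = FALSE)$logits
}
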