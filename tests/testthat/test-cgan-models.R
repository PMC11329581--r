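# Network construction, shape contracts, conditioning plumbing and the
# batch-instance normalization boundary behavior.

test_that("generator shape contract holds across scaled specs", {
  for (sides in list(c(256L, 16L), c(512L, 32L))) {
    gen <- buildGenerator(generatorSpec(input_side_px = sides[1],
                                        output_side_px = sides[2]),
                          seed = 1)
    x <- matrix(runif(sides[1]^2), sides[1], sides[1])
    y <- generatorForward(gen, x, noise_seed = 2)
    expect_equal(dim(y), c(sides[2], sides[2]))
    expect_true(all(y >= 0 & y <= 1))
    bb <- generatorBackbone(gen, x, noise_seed = 2)
    expect_equal(dim(bb), c(sides[2], sides[2], 64L))
  }
  expect_error(generatorSpec(input_side_px = 256, output_side_px = 24),
               "2")
})

test_that("generator output is tanh-bounded, noise-dependent, seeded", {
  gen <- buildGenerator(tinyGenSpec(), seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  y1 <- generatorForward(gen, x, noise_seed = 10, rescale = FALSE)
  expect_true(all(y1 > -1 & y1 < 1))
  # same inputs + same seed -> bit-identical; different seeds -> differ
  y2 <- generatorForward(gen, x, noise_seed = 10, rescale = FALSE)
  expect_identical(y1, y2)
  y3 <- generatorForward(gen, x, noise_seed = 11, rescale = FALSE)
  expect_false(identical(y1, y3))
  # two seeded builds are bit-identical
  gen2 <- buildGenerator(tinyGenSpec(), seed = 3)
  expect_identical(gen$layers, gen2$layers)
})

test_that("condition channel is required exactly for the conditional variant", {
  gen_c <- buildGenerator(tinyGenSpec("cond_multi_area"), seed = 1)
  gen_u <- buildGenerator(tinyGenSpec("uncond_multi_area"), seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_error(generatorForward(gen_c, x, 1), "condition")
  expect_error(generatorForward(gen_u, x, 1, condition = "V1"),
               "non-conditional")
  expect_silent(generatorForward(gen_c, x, 1, condition = "M1"))
  expect_error(generatorForward(gen_c, x, 1, condition = "S1"), "V1")
})

test_that("conditional variant differs by exactly one first-layer slice", {
  nparams <- function(net) sum(vapply(net$layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
  gc <- buildGenerator(tinyGenSpec("cond_multi_area"), seed = 1)
  gu <- buildGenerator(tinyGenSpec("uncond_multi_area"), seed = 1)
  # one extra input channel = one extra k x k x 1 x Cout kernel slice
  expect_equal(nparams(gc) - nparams(gu), 4 * 4 * 2)  # k=4, Cout=2 (tiny)
  dc <- buildDiscriminator(discriminatorSpec(input_side_px = 16L,
                                             conditional = TRUE), 1)
  du <- buildDiscriminator(discriminatorSpec(input_side_px = 16L), 1)
  expect_equal(nparams(dc) - nparams(du), 4 * 4 * 8)  # k=4, Cout=8
})

test_that("discriminator produces one finite logit per patch", {
  disc <- buildDiscriminator(discriminatorSpec(input_side_px = 16L), 2)
  one <- discriminatorForward(disc, matrix(runif(256), 16, 16))
  expect_length(one, 1)
  expect_true(is.finite(one))
  batch <- array(runif(16 * 16 * 5), c(16, 16, 5))
  expect_length(discriminatorForward(disc, batch), 5)
  # all-zeros vs all-ones patches get different logits at random init
  diffs <- vapply(1:10, function(s) {
    d <- buildDiscriminator(discriminatorSpec(input_side_px = 16L), s)
    abs(discriminatorForward(d, matrix(0, 16, 16)) -
          discriminatorForward(d, matrix(1, 16, 16)))
  }, numeric(1))
  expect_true(all(diffs > 0))
  # conditional discriminator reacts to the condition value
  dc <- buildDiscriminator(discriminatorSpec(input_side_px = 16L,
                                             conditional = TRUE), 2)
  p <- matrix(runif(256), 16, 16)
  expect_false(isTRUE(all.equal(
    discriminatorForward(dc, p, condition = "V1"),
    discriminatorForward(dc, p, condition = "M1"))))
  # five-layer option exists; too-small input is rejected
  expect_silent(buildDiscriminator(discriminatorSpec(input_side_px = 32L,
                                                     n_layers = 5L), 1))
  expect_error(discriminatorSpec(input_side_px = 16L, n_layers = 5L),
               "receptive")
})

test_that("LeakyReLU negative-side slope is 0.2 in the discriminator", {
  probe <- array(c(-2, -1, 0.5, 3), c(2, 2, 1, 1))
  f <- ReceptorGAN:::lreluForward(probe, 0.2)
  expect_equal(as.numeric(f$out), c(-0.4, -0.2, 0.5, 3))
  slope <- discriminatorSpec()@leaky_slope
  expect_equal(slope, 0.2)
})

test_that("batch-instance norm hits its boundary cases", {
  set.seed(8)
  x <- array(rnorm(6 * 5 * 3 * 4), c(6, 5, 3, 4))
  # rho = 1: batch normalization over batch + space
  b1 <- batchInstanceNorm(x, rho = 1)
  d <- dim(x)
  bn_oracle <- array(0, d)
  for (c in 1:3) {
    v <- x[, , c, ]
    bn_oracle[, , c, ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  expect_equal(b1, bn_oracle, tolerance = 1e-12)
  # rho = 0: instance normalization per sample over space
  b0 <- batchInstanceNorm(x, rho = 0)
  in_oracle <- array(0, d)
  for (c in 1:3) for (n in 1:4) {
    v <- x[, , c, n]
    in_oracle[, , c, n] <- (v - mean(v)) /
      sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  expect_equal(b0, in_oracle, tolerance = 1e-12)
  # rho = 0.5: the mean of the two normalizations
  expect_equal(batchInstanceNorm(x, rho = 0.5), (b1 + b0) / 2,
               tolerance = 1e-12)
  expect_error(batchInstanceNorm(x, rho = 1.5), "rho")
})
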