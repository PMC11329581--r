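# Deformation application, inversion, warping, landmark handling and
# block-mean downsampling.

test_that("applyDeformation matches identity, shift and a dense oracle", {
  idf <- DeformationField(matrix(0, 30, 30), matrix(0, 30, 30), 125)
  expect_equal(unname(applyDeformation(idf, c(10, 20))),
               matrix(c(10, 20), 1))
  shf <- DeformationField(matrix(2, 30, 30), matrix(0, 30, 30), 125)
  expect_equal(unname(applyDeformation(shf, c(5, 5))), matrix(c(7, 5), 1))
  # random smooth field vs nearest-node + manual bilinear oracle
  set.seed(11)
  gx <- outer(seq_len(20), seq_len(25), function(i, j) sin(i / 4) + j / 30)
  gy <- outer(seq_len(20), seq_len(25), function(i, j) cos(j / 5) - i / 40)
  f <- DeformationField(gx, gy, 125)
  pts <- cbind(runif(50, 0, 24), runif(50, 0, 19))
  got <- applyDeformation(f, pts)
  oracle <- t(apply(pts, 1, function(p) {
    x0 <- floor(p[1]); y0 <- floor(p[2])
    fx <- p[1] - x0; fy <- p[2] - y0
    x1 <- min(x0 + 1, 24); y1 <- min(y0 + 1, 19)
    bi <- function(m) (1 - fx) * (1 - fy) * m[y0 + 1, x0 + 1] +
      fx * (1 - fy) * m[y0 + 1, x1 + 1] +
      (1 - fx) * fy * m[y1 + 1, x0 + 1] + fx * fy * m[y1 + 1, x1 + 1]
    p + c(bi(gx), bi(gy))
  }))
  expect_lt(max(abs(got - oracle)), 1e-9)
  expect_error(applyDeformation(f, c(30, 5)), "outside")
})

test_that("invertDeformation handles identity, shift and sinusoidal fields", {
  idf <- DeformationField(matrix(0, 16, 16), matrix(0, 16, 16), 125)
  inv <- invertDeformation(idf)
  expect_true(all(inv@dx == 0) && all(inv@dy == 0))
  expect_equal(inv@direction, "fixed_to_moving")
  # constant shift inverts to the negated shift
  shf <- DeformationField(matrix(3, 40, 40), matrix(-1, 40, 40), 125)
  invs <- invertDeformation(shf, tol = 1e-6, max_iter = 200L)
  expect_lt(max(abs(invs@dx + 3)), 1e-6)
  expect_lt(max(abs(invs@dy - 1)), 1e-6)
  # sinusoidal field, amplitude 4 px: composition residual < 0.05 at nodes
  H <- 48; W <- 64
  gx <- rep(0:(W - 1), each = H); gy <- rep(0:(H - 1), W)
  ux <- 4 * sin(2 * pi * gx / W) * cos(2 * pi * gy / H)
  uy <- 4 * cos(2 * pi * gx / W) * sin(2 * pi * gy / H)
  f <- DeformationField(matrix(ux, H, W), matrix(uy, H, W), 125)
  fi <- invertDeformation(f, tol = 0.05, max_iter = 100L)
  nodes <- cbind(gx, gy)
  inside <- nodes[, 1] + fi@dx >= 0 & nodes[, 1] + fi@dx <= W - 1 &
    nodes[, 2] + fi@dy >= 0 & nodes[, 2] + fi@dy <= H - 1
  mapped <- applyDeformation(f, cbind(nodes[inside, 1] + fi@dx[inside],
                                      nodes[inside, 2] + fi@dy[inside]))
  expect_lt(max(abs(mapped - nodes[inside, , drop = FALSE])), 0.05)
})

test_that("warpImage matches identity, integer shift and bilinear midpoint", {
  img <- SectionImage(matrix(runif(400), 20, 20), 125)
  idf <- DeformationField(matrix(0, 20, 20), matrix(0, 20, 20), 125)
  warped <- pixels(warpImage(img, idf))
  expect_true(all(attr(warped, "valid")))
  attr(warped, "valid") <- NULL
  expect_identical(warped, pixels(img))
  # +1 px shift in x, nearest: output column j = input column j+1
  shf <- DeformationField(matrix(1, 20, 20), matrix(0, 20, 20), 125)
  w <- warpImage(img, shf, interpolation = "nearest")
  expect_equal(pixels(w)[, 1:19], pixels(img)[, 2:20])
  # half-pixel shift on a two-pixel gradient: bilinear midpoint average
  grad <- SectionImage(matrix(c(0, 1), 1, 2), 125)
  hf <- DeformationField(matrix(0.5, 1, 2), matrix(0, 1, 2), 125)
  expect_equal(pixels(warpImage(grad, hf))[1, 1], 0.5)
  expect_error(warpImage(img, DeformationField(matrix(0, 5, 5),
                                               matrix(0, 5, 5), 125)),
               "inconsistent")
})

test_that("splitLandmarks partitions 42 into 10 validation + 32 fit", {
  pairs <- data.frame(moving_x_mm = runif(42), moving_y_mm = runif(42),
                      fixed_x_mm = runif(42), fixed_y_mm = runif(42),
                      role = "fit")
  lm <- LandmarkSet(pairs)
  sp <- splitLandmarks(lm, seed = 3)
  expect_equal(length(sp$validation), 10)
  expect_equal(length(sp$fit), 32)
  # disjoint and exhaustive
  key <- function(x) paste(landmarkPairs(x)$moving_x_mm,
                           landmarkPairs(x)$moving_y_mm)
  expect_length(intersect(key(sp$fit), key(sp$validation)), 0)
  expect_setequal(c(key(sp$fit), key(sp$validation)),
                  paste(pairs$moving_x_mm, pairs$moving_y_mm))
  # deterministic per seed
  sp2 <- splitLandmarks(lm, seed = 3)
  expect_identical(landmarkPairs(sp$validation),
                   landmarkPairs(sp2$validation))
  expect_error(splitLandmarks(lm, n_holdout = 42L), "smaller")
})

test_that("landmarkResiduals quantifies offsets correctly", {
  idf <- DeformationField(matrix(0, 40, 40), matrix(0, 40, 40), 1000)
  # uniform 2 px perturbation of the fixed points -> mean residual 2 px
  mv <- data.frame(moving_x_mm = runif(8, 5, 30), moving_y_mm = runif(8, 5, 30))
  pairs <- data.frame(mv, fixed_x_mm = mv$moving_x_mm + 2,   # 2 px = 2 mm here
                      fixed_y_mm = mv$moving_y_mm, role = "validation")
  res <- landmarkResiduals(idf, LandmarkSet(pairs))
  expect_equal(res$mean_px, 2, tolerance = 1e-9)
  expect_equal(res$mean_mm, 2, tolerance = 1e-9)
  # random perturbations match hand-computed distances
  set.seed(9)
  dx <- rnorm(8, 0, 0.5); dy <- rnorm(8, 0, 0.5)
  pairs2 <- data.frame(mv, fixed_x_mm = mv$moving_x_mm + dx,
                       fixed_y_mm = mv$moving_y_mm + dy, role = "validation")
  res2 <- landmarkResiduals(idf, LandmarkSet(pairs2))
  expect_equal(res2$per_pair_px, sqrt(dx^2 + dy^2), tolerance = 1e-9)
  expect_true(all(res2$per_pair_px >= 0))
  expect_error(landmarkResiduals(idf, LandmarkSet(pairs2[0, ])), "empty")
})

test_that("resampleImage block-means with floor semantics", {
  const <- SectionImage(matrix(0.37, 20, 25), 1)
  r <- resampleImage(const, 5)
  expect_true(all(abs(pixels(r) - 0.37) < 1e-12))
  expect_equal(dim(pixels(r)), c(4L, 5L))
  # 2048 crop at 1 um -> 409^2 at 5 um (floor semantics)
  big <- SectionImage(matrix(0, 2048, 2048), 1)
  expect_equal(dim(pixels(resampleImage(big, 5))), c(409L, 409L))
  # 2x2 checkerboard blocks at factor 2 -> uniform mean image
  cb <- SectionImage(outer(1:8, 1:8, function(i, j) (i + j) %% 2), 1)
  r2 <- resampleImage(cb, 2)
  expect_true(all(abs(pixels(r2) - 0.5) < 1e-12))
  # mean intensity preserved
  img <- SectionImage(matrix(runif(100), 10, 10), 1)
  expect_equal(mean(pixels(resampleImage(img, 5))), mean(pixels(img)),
               tolerance = 1e-12)
  expect_error(resampleImage(img, 3.5), "non-integer")
  expect_error(resampleImage(resampleImage(img, 5), 1), "downscaling")
})
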