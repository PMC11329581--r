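# Midline spline fitting, patch-centre sampling, window mapping across the
# resolution gap, patch extraction and validity filtering.

test_that("midline spline interpolates and measures arc length", {
  s <- fitMidlineSpline(cbind(c(0, 10), c(0, 0)))
  expect_equal(arcLength(s), 10, tolerance = 1e-6)
  p <- midlinePoint(s, c(0, 5, 10))
  expect_equal(p[, 1], c(0, 5, 10), tolerance = 1e-6)
  expect_equal(p[, 2], c(0, 0, 0), tolerance = 1e-9)
  # passes through all control points to < 1e-6 mm
  set.seed(2)
  cp <- cbind(seq(0, 20, length.out = 7), rnorm(7))
  sp <- fitMidlineSpline(cp)
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  expect_lt(max(abs(sp@fx(chord) - cp[, 1])), 1e-6)
  expect_lt(max(abs(sp@fy(chord) - cp[, 2])), 1e-6)
  # quarter circle, r = 5 mm, 9 points: arc length within 1% of pi*5/2
  th <- seq(0, pi / 2, length.out = 9)
  qc <- fitMidlineSpline(cbind(5 * cos(th), 5 * sin(th)))
  expect_lt(abs(arcLength(qc) - pi * 5 / 2) / (pi * 5 / 2), 0.01)
  expect_error(fitMidlineSpline(cbind(1, 1)), "2 control points")
  expect_error(fitMidlineSpline(cbind(c(1, 1), c(2, 2))), "duplicate")
})

test_that("patch centres step the arc and expand to nine offsets", {
  s <- fitMidlineSpline(cbind(c(0, 1), c(0, 0)))
  centers <- samplePatchCenters(s)
  # 6 base positions (s = 0.0 ... 1.0) x 9 offsets
  expect_equal(length(unique(centers$base_id)), 6)
  expect_equal(nrow(centers), 54)
  expect_equal(sum(centers$base_id == 1), 9)
  # offsets {0} collapse to the base positions
  c0 <- samplePatchCenters(s, offsets_mm = 0)
  expect_equal(nrow(c0), 6)
  expect_equal(c0$center_x_mm, seq(0, 1, by = 0.2), tolerance = 1e-6)
  # the 9 offsets form the Cartesian product {-0.5, 0, 0.5}^2
  b1 <- centers[centers$base_id == 1, ]
  expect_setequal(round(b1$center_x_mm, 6), c(-0.5, 0, 0.5))
  expect_setequal(round(b1$center_y_mm, 6), c(-0.5, 0, 0.5))
  expect_error(samplePatchCenters(s, interval_mm = 0), "positive")
})

test_that("consecutive base windows overlap 90% on a straight midline", {
  s <- fitMidlineSpline(cbind(c(0, 10), c(0, 0)))
  centers <- samplePatchCenters(s, offsets_mm = 0)
  step <- diff(centers$center_x_mm[1:2])
  side <- 2
  overlap <- (side - step) / side
  expect_equal(overlap, 0.9, tolerance = 1e-9)
})

test_that("window corners map through fields and scale to cyto pixels", {
  w <- PatchWindow(c(3, 2), side_mm = 2)
  H <- 48; W <- 96
  idf <- DeformationField(matrix(0, H, W), matrix(0, H, W), 125,
                          "fixed_to_moving")
  # identity fields: corners scaled by the resolution ratio only
  mp <- mapWindowToCyto(w, idf, idf, cyto_resolution_um = 125 / 16)
  expect_true(mp$valid)
  expect_equal(mp$corners_px, w@corner_points / (125 / 16 / 1000),
               tolerance = 1e-9)
  # constant-shift D_inv: corners uniformly shifted (2 px = 0.25 mm)
  shf <- DeformationField(matrix(2, H, W), matrix(0, H, W), 125)
  mp2 <- mapWindowToCyto(w, idf, shf, cyto_resolution_um = 125 / 16)
  expect_equal(mp2$corners_px[, 1] - mp$corners_px[, 1],
               rep(2 * 16, 4), tolerance = 1e-9)
  # synthetic field with known inverse: mapped corners agree with the
  # analytic ground truth to < 0.5 px (cyto pixels)
  spec <- deskSpec(deformation_amplitude_px = 2)
  def <- makeDeformation(spec)
  mp3 <- mapWindowToCyto(w, idf, def$forward,
                         cyto_resolution_um = 125 / 16)
  truth <- applyDeformation(def$forward, w@corner_points / 0.125) * 0.125 /
    (125 / 16 / 1000)
  expect_lt(max(abs(mp3$corners_px - truth)), 0.5)
  # out-of-extent corner flags the window invalid
  w_out <- PatchWindow(c(11.9, 2), side_mm = 2)
  expect_false(mapWindowToCyto(w_out, idf, idf, 125 / 16)$valid)
})

test_that("extractPatchPair crops exactly under identity geometry", {
  # receptor and cyto share resolution and geometry: extraction = crop
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  rec <- SectionImage(img, 125, "receptor")
  cyt <- SectionImage(img, 125, "cyto")
  # window aligned to pixel boundaries (mm origin is at the first pixel
  # centre, so boundaries sit at half-integer pixel coordinates)
  w <- PatchWindow(c(4.0625, 4.0625), side_mm = 2)
  corners <- w@corner_points / 0.125
  pp <- extractPatchPair(rec, cyt, w, corners, receptor_patch_px = 16L,
                         factor = 1L)
  expect_equal(dim(pp@receptor), c(16L, 16L))
  expect_identical(pp@receptor, pp@cyto)
  # sample positions land on pixel centres 25..40 (0-based), i.e. matrix
  # rows/columns 26..41
  expect_equal(pp@receptor, img[26:41, 26:41], tolerance = 1e-9)
  expect_error(extractPatchPair(rec, cyt, PatchWindow(c(0.5, 4), 2),
                                PatchWindow(c(0.5, 4), 2)@corner_points /
                                  0.125, 16L, 1L),
               "bounds")
})

test_that("default patch dimensions honor the 2048/128 contract", {
  # pure shape check on small synthetic sections with the default sides
  # (22 px at 100 um: a 2 mm window fits with half-pixel margins)
  rec <- SectionImage(matrix(0.5, 22, 22), 100)
  cyt <- SectionImage(matrix(0.5, 352, 352), 100 / 16)
  w <- PatchWindow(c(1.05, 1.05), side_mm = 2)
  pp <- extractPatchPair(rec, cyt, w, w@corner_points / (100 / 16 / 1000),
                         receptor_patch_px = 128L, factor = 16L)
  expect_equal(dim(pp@receptor), c(128L, 128L))
  expect_equal(dim(pp@cyto), c(2048L, 2048L))
  expect_equal(nrow(pp@cyto) / nrow(pp@receptor), 16)
})

test_that("filterValidWindows drops out-of-bounds and low-coverage windows", {
  mask_px <- matrix(1, 48, 96)
  mask_px[, 40:48] <- 0                     # simulated damage hole
  mask <- SectionImage(mask_px, 125, "mask")
  inside <- PatchWindow(c(3, 3), 2)
  edge <- PatchWindow(c(0.2, 3), 2)         # leaves the canvas
  hole <- PatchWindow(c(5.2, 3), 2)         # ~50% over the hole
  flt <- filterValidWindows(list(inside, edge, hole), mask,
                            min_coverage = 0.98)
  expect_equal(flt$kept_idx, 1L)
  expect_equal(flt$log$reason[flt$log$window == 2], "out_of_bounds")
  expect_equal(flt$log$reason[flt$log$window == 3], "coverage")
  # filtering never increases counts
  expect_lte(length(flt$kept), 3)
})
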