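# Synthetic cortex simulator: laminar profiles, midline, rendering,
# deformation, landmarks and dataset composition.

test_that("laminar profiles honor the qualitative depth orderings", {
  # V1 (both receptors): low mid-depth, high towards pia and grey/white
  expect_lt(laminarProfile("V1", "M2", 0.5), laminarProfile("V1", "M2", 0.05))
  expect_lt(laminarProfile("V1", "M2", 0.5), laminarProfile("V1", "M2", 0.95))
  expect_lt(laminarProfile("V1", "kainate", 0.5),
            laminarProfile("V1", "kainate", 0.05))
  # M1 kainate high at the edges; M1 M2 high in the cortex centre
  expect_lt(laminarProfile("M1", "kainate", 0.5),
            laminarProfile("M1", "kainate", 0.05))
  expect_gt(laminarProfile("M1", "M2", 0.5), laminarProfile("M1", "M2", 0.05))
  expect_gt(laminarProfile("M1", "M2", 0.5), laminarProfile("M1", "M2", 0.95))
  # bounded [0, 1] everywhere, all pairings
  d <- seq(0, 1, by = 0.01)
  for (a in c("V1", "M1")) for (r in c("M2", "kainate")) {
    v <- laminarProfile(a, r, d)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(laminarProfile("V1", "M2", 1.2), "depth")
  expect_error(laminarProfile("V1", "M2", -0.1), "depth")
})

test_that("midline control points are spaced ~8.6 mm and interpolated", {
  # 30 mm canvas: at least 3 collinear control points for a straight spec
  spec30 <- SyntheticSpec(canvas_px = c(48L, 240L),
                          receptor_resolution_um = 125)
  m <- makeMidline(spec30)
  cp <- controlPoints(m)
  expect_gte(nrow(cp), 3)
  expect_true(all(abs(cp[, 2] - cp[1, 2]) < 1e-9))       # collinear
  spacing <- diff(cp[, 1])
  expect_true(all(abs(spacing - 8.6) / 8.6 <= 0.1))      # ~8.6 mm +- 10%
  # sinusoid spec: fitted curve passes through all its control points
  spec_sin <- SyntheticSpec(canvas_px = c(48L, 240L),
                            receptor_resolution_um = 125,
                            curvature = "sinusoid",
                            curvature_amplitude_mm = 0.4)
  ms <- makeMidline(spec_sin)
  cps <- controlPoints(ms)
  chord <- c(0, cumsum(sqrt(rowSums(diff(cps)^2))))
  expect_lt(max(abs(ms@fx(chord) - cps[, 1])), 1e-6)
  expect_lt(max(abs(ms@fy(chord) - cps[, 2])), 1e-6)
  # canvas too small for one interval
  expect_error(makeMidline(SyntheticSpec(canvas_px = c(48L, 60L),
                                         receptor_resolution_um = 125)),
               "too small")
})

test_that("noise-free receptor render equals the laminar profile exactly", {
  spec <- deskSpec(noise_sd = 0, intensity_jitter = 0)
  m <- makeMidline(spec)
  r <- renderSectionPair(spec, m)
  d <- depthValues(r$depth)
  ok <- !is.na(d)
  expect_equal(pixels(r$receptor)[ok],
               laminarProfile("V1", "M2", d[ok]), tolerance = 1e-12)
  # re-rendering with the same spec is bit-identical
  r2 <- renderSectionPair(spec, m)
  expect_identical(pixels(r2$receptor), pixels(r$receptor))
  expect_identical(pixels(r2$cyto), pixels(r$cyto))
})

test_that("rendered laminar ordering holds as band-mean inequalities", {
  for (conf in list(c("V1", "M2"), c("V1", "kainate"), c("M1", "kainate"))) {
    spec <- deskSpec(area = conf[1], receptor = conf[2],
                     noise_sd = 0, intensity_jitter = 0)
    r <- renderSectionPair(spec, makeMidline(spec))
    px <- pixels(r$receptor); d <- depthValues(r$depth)
    mid <- mean(px[!is.na(d) & d > 0.4 & d < 0.6])
    edge <- mean(px[!is.na(d) & (d < 0.1 | d > 0.9)])
    expect_lt(mid, edge)
  }
  spec <- deskSpec(area = "M1", receptor = "M2", noise_sd = 0,
                   intensity_jitter = 0)
  r <- renderSectionPair(spec, makeMidline(spec))
  px <- pixels(r$receptor); d <- depthValues(r$depth)
  expect_gt(mean(px[!is.na(d) & d > 0.4 & d < 0.6]),
            mean(px[!is.na(d) & (d < 0.1 | d > 0.9)]))
})

test_that("section pair geometry and depth map contracts hold", {
  spec <- deskSpec()
  r <- renderSectionPair(spec, makeMidline(spec))
  # cyto canvas side = resolution_factor x receptor canvas side
  expect_equal(dim(pixels(r$cyto)), 16L * dim(pixels(r$receptor)))
  expect_equal(resolutionUm(r$cyto) * 16, resolutionUm(r$receptor))
  # depth defined exactly on the tissue (ribbon) mask, within [0, 1]
  d <- depthValues(r$depth)
  expect_identical(!is.na(d), pixels(r$mask) > 0.5)
  expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 1))
  expect_true(validObject(r$depth))
})

test_that("synthetic deformation respects amplitude and inverts", {
  spec0 <- deskSpec(deformation_amplitude_px = 0)
  def0 <- makeDeformation(spec0)
  expect_true(all(def0$forward@dx == 0) && all(def0$forward@dy == 0))

  spec5 <- deskSpec(deformation_amplitude_px = 5)
  def5 <- makeDeformation(spec5)
  mag <- sqrt(def5$forward@dx^2 + def5$forward@dy^2)
  expect_lte(max(mag), 5 + 1e-9)
  # forward then inverse returns 100 random points to within 0.1 px
  set.seed(4)
  pts <- cbind(runif(100, 3, 92), runif(100, 3, 44))
  back <- applyDeformation(def5$inverse, applyDeformation(def5$forward, pts))
  expect_lt(max(abs(back - pts)), 0.1)
})

test_that("landmarks are exact, sized, and deterministic", {
  spec <- deskSpec(deformation_amplitude_px = 2)
  def <- makeDeformation(spec)
  lm <- makeLandmarks(def$forward, n = 42L, seed = 5)
  expect_equal(nrow(landmarkPairs(lm)), 42)
  lm2 <- makeLandmarks(def$forward, n = 42L, seed = 5)
  expect_identical(landmarkPairs(lm), landmarkPairs(lm2))
  # residual of the generating field is exactly zero
  val <- landmarkPairs(lm); val$role <- "validation"
  res <- landmarkResiduals(def$forward, LandmarkSet(val))
  expect_equal(res$max_px, 0, tolerance = 1e-9)
  # identity field maps each point to itself
  idf <- DeformationField(matrix(0, 10, 10), matrix(0, 10, 10), 125)
  lm_id <- makeLandmarks(idf, n = 5L, seed = 1)
  p <- landmarkPairs(lm_id)
  expect_equal(p$moving_x_mm, p$fixed_x_mm)
  expect_equal(p$moving_y_mm, p$fixed_y_mm)
  expect_error(makeLandmarks(idf, n = 1000L, seed = 1), "exceeds")
})

test_that("generated datasets are labeled, deterministic and 9-per-base", {
  ds <- deskDataset()
  expect_gt(length(ds), 0)
  areas <- vapply(patchPairs(ds), function(p) p@area, character(1))
  recs <- vapply(patchPairs(ds), function(p) p@receptor_type, character(1))
  expect_true(all(areas == "V1") && all(recs == "M2"))
  # pair count is 9 x (surviving base positions): complete offset groups
  expect_equal(length(ds) %% 9, 0)
  # same seed twice -> bit-identical datasets (check one section for speed)
  spec <- deskSpec(seed = 33)
  d1 <- generateDataset(spec, n_sections = 1L, seed = 33)
  d2 <- generateDataset(spec, n_sections = 1L, seed = 33)
  expect_identical(lapply(patchPairs(d1), function(p) p@receptor),
                   lapply(patchPairs(d2), function(p) p@receptor))
  expect_identical(lapply(patchPairs(d1), function(p) p@cyto),
                   lapply(patchPairs(d2), function(p) p@cyto))
  # patch shape contract at desk scale
  p <- patchPairs(ds)[[1]]
  expect_equal(dim(p@receptor), c(16L, 16L))
  expect_equal(dim(p@cyto), c(256L, 256L))
  # receptor target is consistent with profile(depth) ground truth
  ok <- !is.na(p@depth)
  expect_gt(cor(p@receptor[ok], laminarProfile("V1", "M2", p@depth[ok])),
            0.8)
})

test_that("combineDatasets keeps labels and reassigns section ids", {
  d1 <- thinDataset(deskDataset(), 18)
  spec_m <- deskSpec(area = "M1", seed = 40)
  d2 <- thinDataset(generateDataset(spec_m, n_sections = 1L, seed = 40), 18)
  comb <- combineDatasets(d1, d2)
  expect_equal(length(comb), length(d1) + length(d2))
  expect_equal(length(unique(sectionIds(comb))),
               length(unique(sectionIds(d1))) +
                 length(unique(sectionIds(d2))))
})
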