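# Metric definitions, their ideal values, closed forms and Monte-Carlo
# oracles, plus the report aggregation.

test_that("z-scoring standardizes with target statistics only", {
  set.seed(1)
  t <- matrix(runif(256), 16, 16)
  z <- zscorePair(t, t)
  expect_equal(mean(z$z_target), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z_target^2)), 1, tolerance = 1e-12)
  expect_identical(z$z_target, z$z_pred)
  # pred = target + c: z difference is the constant c / sigma_target
  sg <- sqrt(mean((t - mean(t))^2))
  z2 <- zscorePair(t, t + 0.2)
  expect_equal(unique(round(as.numeric(z2$z_pred - z2$z_target), 10)),
               round(0.2 / sg, 10))
  expect_error(zscorePair(matrix(0.5, 4, 4), matrix(0.4, 4, 4)),
               "degenerate")
})

test_that("z-MAE matches brute force and the independent-noise limit", {
  set.seed(2)
  a <- matrix(rnorm(100), 10, 10); b <- matrix(rnorm(100), 10, 10)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, b), mean(abs(a - b)), tolerance = 1e-15)
  # independent standard normals: E|X - Y| = 2/sqrt(pi), n = 1e6 pixels
  n <- 1e6
  x <- rnorm(n); y <- rnorm(n)
  se <- sd(abs(x - y)) / sqrt(n)
  expect_lt(abs(mae(x, y) - 2 / sqrt(pi)), 3 * se)
})

test_that("PSNR follows its closed form with max_p = 1", {
  t <- matrix(0, 10, 10)
  # MSE = 1 -> 0 dB (pred constant 1 against target 0)
  expect_equal(psnr(t, t + 1), 0, tolerance = 1e-12)
  # MSE = 0.01 -> 20 dB
  expect_equal(psnr(t, t + 0.1), 20, tolerance = 1e-12)
  expect_identical(psnr(t, t), Inf)
})

test_that("global SSIM hits identity, constant and anti-correlated cases", {
  set.seed(3)
  a <- matrix(runif(256), 16, 16)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  # two constant patches: closed form (2ab + c1)/(a^2 + b^2 + c1)
  c1 <- 0.01^2
  expect_equal(ssim(matrix(0.3, 8, 8), matrix(0.6, 8, 8)),
               (2 * 0.3 * 0.6 + c1) / (0.3^2 + 0.6^2 + c1),
               tolerance = 1e-12)
  # anti-correlated zero-mean patches give negative SSIM
  z <- a - mean(a)
  expect_lt(ssim(z, -z), 0)
  expect_true(ssim(a, matrix(runif(256), 16, 16)) >= -1)
})

test_that("FID matches the 1-D closed form and is symmetric", {
  # identical feature sets
  set.seed(4)
  f <- matrix(rnorm(50 * 4), 50, 4)
  expect_lt(fid(f, f), 1e-6)
  # exact sample moments: N(0,1) vs N(1,1) in 1-D -> (mu diff)^2 = 1
  a <- matrix(c(-sqrt(0.5), sqrt(0.5)), 2, 1)   # mean 0, unbiased var 1
  b <- a + 1
  expect_equal(fid(a, b), 1, tolerance = 1e-3)
  # symmetry and non-negativity on random multivariate sets
  g <- matrix(rnorm(40 * 4, 0.3, 1.2), 40, 4)
  expect_lt(abs(fid(f, g) - fid(g, f)), 1e-8)
  expect_gte(fid(f, g), 0)
  expect_error(fid(f[1, , drop = FALSE], g), "at least 2")
})

test_that("feature extraction is deterministic and permutation-safe", {
  set.seed(5)
  patches <- lapply(1:12, function(i) matrix(runif(16 * 16), 16, 16))
  fx <- extractFeatures(patches, "builtin_cnn", seed = 7)
  expect_equal(dim(fx), c(12L, 64L))
  expect_identical(fx, extractFeatures(patches, "builtin_cnn", seed = 7))
  # permuting patch order permutes rows only; FID is invariant
  perm <- sample(12)
  fp <- extractFeatures(patches[perm], "builtin_cnn", seed = 7)
  expect_equal(fp, fx[perm, ], tolerance = 1e-12)
  other <- lapply(1:12, function(i) matrix(runif(16 * 16, 0.3, 1), 16, 16))
  fo <- extractFeatures(other, "builtin_cnn", seed = 7)
  expect_equal(fid(fx, fo), fid(fp, fo), tolerance = 1e-9)
  expect_error(extractFeatures(patches, "inception_v3"), "builtin_cnn")
})

test_that("all four metrics attain their ideal values on identical inputs", {
  set.seed(6)
  targets <- lapply(1:8, function(i) matrix(runif(64), 8, 8))
  rep <- evaluatePatches(targets, targets)
  agg <- metricAggregates(rep)
  expect_equal(agg$mean[agg$metric == "mae"], 0, tolerance = 1e-9)
  expect_equal(agg$mean[agg$metric == "ssim"], 1, tolerance = 1e-9)
  expect_true(is.infinite(agg$mean[agg$metric == "psnr_db"]))
  expect_lt(fidValue(rep), 1e-6)
  expect_equal(rep@constants$n_infinite_psnr, 8)
})

test_that("aggregation respects polarity, population sd and exclusions", {
  pp <- data.frame(patch_id = 1:2, area = "V1", receptor = "M2",
                   mae = c(0.2, 0.9), psnr_db = c(10, 30),
                   ssim = c(0.8, 0.95))
  rep <- aggregateReport(pp, fid_value = 3)
  agg <- metricAggregates(rep)
  expect_equal(agg$worst[agg$metric == "mae"], 0.9)
  expect_equal(agg$worst[agg$metric == "psnr_db"], 10)
  expect_equal(agg$worst[agg$metric == "ssim"], 0.8)
  # population (not sample) standard deviation
  expect_equal(agg$sd[agg$metric == "mae"], 0.35, tolerance = 1e-12)
  # single patch: sd 0, worst = mean
  one <- aggregateReport(pp[1, ], fid_value = 0)
  a1 <- metricAggregates(one)
  expect_equal(a1$sd[a1$metric == "mae"], 0)
  expect_equal(a1$worst[a1$metric == "mae"],
               a1$mean[a1$metric == "mae"])
  expect_error(aggregateReport(pp[0, ], 0), "empty")
  # degenerate target patches are excluded with a log entry
  targets <- list(matrix(0.5, 8, 8), matrix(runif(64), 8, 8))
  preds <- list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
  r2 <- evaluatePatches(targets, preds)
  expect_equal(r2@excluded$reason, "degenerate_target_sd")
  expect_true(is.na(perPatchMetrics(r2)$mae[1]))
  expect_true(is.finite(metricAggregates(r2)$mean[1]))
})

test_that("report serialization round-trips the per-patch table", {
  set.seed(7)
  targets <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
  preds <- lapply(targets, function(t) t + rnorm(64, 0, 0.05))
  rep <- evaluatePatches(targets, preds)
  prefix <- tempfile()
  writeMetricReport(rep, prefix)
  back <- read.csv(paste0(prefix, "_per_patch.csv"))
  expect_equal(back$mae, perPatchMetrics(rep)$mae, tolerance = 1e-9)
  # recomputing the aggregates from the CSV matches the report
  expect_equal(mean(back$mae),
               metricAggregates(rep)$mean[metricAggregates(rep)$metric ==
                                            "mae"],
               tolerance = 1e-9)
  js <- jsonlite::read_json(paste0(prefix, "_report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$fid, fidValue(rep), tolerance = 1e-9)
})
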