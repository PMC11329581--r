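#' @include AllClasses.R nn_core.R
NULL

# The four metrics (z-score MAE, PSNR, SSIM, FID) plus the set-level
# aggregation with least-favorable ("worst") patch scores.

#' Z-score a patch pair with target statistics
#'
#' Standardizes both patches using the target's mean and standard
#' deviation only, so a biased prediction is penalized rather than
#' renormalized away.
#'
#' @param target_patch,predicted_patch equal-shape numeric matrices.
#' @param eps smallest admissible target standard deviation; a target with
#'   sd below this is degenerate and the pair is rejected.
#' @return list with `z_target` and `z_pred`.
#' @export
zscorePair <- function(target_patch, predicted_patch, eps = 1e-8) {
  if (!all(dim(target_patch) == dim(predicted_patch)))
    stop("patch shapes differ")
  mu <- mean(target_patch)
  sg <- sqrt(mean((target_patch - mu)^2))
  if (!is.finite(sg) || sg <= eps)
    stop("degenerate target patch (zero variance)")
  list(z_target = (target_patch - mu) / sg,
       z_pred = (predicted_patch - mu) / sg)
}

#' Mean absolute error
#'
#' Mean absolute pixel difference, conventionally applied to z-score
#' normalized patches (see [zscorePair()]).
#'
#' @param z_target,z_pred equal-shape numeric arrays.
#' @return scalar MAE.
#' @export
mae <- function(z_target, z_pred) {
  if (length(z_target) != length(z_pred)) stop("shape mismatch")
  mean(abs(z_target - z_pred))
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 log10(max_p / sqrt(MSE))` with `max_p = 1` for intensities on
#' \[0, 1\]. Identical patches give `Inf` (to be excluded from averages
#' with a logged count).
#'
#' @param target,predicted equal-shape numeric arrays on \[0, max_p\].
#' @param max_p maximum possible pixel value (default 1).
#' @return PSNR in dB (`Inf` for zero MSE).
#' @export
psnr <- function(target, predicted, max_p = 1) {
  mse <- mean((target - predicted)^2)
  if (mse == 0) return(Inf)
  20 * log10(max_p / sqrt(mse))
}

#' Global structural similarity index
#'
#' SSIM computed from whole-patch statistics (means, variances and the
#' covariance), not the windowed variant: one score per patch pair.
#' Stability constants default to `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`
#' with dynamic range `L = 1`.
#'
#' @param target,predicted equal-shape numeric arrays.
#' @param c1,c2 stability constants.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(target, predicted, c1 = 0.01^2, c2 = 0.03^2) {
  if (length(target) != length(predicted)) stop("shape mismatch")
  mx <- mean(target); my <- mean(predicted)
  vx <- mean((target - mx)^2); vy <- mean((predicted - my)^2)
  cxy <- mean((target - mx) * (predicted - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Frechet distance between two feature distributions
#'
#' Fits a Gaussian to each feature set and computes
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))`. The matrix square
#' root uses a symmetric eigendecomposition of `S1^(1/2) S2 S1^(1/2)`;
#' near-singular covariances are ridge-regularized and small negative
#' eigenvalues from round-off are clipped, so the result is non-negative.
#'
#' @param real_features,generated_features n x d matrices (rows =
#'   observations), n >= 2, equal d.
#' @param eps ridge added to the covariance diagonals.
#' @return non-negative Frechet distance.
#' @export
fid <- function(real_features, generated_features, eps = 1e-6) {
  a <- as.matrix(real_features); b <- as.matrix(generated_features)
  if (ncol(a) != ncol(b)) stop("feature dimensionality differs")
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("at least 2 feature vectors per set are required")
  mu1 <- colMeans(a); mu2 <- colMeans(b)
  n1 <- nrow(a); n2 <- nrow(b)
  s1 <- crossprod(sweep(a, 2, mu1)) / (n1 - 1) + diag(eps, ncol(a))
  s2 <- crossprod(sweep(b, 2, mu2)) / (n2 - 1) + diag(eps, ncol(b))
  sq1 <- symSqrt(s1)
  mid <- symSqrt(sq1 %*% s2 %*% sq1)
  val <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) -
    2 * sum(diag(mid))
  max(val, 0)
}

symSqrt <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Feature embedding of patches for FID
#'
#' Embeds patches as fixed-length vectors. The `builtin_cnn` extractor is
#' a small fixed-seed untrained convolutional embedder (three stride-2
#' convolutions with LeakyReLU, spatial mean + max pooling per channel)
#' that requires no download; random convolutional features preserve
#' distributional differences well enough for relative comparisons. The
#' `inception_v3` option documents the conventional choice but requires
#' pretrained weights that cannot be fetched in an offline installation.
#'
#' @param patches list of matrices, or an (H, W, N) array.
#' @param extractor `"builtin_cnn"` or `"inception_v3"`.
#' @param seed weight seed of the builtin embedder.
#' @param side internal resampling side (patches are block-averaged or
#'   bilinearly resized to side x side before embedding).
#' @return n x d feature matrix (d = 64 for the builtin embedder).
#' @export
extractFeatures <- function(patches, extractor = c("builtin_cnn",
                                                   "inception_v3"),
                            seed = 7L, side = 32L) {
  extractor <- match.arg(extractor)
  if (extractor == "inception_v3")
    stop("pretrained Inception-V3 weights are not available offline; ",
         "use extractor = 'builtin_cnn'")
  if (is.array(patches) && length(dim(patches)) == 3)
    patches <- lapply(seq_len(dim(patches)[3]), function(i) patches[, , i])
  n <- length(patches)
  x <- array(0, dim = c(side, side, 1, n))
  for (i in seq_len(n)) x[, , 1, i] <- resizeBilinear(patches[[i]], side)
  layers <- withSeed(seed, list(
    c1 = newConvLayer(3L, 1L, 8L, 2L, 1L),
    c2 = newConvLayer(3L, 8L, 16L, 2L, 1L),
    c3 = newConvLayer(3L, 16L, 32L, 2L, 1L)))
  t <- x
  for (l in layers) t <- lreluForward(convForward(l, t)$out, 0.2)$out
  d <- dim(t)
  tm <- matrix(t, d[1] * d[2], d[3] * d[4])
  avg <- matrix(.colMeans(tm, nrow(tm), ncol(tm)), d[3], d[4])
  mx <- matrix(apply(tm, 2, max), d[3], d[4])
  t(rbind(avg, mx))
}

resizeBilinear <- function(img, side) {
  H <- nrow(img); W <- ncol(img)
  u <- ((seq_len(side) - 0.5) / side)
  gx <- u * (W - 1); gy <- u * (H - 1)
  matrix(bilinearSample(img, rep(gx, each = side), rep(gy, side)),
         side, side)
}

#' Evaluate predictions against targets and aggregate
#'
#' Computes per-patch z-score MAE, PSNR and SSIM, the set-level FID from
#' builtin-CNN features, and the set aggregation: mean, population
#' standard deviation and the least favorable patch score per metric
#' (maximum for MAE, minimum for PSNR and SSIM). Degenerate target patches
#' (zero variance) are excluded from the MAE aggregation and logged;
#' infinite PSNR values (identical patches) are excluded from the PSNR
#' mean with a logged count.
#'
#' @param targets,predictions lists of equal-shape matrices (intensities
#'   on \[0, 1\]).
#' @param patch_ids optional ids for the report (default: indices).
#' @param areas,receptors optional label columns.
#' @param fid_features feature extractor passed to [extractFeatures()].
#' @param fid_seed seed of the builtin feature extractor.
#' @return a [MetricReport-class].
#' @export
evaluatePatches <- function(targets, predictions, patch_ids = NULL,
                            areas = NA, receptors = NA,
                            fid_features = "builtin_cnn", fid_seed = 7L) {
  n <- length(targets)
  if (n == 0 || n != length(predictions))
    stop("need equal, non-empty target and prediction lists")
  if (is.null(patch_ids)) patch_ids <- seq_len(n)
  rows <- vector("list", n)
  excluded <- NULL
  for (i in seq_len(n)) {
    m_mae <- NA_real_
    z <- tryCatch(zscorePair(targets[[i]], predictions[[i]]),
                  error = function(e) NULL)
    if (is.null(z)) {
      excluded <- rbind(excluded,
                        data.frame(patch_id = patch_ids[i],
                                   reason = "degenerate_target_sd"))
    } else m_mae <- mae(z$z_target, z$z_pred)
    rows[[i]] <- data.frame(
      patch_id = patch_ids[i],
      area = if (length(areas) == n) areas[i] else areas,
      receptor = if (length(receptors) == n) receptors[i] else receptors,
      mae = m_mae,
      psnr_db = psnr(targets[[i]], predictions[[i]]),
      ssim = ssim(targets[[i]], predictions[[i]]))
  }
  per_patch <- do.call(rbind, rows)
  fid_val <- fid(extractFeatures(targets, fid_features, seed = fid_seed),
                 extractFeatures(predictions, fid_features, seed = fid_seed))
  aggregateReport(per_patch, fid_val,
                  excluded = if (is.null(excluded))
                    data.frame(patch_id = integer(0), reason = character(0))
                  else excluded)
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate per-patch metrics into a report
#'
#' @param per_patch data.frame with columns `mae`, `psnr_db`, `ssim` (plus
#'   any id/label columns).
#' @param fid_value set-level FID.
#' @param excluded optional exclusion log data.frame.
#' @param constants metric constants recorded in the report metadata.
#' @return a [MetricReport-class].
#' @export
aggregateReport <- function(per_patch, fid_value,
                            excluded = data.frame(patch_id = integer(0),
                                                  reason = character(0)),
                            constants = list(max_p = 1, c1 = 0.01^2,
                                             c2 = 0.03^2,
                                             ssim_mode = "global")) {
  if (nrow(per_patch) == 0) stop("empty per-patch metric table")
  m_mae <- per_patch$mae[is.finite(per_patch$mae)]
  m_psnr <- per_patch$psnr_db[is.finite(per_patch$psnr_db)]
  m_ssim <- per_patch$ssim[is.finite(per_patch$ssim)]
  n_inf_psnr <- sum(is.infinite(per_patch$psnr_db))
  agg <- rbind(
    data.frame(metric = "mae", mean = mean(m_mae), sd = popSd(m_mae),
               worst = max(m_mae)),
    data.frame(metric = "psnr_db",
               mean = if (length(m_psnr)) mean(m_psnr) else Inf,
               sd = if (length(m_psnr)) popSd(m_psnr) else 0,
               worst = if (length(m_psnr)) min(m_psnr) else Inf),
    data.frame(metric = "ssim", mean = mean(m_ssim), sd = popSd(m_ssim),
               worst = min(m_ssim)),
    data.frame(metric = "fid", mean = fid_value, sd = 0, worst = fid_value))
  constants$n_infinite_psnr <- n_inf_psnr
  new("MetricReport", per_patch = per_patch, fid = fid_value,
      aggregates = agg, constants = constants, excluded = excluded)
}

#' Write a metric report to disk
#'
#' Writes the per-patch table as CSV and the aggregates plus metadata as
#' JSON next to it.
#'
#' @param report a [MetricReport-class].
#' @param prefix output path prefix (files `<prefix>_per_patch.csv`,
#'   `<prefix>_report.json`).
#' @return invisibly, the two file paths.
#' @export
writeMetricReport <- function(report, prefix) {
  csv <- paste0(prefix, "_per_patch.csv")
  js <- paste0(prefix, "_report.json")
  write.csv(report@per_patch, csv, row.names = FALSE)
  jsonlite::write_json(
    list(fid = report@fid,
         aggregates = report@aggregates,
         constants = report@constants,
         excluded = report@excluded),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}
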