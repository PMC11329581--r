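#' @include AllClasses.R
NULL

# Dense deformation fields link the receptor autoradiography (moving) to the
# cell-body stained reference (fixed). Registration itself is performed by an
# external tool; this module consumes, inverts and validates its output.

#' Apply a deformation field to points
#'
#' Displaces each point `p` (pixel coordinates at the field's grid) to
#' `p + u(p)`, where the displacement `u` is looked up by bilinear
#' interpolation between grid nodes. No extrapolation: points outside the
#' field extent raise an error.
#'
#' @param field a [DeformationField-class].
#' @param points n x 2 matrix (or length-2 vector) of (x, y) pixel
#'   coordinates, 0-based, origin at the top-left pixel centre.
#' @return n x 2 matrix of displaced points.
#' @examples
#' f <- DeformationField(matrix(2, 8, 8), matrix(0, 8, 8), 5)
#' applyDeformation(f, c(5, 5))  # -> (7, 5)
#' @export
applyDeformation <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  H <- nrow(field@dx); W <- ncol(field@dx)
  x <- points[, 1]; y <- points[, 2]
  if (any(x < 0 | x > W - 1 | y < 0 | y > H - 1))
    stop("point outside the field extent (no extrapolation)")
  ux <- bilinearSample(field@dx, x, y)
  uy <- bilinearSample(field@dy, x, y)
  cbind(x = x + as.numeric(ux), y = y + as.numeric(uy))
}

# Field lookup with border clamping, used internally by the fixed-point
# inversion where intermediate iterates may momentarily leave the grid.
lookupDisplacement <- function(field, x, y) {
  H <- nrow(field@dx); W <- ncol(field@dx)
  xc <- clampRange(x, 0, W - 1); yc <- clampRange(y, 0, H - 1)
  list(ux = as.numeric(bilinearSample(field@dx, xc, yc)),
       uy = as.numeric(bilinearSample(field@dy, xc, yc)))
}

#' Invert a deformation field by fixed-point iteration
#'
#' Solves `v(x) = -u(x + v(x))` on every grid node, which makes
#' `x + v(x)` the preimage of `x` under the forward map `x + u(x)`. The
#' iteration contracts when the forward displacements are small relative
#' to their spatial wavelength (Lipschitz constant of `u` below 1);
#' synthetic fields in this package keep amplitudes in that regime.
#'
#' @param field forward [DeformationField-class].
#' @param tol convergence tolerance on the composition residual
#'   `max |v + u(x + v)|`, in pixels (default 0.05).
#' @param max_iter iteration cap (default 100).
#' @return the inverse [DeformationField-class] (direction flag flipped).
#' @export
invertDeformation <- function(field, tol = 0.05, max_iter = 100L) {
  H <- nrow(field@dx); W <- ncol(field@dx)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), W)
  vx <- numeric(H * W); vy <- numeric(H * W)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    u <- lookupDisplacement(field, gx + vx, gy + vy)
    nvx <- -u$ux; nvy <- -u$uy
    resid <- max(abs(nvx - vx), abs(nvy - vy))
    vx <- nvx; vy <- nvy
    if (resid < tol / 2) break
  }
  # final composition residual at the grid nodes
  u <- lookupDisplacement(field, gx + vx, gy + vy)
  comp <- max(abs(vx + u$ux), abs(vy + u$uy))
  if (comp > tol)
    stop(sprintf(
      "deformation inversion did not converge: residual %.4g px > tol %g",
      comp, tol))
  dir <- if (field@direction == "moving_to_fixed") "fixed_to_moving"
         else "moving_to_fixed"
  DeformationField(matrix(vx, H, W), matrix(vy, H, W),
                   field@resolution_um, direction = dir)
}

#' Warp an image through a deformation field
#'
#' Backward warping: each output pixel `p` takes the source value at
#' `p + u(p)`. Pixels whose source location falls outside the image are
#' filled with `fill`; a logical validity mask is attached as attribute
#' `"valid"` of the returned image's pixel matrix.
#'
#' @param image a [SectionImage-class] whose grid matches the field.
#' @param field a [DeformationField-class].
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill fill value for out-of-source pixels (default 0).
#' @return a warped [SectionImage-class].
#' @export
warpImage <- function(image, field, interpolation = c("bilinear", "nearest"),
                      fill = 0) {
  interpolation <- match.arg(interpolation)
  img <- image@pixels
  if (!all(dim(img) == dim(field@dx)))
    stop("image and field dimensions are inconsistent")
  H <- nrow(img); W <- ncol(img)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), W)
  sx <- gx + as.numeric(field@dx)
  sy <- gy + as.numeric(field@dy)
  v <- if (interpolation == "bilinear") bilinearSample(img, sx, sy, fill)
       else nearestSample(img, sx, sy, fill)
  out <- matrix(as.numeric(v), H, W)
  attr(out, "valid") <- matrix(attr(v, "valid"), H, W)
  new("SectionImage", pixels = out, resolution_um = image@resolution_um,
      modality = image@modality, area = image@area,
      receptor = image@receptor)
}

#' Split landmarks into fit and held-out validation subsets
#'
#' Randomly reserves `n_holdout` landmark pairs (default 10, mirroring the
#' published protocol of holding ten of the ~42 landmarks back) for
#' validating registration quality; the remainder keep role `"fit"`.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param n_holdout number of validation pairs (default 10).
#' @param seed RNG seed; the split is deterministic per seed.
#' @return list with elements `fit` and `validation`, both
#'   [LandmarkSet-class] objects forming a disjoint exhaustive partition.
#' @export
splitLandmarks <- function(landmarks, n_holdout = 10L, seed = 1L) {
  n <- nrow(landmarks@pairs)
  if (n_holdout >= n)
    stop("n_holdout must be smaller than the number of landmark pairs")
  idx <- withSeed(seed, sample.int(n, n_holdout))
  fit <- landmarks@pairs[-idx, , drop = FALSE]
  val <- landmarks@pairs[idx, , drop = FALSE]
  fit$role <- "fit"; val$role <- "validation"
  list(fit = LandmarkSet(fit), validation = LandmarkSet(val))
}

#' Landmark residuals of a deformation field
#'
#' Maps the moving coordinates of validation landmarks through the field
#' and measures Euclidean distances to their fixed counterparts.
#'
#' @param field a [DeformationField-class] mapping moving to fixed space.
#' @param validation a non-empty [LandmarkSet-class].
#' @return list with `per_pair_px`, `per_pair_mm`, `mean_px`, `max_px`,
#'   `mean_mm`, `max_mm`.
#' @export
landmarkResiduals <- function(field, validation) {
  p <- validation@pairs
  if (nrow(p) == 0) stop("validation landmark set is empty")
  res_mm <- field@resolution_um / 1000
  moving_px <- cbind(p$moving_x_mm, p$moving_y_mm) / res_mm
  mapped <- applyDeformation(field, moving_px)
  fixed_px <- cbind(p$fixed_x_mm, p$fixed_y_mm) / res_mm
  d_px <- sqrt(rowSums((mapped - fixed_px)^2))
  list(per_pair_px = d_px, per_pair_mm = d_px * res_mm,
       mean_px = mean(d_px), max_px = max(d_px),
       mean_mm = mean(d_px) * res_mm, max_mm = max(d_px) * res_mm)
}

#' Downscale a section image by block averaging
#'
#' Reduces a fine grid to a coarser resolution by averaging non-overlapping
#' blocks, emulating densitometric averaging. Only integer downscale
#' factors are supported; trailing rows/columns that do not fill a whole
#' block are dropped (floor semantics), so 2048 px at 1 um -> 409 px at
#' 5 um.
#'
#' @param image a [SectionImage-class].
#' @param target_resolution_um target pixel size, an integer multiple of
#'   the source resolution.
#' @return the downsampled [SectionImage-class].
#' @export
resampleImage <- function(image, target_resolution_um) {
  f <- target_resolution_um / image@resolution_um
  if (f < 1) stop("only downscaling is supported (target >= source)")
  if (abs(f - round(f)) > 1e-8)
    stop(sprintf("non-integer downscale factor %.6g", f))
  f <- as.integer(round(f))
  img <- image@pixels
  Ho <- nrow(img) %/% f; Wo <- ncol(img) %/% f
  img <- img[seq_len(Ho * f), seq_len(Wo * f), drop = FALSE]
  # block mean via two strided averaging passes
  rowsum_idx <- rep(seq_len(Ho), each = f)
  a <- rowsum(img, rowsum_idx) / f
  b <- t(rowsum(t(a), rep(seq_len(Wo), each = f))) / f
  new("SectionImage", pixels = b, resolution_um = target_resolution_um,
      modality = image@modality, area = image@area,
      receptor = image@receptor)
}
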