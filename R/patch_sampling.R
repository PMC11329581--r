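#' @include AllClasses.R alignment.R
NULL

# Midline-guided extraction of corresponding multi-resolution patch pairs:
# a cubic spline through control points on the cortical midline of the
# receptor section, 2 mm windows stepped every 0.2 mm along the arc, each
# expanded to nine offset windows, mapped into the cyto section through the
# inverse deformation fields.

#' Fit the cortical midline spline
#'
#' Natural cubic spline through control points, parameterized by cumulative
#' chord length and reparameterized by arc length computed from a dense
#' polyline quadrature.
#'
#' @param control_points n x 2 matrix (or data.frame) of (x_mm, y_mm)
#'   points, n >= 2, no duplicates.
#' @return a [MidlineSpline-class].
#' @examples
#' s <- fitMidlineSpline(cbind(c(0, 10), c(0, 0)))
#' arcLength(s)  # 10
#' @export
fitMidlineSpline <- function(control_points) {
  cp <- as.matrix(control_points)[, 1:2, drop = FALSE]
  storage.mode(cp) <- "double"
  if (nrow(cp) < 2) stop("at least 2 control points are required")
  if (anyDuplicated(cp)) stop("duplicate control points")
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  fx <- splinefun(chord, cp[, 1], method = "natural")
  fy <- splinefun(chord, cp[, 2], method = "natural")
  tt <- seq(0, max(chord), length.out = max(2000L, 200L * nrow(cp)))
  dense <- cbind(fx(tt), fy(tt))
  seg <- sqrt(rowSums(diff(dense)^2))
  arc <- c(0, cumsum(seg))
  arc_to_t <- approxfun(arc, tt, rule = 2)
  new("MidlineSpline", control_points = cp, fx = fx, fy = fy,
      arc_to_t = arc_to_t, total_arc_length_mm = arc[length(arc)],
      dense = dense)
}

#' Evaluate a midline spline at arc-length positions
#'
#' @param spline a [MidlineSpline-class].
#' @param s_mm arc-length positions in mm.
#' @return n x 2 matrix of (x_mm, y_mm).
#' @export
midlinePoint <- function(spline, s_mm) {
  t <- spline@arc_to_t(s_mm)
  cbind(spline@fx(t), spline@fy(t))
}

#' Sample patch centre positions along the midline
#'
#' Base positions are equidistant in arc length, starting at the first
#' control point and stepping `interval_mm` (default 0.2 mm) until the
#' total arc length; a final partial step is dropped. Each base position is
#' expanded to the Cartesian product of `offsets_mm` in x and y (default
#' \{-0.5, 0, 0.5\} mm, i.e. nine shifted centres per base position).
#'
#' @param spline a [MidlineSpline-class].
#' @param interval_mm arc-length step (default 0.2).
#' @param offsets_mm offset set applied in both axes (default
#'   `c(-0.5, 0, 0.5)`).
#' @return data.frame with columns `base_id`, `base_s_mm`, `center_x_mm`,
#'   `center_y_mm`.
#' @export
samplePatchCenters <- function(spline, interval_mm = 0.2,
                               offsets_mm = c(-0.5, 0, 0.5)) {
  if (interval_mm <= 0) stop("interval_mm must be positive")
  L <- spline@total_arc_length_mm
  s <- if (L <= 0) 0 else seq(0, L + 1e-9, by = interval_mm)
  s <- s[s <= L + 1e-9]
  base <- midlinePoint(spline, s)
  off <- expand.grid(dx = offsets_mm, dy = offsets_mm)
  out <- do.call(rbind, lapply(seq_along(s), function(i) {
    data.frame(base_id = i, base_s_mm = s[i],
               center_x_mm = base[i, 1] + off$dx,
               center_y_mm = base[i, 2] + off$dy)
  }))
  rownames(out) <- NULL
  out
}

#' Map a patch window into cyto pixel coordinates
#'
#' Transforms the four window corners from receptor (moving) space into the
#' cell-body stained section: first through `D_inv`, then through `F_inv`
#' (both dense displacement fields at receptor resolution), then scales the
#' physical coordinates to cyto pixels. The mapped quadrilateral is in
#' general not axis-aligned.
#'
#' @param window a [PatchWindow-class].
#' @param F_inv,D_inv inverse [DeformationField-class] objects.
#' @param cyto_resolution_um pixel size of the cyto section.
#' @return list with `corners_px` (4 x 2 matrix in cyto pixel coordinates)
#'   and `valid` (FALSE when any corner left a field's extent).
#' @export
mapWindowToCyto <- function(window, F_inv, D_inv, cyto_resolution_um) {
  res_mm <- D_inv@resolution_um / 1000
  px <- window@corner_points / res_mm
  ok <- TRUE
  mapped <- tryCatch({
    p1 <- applyDeformation(D_inv, px)
    applyDeformation(F_inv, p1)
  }, error = function(e) { ok <<- FALSE; NULL })
  if (!ok) return(list(corners_px = NULL, valid = FALSE))
  mm <- unname(mapped) * res_mm
  list(corners_px = mm / (cyto_resolution_um / 1000), valid = TRUE)
}

#' Extract one corresponding patch pair
#'
#' The receptor patch is an axis-aligned resampling of the window at the
#' receptor grid (`receptor_patch_px` square, default 128 over the 2 mm
#' window); the cyto patch resamples the mapped quadrilateral onto a
#' regular square grid of side `factor * receptor_patch_px` by bilinear
#' interpolation of both the geometry (bilinear warp of the unit square
#' onto the quadrilateral) and the intensities.
#'
#' @param receptor_section,cyto_section [SectionImage-class] objects.
#' @param window a [PatchWindow-class] (receptor space).
#' @param mapped_corners 4 x 2 matrix of cyto pixel corners from
#'   [mapWindowToCyto()].
#' @param receptor_patch_px receptor patch side (default 128).
#' @param factor cyto/receptor side ratio (default 16).
#' @param depth_map optional [DepthMap-class] in fixed space; when given,
#'   the ground-truth depth is sampled at the mapped window grid.
#' @return a [PatchPair-class].
#' @export
extractPatchPair <- function(receptor_section, cyto_section, window,
                             mapped_corners, receptor_patch_px = 128L,
                             factor = 16L, depth_map = NULL) {
  res_mm <- receptor_section@resolution_um / 1000
  n <- as.integer(receptor_patch_px)
  half <- window@side_mm / 2
  # receptor: axis-aligned crop, pixel centres across the window extent
  u <- (seq_len(n) - 0.5) / n                        # in (0, 1)
  cx <- (window@center_xy_mm[1] - half + u * window@side_mm) / res_mm
  cy <- (window@center_xy_mm[2] - half + u * window@side_mm) / res_mm
  gx <- rep(cx, each = n); gy <- rep(cy, n)
  rv <- bilinearSample(receptor_section@pixels, gx, gy)
  if (!all(attr(rv, "valid"))) stop("window out of receptor section bounds")
  rec <- matrix(as.numeric(rv), n, n)
  # cyto: bilinear warp of the unit square onto the mapped quadrilateral
  m <- as.integer(factor) * n
  um <- (seq_len(m) - 0.5) / m
  a <- rep(um, each = m)   # along x (corner 1 -> 2)
  b <- rep(um, m)          # along y (corner 1 -> 4)
  cc <- mapped_corners
  qx <- (1 - a) * (1 - b) * cc[1, 1] + a * (1 - b) * cc[2, 1] +
        a * b * cc[3, 1] + (1 - a) * b * cc[4, 1]
  qy <- (1 - a) * (1 - b) * cc[1, 2] + a * (1 - b) * cc[2, 2] +
        a * b * cc[3, 2] + (1 - a) * b * cc[4, 2]
  cvv <- bilinearSample(cyto_section@pixels, qx, qy)
  if (!all(attr(cvv, "valid"))) stop("mapped window out of cyto bounds")
  cyt <- matrix(as.numeric(cvv), m, m)
  depth <- matrix(numeric(0), 0, 0)
  if (!is.null(depth_map)) {
    dres <- depth_map@resolution_um / 1000
    # depth is stored in fixed space; sample at the mapped window centres
    ccd <- cc * (cyto_section@resolution_um / 1000) / dres
    ad <- rep(u, each = n); bd <- rep(u, n)
    dqx <- (1 - ad) * (1 - bd) * ccd[1, 1] + ad * (1 - bd) * ccd[2, 1] +
           ad * bd * ccd[3, 1] + (1 - ad) * bd * ccd[4, 1]
    dqy <- (1 - ad) * (1 - bd) * ccd[1, 2] + ad * (1 - bd) * ccd[2, 2] +
           ad * bd * ccd[3, 2] + (1 - ad) * bd * ccd[4, 2]
    dv <- bilinearSample(depth_map@values, dqx, dqy, fill = NA_real_)
    depth <- matrix(as.numeric(dv), n, n)
  }
  new("PatchPair", cyto = cyt, receptor = rec, area = window@area,
      receptor_type = window@receptor, window = window, depth = depth)
}

#' Filter windows by canvas bounds and tissue coverage
#'
#' Automated stand-in for the manual exclusion of patches that leave the
#' section or cover damaged tissue: drops windows extending beyond the
#' canvas (reason `"out_of_bounds"`) or whose tissue coverage is below
#' `min_coverage` (reason `"coverage"`, default 0.98).
#'
#' @param windows list of [PatchWindow-class] objects.
#' @param mask tissue mask [SectionImage-class] (modality `"mask"`, values
#'   0/1) aligned with the receptor section.
#' @param min_coverage minimum tissue fraction (default 0.98).
#' @return list with `kept` (windows), `kept_idx` (their indices) and
#'   `log` (data.frame window, reason for each exclusion).
#' @export
filterValidWindows <- function(windows, mask, min_coverage = 0.98) {
  res_mm <- mask@resolution_um / 1000
  H <- nrow(mask@pixels); W <- ncol(mask@pixels)
  keep <- logical(length(windows))
  reasons <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    half <- w@side_mm / 2
    n <- max(8L, ceiling(w@side_mm / res_mm))
    u <- (seq_len(n) - 0.5) / n
    px <- (w@center_xy_mm[1] - half + u * w@side_mm) / res_mm
    py <- (w@center_xy_mm[2] - half + u * w@side_mm) / res_mm
    gx <- rep(px, each = n); gy <- rep(py, n)
    if (any(gx < 0 | gx > W - 1 | gy < 0 | gy > H - 1)) {
      reasons[i] <- "out_of_bounds"
      next
    }
    v <- nearestSample(mask@pixels, gx, gy)
    if (mean(v >= 0.5) < min_coverage) {
      reasons[i] <- "coverage"
      next
    }
    keep[i] <- TRUE
  }
  excl <- which(!keep)
  list(kept = windows[keep], kept_idx = which(keep),
       log = data.frame(window = excl, reason = reasons[excl]))
}
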