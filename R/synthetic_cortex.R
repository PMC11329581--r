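#' @include AllClasses.R alignment.R patch_sampling.R
NULL

# Synthetic paired-section simulator. Real macaque material is not publicly
# deposited, so every downstream stage is exercised on simulated data: a
# curved cortical ribbon with a normalized depth coordinate, modality-
# specific laminar intensity profiles, cell-body speckle texture, smooth
# labeling-intensity jitter, a 16x resolution gap, and a smooth nonlinear
# deformation with exactly known landmark correspondences.

# Receptor laminar profile parameters: value = a + b * (2 d - 1)^2.
# V1 profiles are U-shaped (low mid-depth, high towards pial surface and
# grey/white boundary); M1 kainate is U-shaped; M1 M2 is inverted-U (high
# in the cortex centre, low at the edges).
.laminar_params <- list(
  V1 = list(M2 = c(a = 0.30, b = 0.45), kainate = c(a = 0.20, b = 0.65)),
  M1 = list(M2 = c(a = 0.85, b = -0.60), kainate = c(a = 0.25, b = 0.60))
)

#' Laminar receptor-density profile
#'
#' Smooth parametric density profile over normalized cortical depth
#' (0 = pial surface, 1 = grey/white boundary), one per (area, receptor)
#' pairing. The shapes honor the qualitative laminar orderings of the two
#' areas: V1 profiles (both receptors) and M1 kainate are U-shaped with
#' low mid-depth densities, while M1 M2 peaks in the cortex centre.
#'
#' @param area `"V1"` or `"M1"`.
#' @param receptor `"M2"` or `"kainate"`.
#' @param depth normalized depth values in \[0, 1\].
#' @return densities in \[0, 1\], same length as `depth`.
#' @examples
#' laminarProfile("V1", "M2", c(0.05, 0.5))  # edge > centre
#' laminarProfile("M1", "M2", c(0.05, 0.5))  # centre > edge
#' @export
laminarProfile <- function(area, receptor, depth) {
  if (any(depth < 0 | depth > 1 | !is.finite(depth)))
    stop("depth must lie within [0, 1]")
  p <- .laminar_params[[match.arg(area, c("V1", "M1"))]][[
    match.arg(receptor, c("M2", "kainate"))]]
  p[["a"]] + p[["b"]] * (2 * depth - 1)^2
}

# Cell-density profile for the cyto speckle texture: broadly increasing
# towards the grey/white boundary with a band of higher density mid-depth
# (layer IV analog). Deliberately different from every receptor profile so
# the cross-modality mapping is non-trivial but learnable.
cytoDensityProfile <- function(depth) {
  clampRange(0.12 + 0.5 * depth + 0.30 * exp(-((depth - 0.45) / 0.12)^2),
             0, 0.95)
}

#' Ground-truth cortical midline for a synthetic spec
#'
#' Places control points spaced 8.6 mm apart along the ribbon axis (the
#' published average control-point spacing), centred in the canvas, on the
#' curve selected by the spec's `curvature`, and fits the midline spline
#' through them. The fitted spline is the simulator's ground-truth
#' midline.
#'
#' @param spec a [SyntheticSpec-class].
#' @param spacing_mm control-point spacing (default 8.6).
#' @return a [MidlineSpline-class].
#' @export
makeMidline <- function(spec, spacing_mm = 8.6) {
  res_mm <- spec@receptor_resolution_um / 1000
  w_mm <- spec@canvas_px[2] * res_mm
  h_mm <- spec@canvas_px[1] * res_mm
  if (w_mm < spacing_mm)
    stop(sprintf(
      "canvas width %.2f mm too small for one control-point interval (%.1f mm)",
      w_mm, spacing_mm))
  n <- floor(w_mm / spacing_mm) + 1
  span <- spacing_mm * (n - 1)
  x <- (w_mm - span) / 2 + spacing_mm * (0:(n - 1))
  y <- midlineCurveY(spec, x, h_mm, span, x[1])
  fitMidlineSpline(cbind(x, y))
}

midlineCurveY <- function(spec, x, h_mm, span, x0) {
  a <- spec@curvature_amplitude_mm
  switch(spec@curvature,
    straight = rep(h_mm / 2, length(x)),
    sinusoid = h_mm / 2 + a * sin(2 * pi * (x - x0) / (span / 1.5)),
    sulcus = h_mm / 2 + a * exp(-((x - (x0 + span / 2)) / (span / 6))^2))
}

# Signed-distance-based depth lookup: depth 0 at the pial (upper) ribbon
# boundary, 1 at the grey/white (lower) boundary; values outside [0, 1]
# lie above the pia (negative) or in the white matter (> 1). Distances
# are measured along the local normal using the slope-corrected vertical
# offset from the midline, which is exact for straight ribbons and a close
# approximation for the gentle curvatures simulated here.
signedDepthAt <- function(midline, x_mm, y_mm, thickness_mm) {
  dn <- midline@dense
  yofx <- approxfun(dn[, 1], dn[, 2], rule = 2)
  eps <- 1e-3
  slope <- (yofx(x_mm + eps) - yofx(x_mm - eps)) / (2 * eps)
  d_signed <- (y_mm - yofx(x_mm)) / sqrt(1 + slope^2)
  d_signed / thickness_mm + 0.5
}

depthAt <- function(midline, x_mm, y_mm, thickness_mm) {
  depth <- signedDepthAt(midline, x_mm, y_mm, thickness_mm)
  depth[depth < 0 | depth > 1] <- NA_real_
  depth
}

# Flat intensity levels of the non-cortical section zones.
.zone_levels <- list(receptor_above = 0.05, receptor_wm = 0.12,
                     cyto_density_above = 0.03, cyto_density_wm = 0.08)

#' Render a corresponding synthetic section pair
#'
#' Renders, in the common fixed (reference) geometry: the receptor
#' autoradiography section at receptor resolution, the cell-body stained
#' section on a grid `resolution_factor` times finer, the tissue mask and
#' the normalized depth map. Receptor intensity at a tissue pixel is
#' `laminarProfile(depth) * jitter + noise`; the cyto section is a
#' cell-body speckle texture whose dot density follows its own laminar
#' profile. With `noise_sd = 0` and `intensity_jitter = 0` the receptor
#' image equals the laminar profile exactly.
#'
#' The simulated field of view lies entirely inside the section: above the
#' pial boundary the slab continues as a sparse low-intensity zone, below
#' the grey/white boundary as white matter (low receptor density, sparse
#' cell bodies), so every canvas pixel carries section signal. The
#' returned tissue mask marks the cortical ribbon, exactly where the depth
#' map is defined.
#'
#' @param spec a [SyntheticSpec-class].
#' @param midline the ground-truth [MidlineSpline-class] (from
#'   [makeMidline()]).
#' @param section_seed optional seed override for this section's textures
#'   (defaults to the spec seed).
#' @return list with `cyto`, `receptor`, `mask` ([SectionImage-class],
#'   cortical ribbon) and `depth` ([DepthMap-class], receptor resolution).
#' @export
renderSectionPair <- function(spec, midline, section_seed = spec@seed) {
  res_mm <- spec@receptor_resolution_um / 1000
  H <- spec@canvas_px[1]; W <- spec@canvas_px[2]
  f <- spec@resolution_factor
  cyto_res_mm <- res_mm / f

  # receptor grid depth
  gx <- rep((0:(W - 1)) * res_mm, each = H)
  gy <- rep((0:(H - 1)) * res_mm, W)
  sdep <- signedDepthAt(midline, gx, gy, spec@ribbon_thickness_mm)
  depth_r <- matrix(ifelse(sdep < 0 | sdep > 1, NA_real_, sdep), H, W)
  mask_r <- !is.na(depth_r)

  # receptor intensity: laminar profile in the ribbon, flat zone levels in
  # the white matter and above the pia
  base <- ifelse(sdep < 0, .zone_levels$receptor_above,
                 ifelse(sdep > 1, .zone_levels$receptor_wm,
                        laminarProfile(spec@area, spec@receptor,
                                       clampRange(sdep, 0, 1))))
  jit <- 1
  if (spec@intensity_jitter > 0) {
    jit <- withSeed(childSeed(section_seed, "jitter"), {
      ph <- runif(4, 0, 2 * pi)
      w_mm <- W * res_mm; h_mm <- H * res_mm
      g <- sin(2 * pi * gx / w_mm + ph[1]) * cos(2 * pi * gy / h_mm + ph[2]) +
        0.5 * sin(4 * pi * gx / w_mm + ph[3]) *
          cos(4 * pi * gy / h_mm + ph[4])
      1 + spec@intensity_jitter * g / 1.5
    })
  }
  val <- base * jit
  if (spec@noise_sd[2] > 0)
    val <- val + withSeed(childSeed(section_seed, "rnoise"),
                          rnorm(length(val), 0, spec@noise_sd[2]))
  rec <- matrix(clampRange(val, 0, 1), H, W)

  # cyto grid: speckle texture modulated by the cell-density profile
  Hc <- H * f; Wc <- W * f
  cgx <- rep((0:(Wc - 1)) * cyto_res_mm, each = Hc)
  cgy <- rep((0:(Hc - 1)) * cyto_res_mm, Wc)
  sdep_c <- signedDepthAt(midline, cgx, cgy, spec@ribbon_thickness_mm)
  dens <- ifelse(sdep_c < 0, .zone_levels$cyto_density_above,
                 ifelse(sdep_c > 1, .zone_levels$cyto_density_wm,
                        cytoDensityProfile(clampRange(sdep_c, 0, 1))))
  dots <- withSeed(childSeed(section_seed, "speckle"),
                   as.numeric(runif(length(dens)) < dens))
  cv <- 1 - 0.8 * dots   # bright background, dark cell bodies
  if (spec@noise_sd[1] > 0)
    cv <- cv + withSeed(childSeed(section_seed, "cnoise"),
                        rnorm(length(cv), 0, spec@noise_sd[1]))
  cyto <- matrix(clampRange(cv, 0, 1), Hc, Wc)

  list(
    cyto = SectionImage(cyto, spec@receptor_resolution_um / f,
                        modality = "cyto", area = spec@area,
                        receptor = spec@receptor),
    receptor = SectionImage(rec, spec@receptor_resolution_um,
                            modality = "receptor", area = spec@area,
                            receptor = spec@receptor),
    mask = SectionImage(mask_r + 0, spec@receptor_resolution_um,
                        modality = "mask"),
    depth = new("DepthMap", values = depth_r,
                resolution_um = spec@receptor_resolution_um)
  )
}

#' Synthetic smooth deformation field with known inverse
#'
#' Builds a band-limited displacement field (a sum of two low-frequency
#' sinusoidal modes with seed-controlled phases) at receptor resolution,
#' scaled so the maximum displacement magnitude equals the spec's
#' amplitude. Because the field is smooth and small relative to its
#' wavelength, the fixed-point inversion converges to machine precision,
#' and the returned inverse composes with the forward field to identity.
#'
#' @param spec a [SyntheticSpec-class].
#' @param section_seed optional per-section seed override.
#' @return list with `forward` and `inverse` [DeformationField-class]
#'   objects (forward direction: moving to fixed).
#' @export
makeDeformation <- function(spec, section_seed = spec@seed) {
  H <- spec@canvas_px[1]; W <- spec@canvas_px[2]
  A <- spec@deformation_amplitude_px
  if (A == 0) {
    z <- matrix(0, H, W)
    idf <- DeformationField(z, z, spec@receptor_resolution_um)
    inv <- DeformationField(z, z, spec@receptor_resolution_um,
                            direction = "fixed_to_moving")
    return(list(forward = idf, inverse = inv))
  }
  ph <- withSeed(childSeed(section_seed, "deform"), runif(8, 0, 2 * pi))
  gx <- rep(0:(W - 1), each = H); gy <- rep(0:(H - 1), W)
  # wavelengths no shorter than the canvas keep the field band-limited
  # enough that bilinear lookups between grid nodes track the analytic
  # field to well under a tenth of a pixel
  px <- max(W, 24); py <- max(H, 24)
  ux <- sin(2 * pi * gx / px + ph[1]) * cos(2 * pi * gy / py + ph[2]) +
    0.2 * sin(3 * pi * gx / px + ph[3]) * cos(3 * pi * gy / py + ph[4])
  uy <- cos(2 * pi * gx / px + ph[5]) * sin(2 * pi * gy / py + ph[6]) +
    0.2 * cos(3 * pi * gx / px + ph[7]) * sin(3 * pi * gy / py + ph[8])
  scale <- A / max(sqrt(ux^2 + uy^2))
  fwd <- DeformationField(matrix(ux * scale, H, W), matrix(uy * scale, H, W),
                          spec@receptor_resolution_um)
  inv <- invertDeformation(fwd, tol = 1e-6, max_iter = 500L)
  list(forward = fwd, inverse = inv)
}

#' Exact landmark pairs for a deformation field
#'
#' Samples `n` moving-space points (restricted to the tissue mask when one
#' is given) and pairs each with its exact image under the field, so the
#' landmark residual of the generating field is identically zero.
#'
#' @param field forward [DeformationField-class] (moving to fixed).
#' @param n number of landmark pairs (the study protocol averages 42).
#' @param seed RNG seed; the set is deterministic per seed.
#' @param mask optional tissue mask [SectionImage-class] in moving space.
#' @return a [LandmarkSet-class] (all pairs role `"fit"`), coordinates in
#'   mm.
#' @export
makeLandmarks <- function(field, n = 42L, seed = 1L, mask = NULL) {
  if (n < 1) stop("n must be >= 1")
  H <- nrow(field@dx); W <- ncol(field@dx)
  # stay one pixel inside the border so displaced points remain in extent
  cand <- expand.grid(x = 1:(W - 2), y = 1:(H - 2))
  if (!is.null(mask)) {
    keep <- mask@pixels[cbind(cand$y + 1, cand$x + 1)] >= 0.5
    cand <- cand[keep, , drop = FALSE]
  }
  if (n > nrow(cand))
    stop(sprintf("n = %d exceeds the %d available tissue pixels", n,
                 nrow(cand)))
  idx <- withSeed(seed, sample.int(nrow(cand), n))
  moving_px <- as.matrix(cand[idx, c("x", "y")])
  fixed_px <- applyDeformation(field, moving_px)
  res_mm <- field@resolution_um / 1000
  LandmarkSet(data.frame(
    moving_x_mm = moving_px[, 1] * res_mm,
    moving_y_mm = moving_px[, 2] * res_mm,
    fixed_x_mm = fixed_px[, 1] * res_mm,
    fixed_y_mm = fixed_px[, 2] * res_mm,
    role = "fit"))
}

identityField <- function(H, W, resolution_um,
                          direction = "fixed_to_moving") {
  z <- matrix(0, H, W)
  DeformationField(z, z, resolution_um, direction = direction)
}

#' Generate a complete synthetic patch dataset
#'
#' End-to-end composition of the simulator: for each synthetic section,
#' build the ground-truth midline, render the section pair, deform the
#' receptor section with a known smooth field, fit the sampling midline in
#' the deformed (moving) space, step 2 mm windows along it, filter them
#' against bounds and tissue coverage, and extract corresponding patch
#' pairs (receptor crop + quadrilateral-resampled cyto patch + ground-truth
#' depth). All pairs carry the spec's area/receptor labels and a synthetic
#' section id; provenance (spec, seed, exclusion log) is embedded.
#'
#' @param spec a [SyntheticSpec-class].
#' @param n_sections number of synthetic sections (>= 1).
#' @param seed master dataset seed (default: the spec seed).
#' @param interval_mm midline stepping interval (default 0.2).
#' @param offsets_mm offset set (default `c(-0.5, 0, 0.5)`).
#' @param min_coverage tissue-coverage threshold for window filtering.
#' @return a [PatchDataset-class].
#' @export
generateDataset <- function(spec, n_sections = 1L, seed = spec@seed,
                            interval_mm = 0.2, offsets_mm = c(-0.5, 0, 0.5),
                            min_coverage = 0.98) {
  if (n_sections < 1) stop("n_sections must be >= 1")
  res_mm <- spec@receptor_resolution_um / 1000
  side_mm <- 2
  patch_px <- as.integer(round(side_mm / res_mm))
  midline <- makeMidline(spec)
  pairs <- list(); ids <- integer(0); logs <- list()
  for (sec in seq_len(n_sections)) {
    sseed <- childSeed(seed, paste0("section", sec))
    rendered <- renderSectionPair(spec, midline, section_seed = sseed)
    def <- makeDeformation(spec, section_seed = sseed)
    moving_rec <- warpImage(rendered$receptor, def$forward)
    # sampling midline lives on the moving (observed receptor) section
    cp_fixed <- controlPoints(midline)
    cp_mov_px <- applyDeformation(def$inverse, cp_fixed / res_mm)
    spline_mov <- fitMidlineSpline(cp_mov_px * res_mm)
    centers <- samplePatchCenters(spline_mov, interval_mm, offsets_mm)
    windows <- lapply(seq_len(nrow(centers)), function(i)
      PatchWindow(c(centers$center_x_mm[i], centers$center_y_mm[i]),
                  side_mm = side_mm, section_id = sec, area = spec@area,
                  receptor = spec@receptor))
    # coverage is judged against the section support (the simulated slab
    # fills the canvas); a base position is kept only when all of its
    # offset windows survive, so the augmentation group stays complete
    support <- SectionImage(matrix(1, spec@canvas_px[1], spec@canvas_px[2]),
                            spec@receptor_resolution_um, modality = "mask")
    flt <- filterValidWindows(windows, support, min_coverage)
    bad_bases <- unique(centers$base_id[setdiff(seq_along(windows),
                                                flt$kept_idx)])
    keep_idx <- flt$kept_idx[!centers$base_id[flt$kept_idx] %in% bad_bases]
    flt$kept <- windows[keep_idx]
    logs[[sec]] <- if (nrow(flt$log))
      cbind(section = sec, flt$log) else NULL
    # point map from moving (observed receptor) space into the fixed
    # reference space; the second stage is the identity here because the
    # synthetic pipeline has a single deformation stage
    F_inv <- identityField(spec@canvas_px[1], spec@canvas_px[2],
                           spec@receptor_resolution_um)
    extracted <- lapply(flt$kept, function(w) {
      mp <- mapWindowToCyto(w, F_inv = F_inv, D_inv = def$forward,
                            cyto_resolution_um = resolutionUm(rendered$cyto))
      if (!mp$valid) return(NULL)
      tryCatch(
        extractPatchPair(moving_rec, rendered$cyto, w, mp$corners_px,
                         receptor_patch_px = patch_px,
                         factor = spec@resolution_factor,
                         depth_map = rendered$depth),
        error = function(e) NULL)
    })
    # keep only base positions whose full offset group extracted cleanly,
    # so the dataset stays a whole number of augmentation groups
    base_of_kept <- centers$base_id[keep_idx]
    failed_bases <- unique(base_of_kept[vapply(extracted, is.null,
                                               logical(1))])
    for (j in seq_along(extracted)) {
      if (base_of_kept[j] %in% failed_bases) next
      pairs[[length(pairs) + 1L]] <- extracted[[j]]
      ids <- c(ids, sec)
    }
  }
  new("PatchDataset", pairs = pairs, section_ids = ids,
      provenance = list(spec = spec, seed = seed,
                        exclusion_log = do.call(rbind, logs),
                        interval_mm = interval_mm, offsets_mm = offsets_mm,
                        min_coverage = min_coverage))
}

#' Concatenate patch datasets
#'
#' Merges datasets (e.g. the two areas for multi-area training); section
#' ids are offset so they remain unique across the inputs.
#'
#' @param ... [PatchDataset-class] objects.
#' @return the combined [PatchDataset-class].
#' @export
combineDatasets <- function(...) {
  ds <- list(...)
  pairs <- list(); ids <- integer(0); off <- 0L
  for (d in ds) {
    pairs <- c(pairs, d@pairs)
    ids <- c(ids, d@section_ids + off)
    off <- off + max(d@section_ids, 0L)
  }
  new("PatchDataset", pairs = pairs, section_ids = ids,
      provenance = list(combined_from = lapply(ds, provenance)))
}
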