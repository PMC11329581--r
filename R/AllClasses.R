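#' @include utils.R
NULL

# ---------------------------------------------------------------- images ----

#' SectionImage: a 2-D intensity grid with physical resolution
#'
#' The basic container for one histological section (or patch) of either
#' modality. Intensities are stored as a numeric matrix in \[0, 1\]; rows run
#' downward (y) and columns rightward (x). Physical coordinates are in mm
#' with the origin at the centre of the top-left pixel, so
#' `x_mm = x_px * resolutionUm(img) / 1000`.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot resolution_um pixel size in micrometres per pixel.
#' @slot modality `"cyto"` (cell-body stain) or `"receptor"`
#'   (autoradiography), or `"mask"`/`"depth"` for derived grids.
#' @slot area cortical area label, `"V1"`, `"M1"` or `NA`.
#' @slot receptor receptor label, `"M2"`, `"kainate"` or `NA`.
#'
#' @examples
#' img <- SectionImage(matrix(runif(12), 3, 4), resolution_um = 5)
#' dim(pixels(img))
#' @export
setClass("SectionImage",
  representation(
    pixels = "matrix",
    resolution_um = "numeric",
    modality = "character",
    area = "character",
    receptor = "character"
  ),
  prototype(modality = "receptor", area = NA_character_,
            receptor = NA_character_)
)

setValidity("SectionImage", function(object) {
  msg <- NULL
  if (length(object@resolution_um) != 1 || object@resolution_um <= 0)
    msg <- c(msg, "resolution_um must be a single positive number")
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be numeric")
  if (!object@modality %in% c("cyto", "receptor", "mask", "depth"))
    msg <- c(msg, "modality must be cyto, receptor, mask or depth")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SectionImage-class
#' @param pixels numeric matrix of intensities.
#' @param resolution_um pixel size in micrometres per pixel.
#' @param modality,area,receptor metadata tags (see slots).
#' @export
SectionImage <- function(pixels, resolution_um, modality = "receptor",
                         area = NA_character_, receptor = NA_character_) {
  new("SectionImage", pixels = pixels, resolution_um = resolution_um,
      modality = modality, area = as.character(area),
      receptor = as.character(receptor))
}

# ----------------------------------------------------------- deformation ----

#' DeformationField: dense per-pixel displacement grid
#'
#' Holds a dense displacement field at receptor-modality resolution: the
#' field has the same dimensions as the section it belongs to. Applying the
#' field moves a point `p` (in pixels) to `p + u(p)`, where `u` is obtained
#' by bilinear interpolation between grid nodes.
#'
#' @slot dx,dy numeric matrices of displacement components in pixels.
#' @slot resolution_um grid pixel size in micrometres.
#' @slot direction `"moving_to_fixed"` or `"fixed_to_moving"`.
#' @export
setClass("DeformationField",
  representation(dx = "matrix", dy = "matrix", resolution_um = "numeric",
                 direction = "character"),
  prototype(direction = "moving_to_fixed")
)

setValidity("DeformationField", function(object) {
  msg <- NULL
  if (!all(dim(object@dx) == dim(object@dy)))
    msg <- c(msg, "dx and dy must have identical dimensions")
  if (!all(is.finite(object@dx)) || !all(is.finite(object@dy)))
    msg <- c(msg, "all displacement components must be finite")
  if (!object@direction %in% c("moving_to_fixed", "fixed_to_moving"))
    msg <- c(msg, "direction must be moving_to_fixed or fixed_to_moving")
  if (is.null(msg)) TRUE else msg
})

#' @rdname DeformationField-class
#' @param dx,dy displacement component matrices (pixels).
#' @param resolution_um grid pixel size in micrometres.
#' @param direction mapping direction flag.
#' @export
DeformationField <- function(dx, dy, resolution_um,
                             direction = "moving_to_fixed") {
  new("DeformationField", dx = dx, dy = dy, resolution_um = resolution_um,
      direction = direction)
}

# ------------------------------------------------------------- landmarks ----

#' LandmarkSet: paired anatomical landmarks
#'
#' Pairs of corresponding points in the moving (autoradiography) and fixed
#' (cell-body stained reference) sections, in physical mm. Each pair carries
#' a role: `"fit"` landmarks guide registration, `"validation"` landmarks
#' are held back to quantify registration error.
#'
#' @slot pairs data.frame with columns `moving_x_mm`, `moving_y_mm`,
#'   `fixed_x_mm`, `fixed_y_mm`, `role`.
#' @export
setClass("LandmarkSet", representation(pairs = "data.frame"))

setValidity("LandmarkSet", function(object) {
  need <- c("moving_x_mm", "moving_y_mm", "fixed_x_mm", "fixed_y_mm", "role")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (!all(object@pairs$role %in% c("fit", "validation")))
    return("role must be 'fit' or 'validation'")
  TRUE
})

#' @rdname LandmarkSet-class
#' @param pairs landmark data.frame (see slot description).
#' @export
LandmarkSet <- function(pairs) {
  if (!"role" %in% names(pairs)) pairs$role <- "fit"
  new("LandmarkSet", pairs = pairs)
}

# --------------------------------------------------------------- midline ----

#' MidlineSpline: arc-length parameterized cortical midline
#'
#' A natural cubic spline through control points placed along the cortical
#' midline, reparameterized by arc length so that patch centres can be
#' stepped at fixed physical intervals.
#'
#' @slot control_points n x 2 matrix of (x_mm, y_mm) control points.
#' @slot fx,fy componentwise spline functions of the chord parameter.
#' @slot arc_to_t monotone lookup from arc length (mm) to chord parameter.
#' @slot total_arc_length_mm total curve length in mm.
#' @slot dense dense polyline (matrix) used for quadrature.
#' @export
setClass("MidlineSpline",
  representation(control_points = "matrix", fx = "function", fy = "function",
                 arc_to_t = "function", total_arc_length_mm = "numeric",
                 dense = "matrix"))

# ----------------------------------------------------------------- patch ----

#' PatchWindow: a square sampling window in receptor space
#'
#' @slot center_xy_mm numeric length-2 centre (x, y) in mm.
#' @slot side_mm window side length in mm (default 2).
#' @slot corner_points 4 x 2 matrix of corners (mm), row order
#'   top-left, top-right, bottom-right, bottom-left.
#' @slot section_id integer synthetic section identifier.
#' @slot area,receptor labels inherited from the section.
#' @export
setClass("PatchWindow",
  representation(center_xy_mm = "numeric", side_mm = "numeric",
                 corner_points = "matrix", section_id = "integer",
                 area = "character", receptor = "character"))

#' @rdname PatchWindow-class
#' @param center_xy_mm window centre (x, y) in mm.
#' @param side_mm side length in mm.
#' @param section_id integer section id.
#' @param area,receptor labels.
#' @export
PatchWindow <- function(center_xy_mm, side_mm = 2,
                        section_id = 1L, area = NA_character_,
                        receptor = NA_character_) {
  h <- side_mm / 2
  corners <- rbind(
    center_xy_mm + c(-h, -h), center_xy_mm + c(h, -h),
    center_xy_mm + c(h, h), center_xy_mm + c(-h, h))
  new("PatchWindow", center_xy_mm = center_xy_mm, side_mm = side_mm,
      corner_points = corners, section_id = as.integer(section_id),
      area = as.character(area), receptor = as.character(receptor))
}

setValidity("PatchWindow", function(object) {
  h <- object@side_mm / 2
  expect <- rbind(
    object@center_xy_mm + c(-h, -h), object@center_xy_mm + c(h, -h),
    object@center_xy_mm + c(h, h), object@center_xy_mm + c(-h, h))
  if (max(abs(expect - object@corner_points)) > 1e-9)
    return("corner_points inconsistent with center and side")
  TRUE
})

#' PatchPair: corresponding cyto / receptor patches
#'
#' One training example: a high-resolution cell-body stained patch and the
#' corresponding low-resolution receptor autoradiography patch, both
#' normalized to \[0, 1\]. The cyto side length is `resolution_factor` times
#' the receptor side length. Synthetic pairs additionally carry the
#' ground-truth normalized cortical depth of every receptor pixel.
#'
#' @slot cyto numeric matrix (fine grid).
#' @slot receptor numeric matrix (coarse grid).
#' @slot area `"V1"` or `"M1"`.
#' @slot receptor_type `"M2"` or `"kainate"`.
#' @slot window the originating [PatchWindow-class].
#' @slot depth ground-truth depth matrix at receptor resolution (synthetic
#'   data only; 0 x 0 matrix otherwise). `NA` outside tissue.
#' @export
setClass("PatchPair",
  representation(cyto = "matrix", receptor = "matrix", area = "character",
                 receptor_type = "character", window = "PatchWindow",
                 depth = "matrix"))

setValidity("PatchPair", function(object) {
  if (nrow(object@cyto) %% nrow(object@receptor) != 0)
    return("cyto side must be an integer multiple of the receptor side")
  TRUE
})

#' PatchDataset: a labeled collection of patch pairs
#'
#' @slot pairs list of [PatchPair-class] objects.
#' @slot section_ids integer section id per pair.
#' @slot provenance list with the generating spec, seed and exclusion log.
#' @export
setClass("PatchDataset",
  representation(pairs = "list", section_ids = "integer",
                 provenance = "list"))

setValidity("PatchDataset", function(object) {
  if (length(object@pairs) != length(object@section_ids))
    return("one section id per pair required")
  TRUE
})

# ------------------------------------------------------------- synthetic ----

#' SyntheticSpec: study conditions for the paired-section simulator
#'
#' Describes one synthetic "experiment": cortical area, receptor type,
#' canvas geometry at receptor resolution, the cyto/receptor resolution
#' ratio, ribbon thickness and curvature, noise and labeling-jitter levels,
#' and the synthetic deformation amplitude. All downstream randomness
#' derives from the single `seed`.
#'
#' @slot area `"V1"` or `"M1"`.
#' @slot receptor `"M2"` or `"kainate"`.
#' @slot canvas_px integer (height, width) of the receptor-resolution canvas.
#' @slot receptor_resolution_um receptor pixel size, micrometres.
#' @slot resolution_factor integer cyto-to-receptor grid ratio (default 16).
#' @slot ribbon_thickness_mm cortical thickness of the simulated ribbon.
#' @slot curvature `"straight"`, `"sinusoid"` or `"sulcus"`.
#' @slot curvature_amplitude_mm amplitude of the midline undulation.
#' @slot noise_sd additive intensity noise sd per modality (length 2:
#'   cyto, receptor).
#' @slot intensity_jitter relative amplitude of the smooth multiplicative
#'   labeling-intensity variation (0 disables it).
#' @slot deformation_amplitude_px maximum synthetic displacement, receptor px.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticSpec",
  representation(area = "character", receptor = "character",
                 canvas_px = "integer", receptor_resolution_um = "numeric",
                 resolution_factor = "integer", ribbon_thickness_mm = "numeric",
                 curvature = "character", curvature_amplitude_mm = "numeric",
                 noise_sd = "numeric", intensity_jitter = "numeric",
                 deformation_amplitude_px = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (!object@area %in% c("V1", "M1")) msg <- c(msg, "area must be V1 or M1")
  if (!object@receptor %in% c("M2", "kainate"))
    msg <- c(msg, "receptor must be M2 or kainate")
  if (any(object@canvas_px < 1)) msg <- c(msg, "canvas dimensions positive")
  if (object@resolution_factor < 1) msg <- c(msg, "resolution_factor >= 1")
  if (any(object@noise_sd < 0)) msg <- c(msg, "noise_sd >= 0")
  if (object@deformation_amplitude_px < 0)
    msg <- c(msg, "deformation_amplitude_px >= 0")
  if (!object@curvature %in% c("straight", "sinusoid", "sulcus"))
    msg <- c(msg, "curvature must be straight, sinusoid or sulcus")
  canvas_h_mm <- object@canvas_px[1] * object@receptor_resolution_um / 1000
  if (object@ribbon_thickness_mm + 2 * object@curvature_amplitude_mm >
      canvas_h_mm)
    msg <- c(msg, "ribbon (thickness + curvature) must fit in the canvas")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SyntheticSpec-class
#' @param area,receptor labels of the simulated experiment.
#' @param canvas_px (height, width) in receptor pixels.
#' @param receptor_resolution_um receptor pixel size in micrometres.
#' @param resolution_factor integer cyto/receptor grid ratio.
#' @param ribbon_thickness_mm simulated cortical thickness.
#' @param curvature ribbon shape.
#' @param curvature_amplitude_mm undulation amplitude in mm.
#' @param noise_sd additive noise sd, length 2 (cyto, receptor) or scalar.
#' @param intensity_jitter labeling-intensity variation amplitude.
#' @param deformation_amplitude_px max displacement of the synthetic field.
#' @param seed master seed.
#' @export
SyntheticSpec <- function(area = "V1", receptor = "M2",
                          canvas_px = c(64L, 128L),
                          receptor_resolution_um = 125,
                          resolution_factor = 16L,
                          ribbon_thickness_mm = 2.0,
                          curvature = "straight",
                          curvature_amplitude_mm = 0.5,
                          noise_sd = c(0.05, 0.02),
                          intensity_jitter = 0.1,
                          deformation_amplitude_px = 2,
                          seed = 1L) {
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 2)
  if (curvature == "straight") curvature_amplitude_mm <- 0
  new("SyntheticSpec", area = area, receptor = receptor,
      canvas_px = as.integer(canvas_px),
      receptor_resolution_um = receptor_resolution_um,
      resolution_factor = as.integer(resolution_factor),
      ribbon_thickness_mm = ribbon_thickness_mm, curvature = curvature,
      curvature_amplitude_mm = curvature_amplitude_mm, noise_sd = noise_sd,
      intensity_jitter = intensity_jitter,
      deformation_amplitude_px = deformation_amplitude_px,
      seed = as.integer(seed))
}

#' DepthMap: normalized cortical depth grid
#'
#' Depth is 0 at the pial surface and 1 at the grey/white matter boundary;
#' values are `NA` outside the tissue mask.
#'
#' @slot values numeric matrix with values in \[0, 1\] or NA.
#' @slot resolution_um grid pixel size in micrometres.
#' @export
setClass("DepthMap",
  representation(values = "matrix", resolution_um = "numeric"))

setValidity("DepthMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("all defined depth values must lie within [0, 1]")
  TRUE
})

# ----------------------------------------------------------- model specs ----

#' GeneratorSpec: declarative description of the generator network
#'
#' The generator consists of a backbone of four stride-2 convolutions that
#' reduces the fine cyto grid to the receptor grid (2048 -> 128 at
#' defaults, 64 output channels) and a U-Net head operating at receptor
#' resolution. All convolutional layers use batch-instance normalization
#' and ReLU, except the final layer which uses tanh.
#'
#' @slot variant `"single_area"`, `"cond_multi_area"` or
#'   `"uncond_multi_area"`. Exactly the conditional variant adds one extra
#'   constant-valued input channel carrying the area label.
#' @slot input_side_px,output_side_px patch sides; the ratio must equal
#'   2^(number of backbone layers).
#' @slot backbone_channels channel widths of the four backbone layers.
#' @slot unet_channels channel widths of the U-Net encoder levels.
#' @slot norm normalization policy (`"batch_instance"`).
#' @export
setClass("GeneratorSpec",
  representation(variant = "character", input_side_px = "integer",
                 output_side_px = "integer", backbone_channels = "integer",
                 unet_channels = "integer", norm = "character"))

setValidity("GeneratorSpec", function(object) {
  msg <- NULL
  fac <- object@input_side_px / object@output_side_px
  if (fac != 2^length(object@backbone_channels))
    msg <- c(msg, sprintf(
      "input/output ratio (%g) must equal 2^n backbone layers (%g)",
      fac, 2^length(object@backbone_channels)))
  if (!object@variant %in%
      c("single_area", "cond_multi_area", "uncond_multi_area"))
    msg <- c(msg, "unknown variant")
  if (object@output_side_px %% 4 != 0)
    msg <- c(msg, "output side must be divisible by 4 (U-Net depth 3)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname GeneratorSpec-class
#' @param variant conditioning variant.
#' @param input_side_px,output_side_px patch sides in pixels.
#' @param backbone_channels widths of the backbone layers (last must be 64
#'   at defaults).
#' @param unet_channels U-Net encoder widths.
#' @param norm normalization policy.
#' @export
generatorSpec <- function(variant = "single_area", input_side_px = 2048L,
                          output_side_px = 128L,
                          backbone_channels = c(8L, 16L, 32L, 64L),
                          unet_channels = c(64L, 128L, 256L),
                          norm = "batch_instance") {
  new("GeneratorSpec", variant = variant,
      input_side_px = as.integer(input_side_px),
      output_side_px = as.integer(output_side_px),
      backbone_channels = as.integer(backbone_channels),
      unet_channels = as.integer(unet_channels), norm = norm)
}

#' DiscriminatorSpec: declarative description of the discriminator
#'
#' Four (optionally five) convolutions with kernel 4, stride 2, padding 1,
#' each followed by batch normalization and LeakyReLU with negative slope
#' 0.2, then a terminal fully connected layer producing one scalar logit
#' per patch.
#'
#' @slot input_side_px receptor patch side.
#' @slot n_layers number of convolutional layers (4 default, 5 optional).
#' @slot channels channel widths per layer.
#' @slot leaky_slope LeakyReLU negative-side slope (0.2).
#' @slot conditional whether an extra constant condition channel is
#'   appended to the input.
#' @export
setClass("DiscriminatorSpec",
  representation(input_side_px = "integer", n_layers = "integer",
                 channels = "integer", leaky_slope = "numeric",
                 conditional = "logical"))

setValidity("DiscriminatorSpec", function(object) {
  if (length(object@channels) != object@n_layers)
    return("channels must have one width per layer")
  if (object@input_side_px < 2^object@n_layers)
    return("input smaller than the network's receptive reduction")
  TRUE
})

#' @rdname DiscriminatorSpec-class
#' @param input_side_px receptor patch side in pixels.
#' @param n_layers 4 (default) or 5 convolutional layers.
#' @param channels per-layer widths (defaults scale with n_layers).
#' @param leaky_slope LeakyReLU slope.
#' @param conditional append an area condition channel.
#' @export
discriminatorSpec <- function(input_side_px = 128L, n_layers = 4L,
                              channels = NULL, leaky_slope = 0.2,
                              conditional = FALSE) {
  if (is.null(channels)) channels <- 2^(2 + seq_len(n_layers))  # 8,16,32,64
  new("DiscriminatorSpec", input_side_px = as.integer(input_side_px),
      n_layers = as.integer(n_layers), channels = as.integer(channels),
      leaky_slope = leaky_slope, conditional = conditional)
}

# -------------------------------------------------------------- training ----

#' TrainingConfig: optimization settings for cGAN training
#'
#' Defaults follow the published regime: Adam with learning rate 0.001 and
#' betas (0.5, 0.99), 250 epochs, binary cross-entropy adversarial loss
#' balanced against the L1 term by gamma = 0.5, and global-norm gradient
#' clipping.
#'
#' @slot gamma adversarial / L1 balance (0.5).
#' @slot learning_rate Adam learning rate (0.001).
#' @slot beta1,beta2 Adam moment decays (0.5, 0.99).
#' @slot epochs number of passes over the training set (250).
#' @slot batch_size minibatch size (8).
#' @slot clip_norm global gradient-norm clip (1).
#' @slot seed training seed (shuffling, noise tensors, init).
#' @slot variant one of the three conditioning variants.
#' @slot adv_mode `"non_saturating"` (default) or `"minimax"` for the
#'   generator's adversarial update.
#' @export
setClass("TrainingConfig",
  representation(gamma = "numeric", learning_rate = "numeric",
                 beta1 = "numeric", beta2 = "numeric", epochs = "integer",
                 batch_size = "integer", clip_norm = "numeric",
                 seed = "integer", variant = "character",
                 adv_mode = "character"))

setValidity("TrainingConfig", function(object) {
  msg <- NULL
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (object@clip_norm <= 0) msg <- c(msg, "clip_norm must be > 0")
  if (!object@adv_mode %in% c("non_saturating", "minimax"))
    msg <- c(msg, "adv_mode must be non_saturating or minimax")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TrainingConfig-class
#' @param gamma,learning_rate,beta1,beta2,epochs,batch_size,clip_norm,seed
#'   see slot documentation.
#' @param variant conditioning variant.
#' @param adv_mode generator adversarial update mode.
#' @export
trainingConfig <- function(gamma = 0.5, learning_rate = 0.001, beta1 = 0.5,
                           beta2 = 0.99, epochs = 250L, batch_size = 8L,
                           clip_norm = 1, seed = 1L,
                           variant = "single_area",
                           adv_mode = "non_saturating") {
  new("TrainingConfig", gamma = gamma, learning_rate = learning_rate,
      beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), clip_norm = clip_norm,
      seed = as.integer(seed), variant = variant, adv_mode = adv_mode)
}

# ------------------------------------------------------------ evaluation ----

#' MetricReport: per-patch metrics with set-level aggregation
#'
#' Per-patch MAE (on z-scored intensities), PSNR (dB) and SSIM, a set-level
#' FID, and per-metric aggregates: mean, population standard deviation and
#' the least favorable ("worst") patch score -- the maximum for MAE, the
#' minimum for PSNR and SSIM.
#'
#' @slot per_patch data.frame with one row per evaluated patch.
#' @slot fid set-level Frechet distance.
#' @slot aggregates data.frame (metric, mean, sd, worst).
#' @slot constants list of metric constants (max_p, c1, c2) and the SSIM
#'   mode metadata.
#' @slot excluded data.frame logging skipped degenerate patches.
#' @export
setClass("MetricReport",
  representation(per_patch = "data.frame", fid = "numeric",
                 aggregates = "data.frame", constants = "list",
                 excluded = "data.frame"))

# ---------------------------------------------------------- section canvas --

#' SectionCanvas: accumulation buffers for patch inpainting
#'
#' @slot base the base receptor [SectionImage-class].
#' @slot accum,weight accumulation and weight buffers; overlapping patch
#'   placements are averaged as accum/weight.
#' @slot windows list of placed [PatchWindow-class] objects.
#' @export
setClass("SectionCanvas",
  representation(base = "SectionImage", accum = "matrix", weight = "matrix",
                 windows = "list"))

setValidity("SectionCanvas", function(object) {
  if (any(object@weight < 0)) return("weight buffer must be >= 0")
  TRUE
})

#' @rdname SectionCanvas-class
#' @param base base receptor section image.
#' @export
SectionCanvas <- function(base) {
  z <- matrix(0, nrow(pixels(base)), ncol(pixels(base)))
  new("SectionCanvas", base = base, accum = z, weight = z, windows = list())
}
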