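#' @include AllClasses.R
NULL

#' Accessors for ReceptorGAN data classes
#'
#' Small generic accessors used instead of direct slot access.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "SectionImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("resolutionUm", function(x) standardGeneric("resolutionUm"))
#' @rdname accessors
#' @export
setMethod("resolutionUm", "SectionImage", function(x) x@resolution_um)
#' @rdname accessors
#' @export
setMethod("resolutionUm", "DeformationField", function(x) x@resolution_um)
#' @rdname accessors
#' @export
setMethod("resolutionUm", "DepthMap", function(x) x@resolution_um)

#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @rdname accessors
#' @export
setMethod("displacements", "DeformationField",
          function(x) list(dx = x@dx, dy = x@dy))

#' @rdname accessors
#' @export
setGeneric("landmarkPairs", function(x) standardGeneric("landmarkPairs"))
#' @rdname accessors
#' @export
setMethod("landmarkPairs", "LandmarkSet", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setMethod("arcLength", "MidlineSpline", function(x) x@total_arc_length_mm)

#' @rdname accessors
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))
#' @rdname accessors
#' @export
setMethod("controlPoints", "MidlineSpline", function(x) x@control_points)

#' @rdname accessors
#' @export
setGeneric("patchPairs", function(x) standardGeneric("patchPairs"))
#' @rdname accessors
#' @export
setMethod("patchPairs", "PatchDataset", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("sectionIds", function(x) standardGeneric("sectionIds"))
#' @rdname accessors
#' @export
setMethod("sectionIds", "PatchDataset", function(x) x@section_ids)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "PatchDataset", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setMethod("depthValues", "DepthMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("perPatchMetrics", function(x) standardGeneric("perPatchMetrics"))
#' @rdname accessors
#' @export
setMethod("perPatchMetrics", "MetricReport", function(x) x@per_patch)

#' @rdname accessors
#' @export
setGeneric("metricAggregates",
           function(x) standardGeneric("metricAggregates"))
#' @rdname accessors
#' @export
setMethod("metricAggregates", "MetricReport", function(x) x@aggregates)

#' @rdname accessors
#' @export
setGeneric("fidValue", function(x) standardGeneric("fidValue"))
#' @rdname accessors
#' @export
setMethod("fidValue", "MetricReport", function(x) x@fid)

#' @rdname accessors
#' @export
setGeneric("compositedImage",
           function(x) standardGeneric("compositedImage"))

#' Length of a dataset or landmark set
#' @param x object.
#' @export
setMethod("length", "PatchDataset", function(x) length(x@pairs))
#' @rdname length-PatchDataset-method
#' @export
setMethod("length", "LandmarkSet", function(x) nrow(x@pairs))

#' Subset a PatchDataset
#' @param x a PatchDataset.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PatchDataset", function(x, i, j, ..., drop = FALSE) {
  new("PatchDataset", pairs = x@pairs[i],
      section_ids = x@section_ids[i], provenance = x@provenance)
})

# show methods ---------------------------------------------------------------

setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage [%s] %d x %d px @ %g um/px",
              object@modality, nrow(object@pixels), ncol(object@pixels),
              object@resolution_um))
  if (!is.na(object@area))
    cat(sprintf(" (%s/%s)", object@area, object@receptor))
  cat("\n")
})

setMethod("show", "DeformationField", function(object) {
  m <- sqrt(object@dx^2 + object@dy^2)
  cat(sprintf(
    "DeformationField %d x %d px @ %g um/px, direction %s, max |u| %.3f px\n",
    nrow(object@dx), ncol(object@dx), object@resolution_um,
    object@direction, max(m)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet with %d pairs (%d fit, %d validation)\n",
              nrow(object@pairs), sum(object@pairs$role == "fit"),
              sum(object@pairs$role == "validation")))
})

setMethod("show", "MidlineSpline", function(object) {
  cat(sprintf("MidlineSpline: %d control points, arc length %.2f mm\n",
              nrow(object@control_points), object@total_arc_length_mm))
})

setMethod("show", "PatchDataset", function(object) {
  areas <- vapply(object@pairs, function(p) p@area, character(1))
  cat(sprintf("PatchDataset: %d pairs, %d sections, areas: %s\n",
              length(object@pairs), length(unique(object@section_ids)),
              paste(unique(areas), collapse = "/")))
})

setMethod("show", "PatchPair", function(object) {
  cat(sprintf("PatchPair %s/%s: cyto %d^2, receptor %d^2\n",
              object@area, object@receptor_type, nrow(object@cyto),
              nrow(object@receptor)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec %s/%s: canvas %d x %d px @ %g um, factor %d, %s ribbon %g mm, seed %d\n",
    object@area, object@receptor, object@canvas_px[1], object@canvas_px[2],
    object@receptor_resolution_um, object@resolution_factor,
    object@curvature, object@ribbon_thickness_mm, object@seed))
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf(
    "GeneratorSpec [%s]: %d^2 -> %d^2, backbone %s, U-Net %s, %s norm\n",
    object@variant, object@input_side_px, object@output_side_px,
    paste(object@backbone_channels, collapse = "-"),
    paste(object@unet_channels, collapse = "-"), object@norm))
})

setMethod("show", "DiscriminatorSpec", function(object) {
  cat(sprintf(
    "DiscriminatorSpec: %d^2 input, %d conv layers (%s), LeakyReLU %.2f%s\n",
    object@input_side_px, object@n_layers,
    paste(object@channels, collapse = "-"), object@leaky_slope,
    if (object@conditional) ", conditional" else ""))
})

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(
    "TrainingConfig [%s]: lr %g, betas (%g, %g), gamma %g, %d epochs, batch %d, clip %g, seed %d\n",
    object@variant, object@learning_rate, object@beta1, object@beta2,
    object@gamma, object@epochs, object@batch_size, object@clip_norm,
    object@seed))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d patches (FID %.4g)\n",
              nrow(object@per_patch), object@fid))
  print(object@aggregates, row.names = FALSE)
})

setMethod("show", "SectionCanvas", function(object) {
  cat(sprintf("SectionCanvas %d x %d px, %d placed windows\n",
              nrow(object@accum), ncol(object@accum),
              length(object@windows)))
})
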