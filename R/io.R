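#' @include AllClasses.R
NULL

# Plain-file interfaces: single-channel float TIFFs with JSON sidecars for
# images and deformation fields, CSV for landmarks and control points, a
# JSON manifest for patch datasets.

sidecarPath <- function(path) sub("\\.tiff?$", ".json", path)

#' Read/write section images as TIFF
#'
#' Images are written as single-channel 32-bit float TIFF with intensities
#' on \[0, 1\], plus a JSON sidecar carrying resolution and labels.
#'
#' @param image a [SectionImage-class].
#' @param path output path (`.tif`).
#' @return `writeSectionImage` invisibly returns `path`;
#'   `readSectionImage` returns the [SectionImage-class].
#' @export
writeSectionImage <- function(image, path) {
  tiff::writeTIFF(clampRange(pixels(image), 0, 1), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(resolution_um = resolutionUm(image), modality = image@modality,
         area = image@area, receptor = image@receptor),
    sidecarPath(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSectionImage
#' @export
readSectionImage <- function(path) {
  px <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sidecarPath(path))
  SectionImage(px, resolution_um = meta$resolution_um,
               modality = meta$modality,
               area = if (is.null(meta$area)) NA_character_ else meta$area,
               receptor = if (is.null(meta$receptor)) NA_character_
                          else meta$receptor)
}

#' Read/write deformation fields
#'
#' Each component is written as a float TIFF; because TIFF float samples
#' are stored on \[0, 1\], the affine encoding (offset, scale) is recorded
#' in the JSON sidecar together with direction and resolution.
#'
#' @param field a [DeformationField-class].
#' @param prefix output prefix (files `<prefix>_dx.tif`,
#'   `<prefix>_dy.tif`, `<prefix>.json`).
#' @return `writeDeformationField` invisibly returns `prefix`;
#'   `readDeformationField` returns the [DeformationField-class].
#' @export
writeDeformationField <- function(field, prefix) {
  d <- displacements(field)
  rng <- range(c(d$dx, d$dy, 0))
  scale <- max(rng[2] - rng[1], 1e-12)
  tiff::writeTIFF((d$dx - rng[1]) / scale, paste0(prefix, "_dx.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF((d$dy - rng[1]) / scale, paste0(prefix, "_dy.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale, direction = field@direction,
         resolution_um = resolutionUm(field), units = "px"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeDeformationField
#' @export
readDeformationField <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  dx <- tiff::readTIFF(paste0(prefix, "_dx.tif")) * meta$scale + meta$offset
  dy <- tiff::readTIFF(paste0(prefix, "_dy.tif")) * meta$scale + meta$offset
  DeformationField(dx, dy, meta$resolution_um, direction = meta$direction)
}

#' Read/write landmark sets as CSV
#'
#' Columns: moving_x_mm, moving_y_mm, fixed_x_mm, fixed_y_mm, role.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path CSV path.
#' @return `writeLandmarks` invisibly returns `path`; `readLandmarks`
#'   returns the [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  write.csv(landmarkPairs(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) LandmarkSet(read.csv(path))

specToList <- function(spec) {
  list(area = spec@area, receptor = spec@receptor,
       canvas_px = spec@canvas_px,
       receptor_resolution_um = spec@receptor_resolution_um,
       resolution_factor = spec@resolution_factor,
       ribbon_thickness_mm = spec@ribbon_thickness_mm,
       curvature = spec@curvature,
       curvature_amplitude_mm = spec@curvature_amplitude_mm,
       noise_sd = spec@noise_sd, intensity_jitter = spec@intensity_jitter,
       deformation_amplitude_px = spec@deformation_amplitude_px,
       seed = spec@seed)
}

specFromList <- function(lst) {
  do.call(SyntheticSpec, lapply(lst, function(x) unlist(x)))
}

#' Read/write patch datasets
#'
#' A dataset directory holds per-pair TIFFs (`cyto_NNNN.tif`,
#' `receptor_NNNN.tif`, optionally `depth_NNNN.tif`) and a
#' `manifest.json` with labels, window geometry, section ids and
#' provenance.
#'
#' @param dataset a [PatchDataset-class].
#' @param dir dataset directory (created if needed).
#' @return `writePatchDataset` invisibly returns `dir`;
#'   `readPatchDataset` returns the [PatchDataset-class].
#' @export
writePatchDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(dataset@pairs))
  for (i in seq_along(dataset@pairs)) {
    p <- dataset@pairs[[i]]
    tiff::writeTIFF(clampRange(p@cyto, 0, 1),
                    file.path(dir, sprintf("cyto_%04d.tif", i)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(clampRange(p@receptor, 0, 1),
                    file.path(dir, sprintf("receptor_%04d.tif", i)),
                    bits.per.sample = 32L)
    has_depth <- length(p@depth) > 0
    if (has_depth) {
      dd <- p@depth
      dd[is.na(dd)] <- -1
      tiff::writeTIFF((dd + 1) / 2,
                      file.path(dir, sprintf("depth_%04d.tif", i)),
                      bits.per.sample = 32L)
    }
    entries[[i]] <- list(index = i, area = p@area,
                         receptor = p@receptor_type,
                         section_id = dataset@section_ids[i],
                         center_xy_mm = p@window@center_xy_mm,
                         side_mm = p@window@side_mm,
                         has_depth = has_depth)
  }
  prov <- dataset@provenance
  if (!is.null(prov$spec)) prov$spec <- specToList(prov$spec)
  jsonlite::write_json(list(n = length(entries), pairs = entries,
                            provenance = prov),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' @rdname writePatchDataset
#' @export
readPatchDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pairs <- vector("list", man$n)
  ids <- integer(man$n)
  for (e in man$pairs) {
    i <- e$index
    cyto <- tiff::readTIFF(file.path(dir, sprintf("cyto_%04d.tif", i)))
    rec <- tiff::readTIFF(file.path(dir, sprintf("receptor_%04d.tif", i)))
    depth <- matrix(numeric(0), 0, 0)
    if (isTRUE(e$has_depth)) {
      depth <- tiff::readTIFF(file.path(dir,
                                        sprintf("depth_%04d.tif", i))) * 2 - 1
      depth[depth < 0] <- NA_real_
    }
    w <- PatchWindow(unlist(e$center_xy_mm), side_mm = e$side_mm,
                     section_id = e$section_id, area = e$area,
                     receptor = e$receptor)
    pairs[[i]] <- new("PatchPair", cyto = cyto, receptor = rec,
                      area = e$area, receptor_type = e$receptor,
                      window = w, depth = depth)
    ids[i] <- as.integer(e$section_id)
  }
  prov <- man$provenance
  if (!is.null(prov$spec)) prov$spec <- specFromList(prov$spec)
  new("PatchDataset", pairs = pairs, section_ids = ids, provenance = prov)
}
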