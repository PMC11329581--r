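#' @include AllClasses.R
NULL

# Section-level qualitative outputs: generated patches are inpainted back
# at their window positions in the receptor section and the result is
# min-max contrast enhanced. Overlapping placements (the sampling scheme
# overlaps ~90%) are averaged through an accumulation/weight buffer, which
# makes compositing independent of placement order.

#' Inpaint patches into a section canvas
#'
#' Adds each patch into the canvas's accumulation buffer over its window's
#' pixel extent. Overlapping contributions are averaged; pixels never
#' covered by a patch retain the base section values.
#'
#' @param canvas a [SectionCanvas-class].
#' @param patches list of numeric matrices (receptor-resolution patches).
#' @param windows list of [PatchWindow-class] objects, one per patch; each
#'   patch's dimensions must match its window's pixel extent.
#' @return the updated [SectionCanvas-class]; retrieve the composited
#'   image with [compositedImage()].
#' @export
inpaintPatches <- function(canvas, patches, windows) {
  if (length(patches) != length(windows))
    stop("one window per patch required")
  res_mm <- canvas@base@resolution_um / 1000
  H <- nrow(canvas@accum); W <- ncol(canvas@accum)
  for (i in seq_along(patches)) {
    p <- patches[[i]]; w <- windows[[i]]
    half <- w@side_mm / 2
    c0 <- round((w@center_xy_mm[1] - half) / res_mm)
    r0 <- round((w@center_xy_mm[2] - half) / res_mm)
    if (r0 < 0 || c0 < 0 || r0 + nrow(p) > H || c0 + ncol(p) > W)
      stop(sprintf("window %d extends outside the canvas", i))
    side_px <- round(w@side_mm / res_mm)
    if (nrow(p) != side_px || ncol(p) != side_px)
      stop(sprintf("patch %d (%d px) does not match window extent (%d px)",
                   i, nrow(p), side_px))
    rr <- (r0 + 1):(r0 + nrow(p)); cc <- (c0 + 1):(c0 + ncol(p))
    canvas@accum[rr, cc] <- canvas@accum[rr, cc] + p
    canvas@weight[rr, cc] <- canvas@weight[rr, cc] + 1
    canvas@windows[[length(canvas@windows) + 1L]] <- w
  }
  canvas
}

#' @rdname inpaintPatches
#' @param x a [SectionCanvas-class].
#' @export
setMethod("compositedImage", "SectionCanvas", function(x) {
  out <- pixels(x@base)
  covered <- x@weight > 0
  out[covered] <- x@accum[covered] / x@weight[covered]
  SectionImage(out, resolutionUm(x@base), modality = "receptor",
               area = x@base@area, receptor = x@base@receptor)
})

#' Min-max contrast enhancement
#'
#' Linearly rescales intensities so the observed minimum maps to 0 and the
#' maximum to 1, preserving rank order. When a tissue mask is supplied the
#' statistics come from masked pixels only (and only those are rescaled).
#' A constant image has zero dynamic range and is returned unchanged with
#' a warning.
#'
#' @param image a [SectionImage-class].
#' @param mask optional mask [SectionImage-class] (values >= 0.5 = tissue).
#' @return the enhanced [SectionImage-class].
#' @export
minmaxEnhance <- function(image, mask = NULL) {
  px <- pixels(image)
  sel <- if (is.null(mask)) rep(TRUE, length(px)) else pixels(mask) >= 0.5
  lo <- min(px[sel]); hi <- max(px[sel])
  if (hi - lo <= 0) {
    warning("constant image: zero dynamic range, returned unchanged")
    return(image)
  }
  out <- px
  out[sel] <- (px[sel] - lo) / (hi - lo)
  SectionImage(out, resolutionUm(image), modality = image@modality,
               area = image@area, receptor = image@receptor)
}
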