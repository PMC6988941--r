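# The three stimulus-generation methods: Direct (luminance), Edge (Canny
# baseline) and the schematic SIE-OMS representation (object masks and
# silhouettes composited over structural room edges).

new_stimulus <- function(pixels, method) {
  structure(list(pixels = pixels, method = method), class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("Stimulus image (%s), %d x %d, range [%.2f, %.2f]\n",
              x$method, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.stimulus_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5)); on.exit(graphics::par(op))
  image(t(x$pixels[nrow(x$pixels):1, ]), col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = nrow(x$pixels) / ncol(x$pixels), zlim = c(0, 1), ...)
  invisible(x)
}

#' Direct stimulus: scene luminance passed through
#'
#' Converts the scene to luminance (BT.601 weights for color input) and
#' passes it through unchanged; the per-phosphene brightness averaging happens
#' later in [sample_activations()], so the two together implement the direct
#' method of activating the implant from image brightness.
#'
#' @param scene numeric matrix or H x W x 3 array in \[0, 1\].
#' @return a `stimulus_image` with `method = "direct"`.
#' @export
direct_stimulus <- function(scene) {
  new_stimulus(to_luminance(scene), "direct")
}

#' Edge stimulus: Canny baseline
#'
#' Binary stimulus from [canny()] edges of the scene luminance, dilated with a
#' disc to counter aliasing once rendered at phosphene resolution.
#'
#' @param scene numeric matrix or H x W x 3 array in \[0, 1\].
#' @param dilation_radius disc radius in pixels for the dilation (default 1).
#' @param sigma,low,high forwarded to [canny()].
#' @return a `stimulus_image` with `method = "edge"`; edge pixels 1, else 0.
#' @export
edge_stimulus <- function(scene, dilation_radius = 1L, sigma = 1,
                          low = 0.1, high = 0.2) {
  lum <- to_luminance(scene)
  e <- canny(lum, sigma = sigma, low = low, high = high) * 1
  new_stimulus(binary_dilate(e, dilation_radius), "edge")
}

#' Render object masks and silhouettes (OMS)
#'
#' Paints instances in painter's order (call [stack_instances()] first): each
#' instance's mask interior at `mask_level` gray, then its silhouette — the
#' morphological gradient of the mask, thickened to about `contour_px` — at
#' `contour_level`. Later instances overwrite earlier pixels, so with
#' score-ascending stacking the most confident instances stay visible where
#' masks overlap. The result is finally smoothed by a grayscale morphological
#' closing to reduce aliasing.
#'
#' @param instances list of [object_instance()], already stacked.
#' @param shape integer vector `c(rows, cols)` of the output raster.
#' @param contour_px approximate silhouette thickness in pixels (default 2).
#' @param smooth_radius disc radius of the final closing (default 1; 0 skips
#'   the smoothing).
#' @param mask_level,contour_level gray values for interiors (default 0.5) and
#'   silhouettes (default 1).
#' @return a `stimulus_image` with `method = "oms"`.
#' @export
render_oms <- function(instances, shape, contour_px = 2L, smooth_radius = 1L,
                       mask_level = 0.5, contour_level = 1.0) {
  out <- matrix(0, shape[1], shape[2])
  band <- max(1L, as.integer(ceiling(contour_px / 2)))
  for (inst in instances) {
    m <- inst$mask * 1
    if (!identical(dim(m), dim(out)))
      spv_input_error(sprintf("mask of '%s' does not match scene shape",
                              inst$label))
    contour <- binary_dilate(m, band) - binary_erode(m, band)
    paint <- contour > 0 | m > 0
    out[paint] <- mask_level
    out[contour > 0] <- contour_level
  }
  if (smooth_radius > 0 && length(instances))
    out <- clamp01(EBImage::closing(out, disc_brush(smooth_radius)))
  new_stimulus(out, "oms")
}

#' Binarize and thicken a structural-edge probability map
#'
#' Structural informative edges — the wall/wall, wall/floor and wall/ceiling
#' intersection lines that convey the room's 3D layout — arrive as a
#' probability map; they are thresholded and thickened for rendering.
#'
#' @param edges numeric matrix in \[0, 1\].
#' @param threshold binarization cut (default 0.5).
#' @param width_px approximate line width in pixels after thickening
#'   (default 2).
#' @return binary 0/1 matrix.
#' @export
binarize_edges <- function(edges, threshold = 0.5, width_px = 2L) {
  check_raster01(edges, "edge map")
  binary_dilate((edges >= threshold) * 1,
                max(0L, as.integer(ceiling((width_px - 1) / 2))))
}

#' Compose the SIE-OMS schematic stimulus
#'
#' Superposes the object layer over the structural-edge layer with edges always
#' as background and object masks as foreground: the edge lines are drawn
#' first at `edge_level`, then every nonzero OMS pixel overwrites them, so no
#' object pixel is ever occluded by an edge.
#'
#' @param oms a `stimulus_image` from [render_oms()].
#' @param sie numeric matrix in \[0, 1\]: structural-edge probability map.
#' @param edge_level luminance of the rendered edges (default 1).
#' @param edge_width_px forwarded to [binarize_edges()] (default 2).
#' @param edge_threshold forwarded to [binarize_edges()] (default 0.5).
#' @return a `stimulus_image` with `method = "sie_oms"`.
#' @export
compose_sie_oms <- function(oms, sie, edge_level = 1.0, edge_width_px = 2L,
                            edge_threshold = 0.5) {
  op <- if (inherits(oms, "stimulus_image")) oms$pixels else oms
  if (!identical(dim(op), dim(sie)))
    spv_input_error("OMS and SIE shapes differ")
  out <- binarize_edges(sie, edge_threshold, edge_width_px) * edge_level
  fg <- op > 0
  out[fg] <- op[fg]
  new_stimulus(out, "sie_oms")
}

#' Run one stimulus method on an annotated scene
#'
#' Dispatcher over the three methods. For `"sie_oms"` the annotation's
#' instances are class-filtered, stacked by score and rendered as OMS, then
#' composited over the structural-edge map.
#'
#' @param annotation a `scene_annotation` (see [read_annotation()] or
#'   [generate_scene()]).
#' @param method one of `"direct"`, `"edge"`, `"sie_oms"`.
#' @param ... extra arguments passed to the underlying method.
#' @return a `stimulus_image`.
#' @export
process_scene <- function(annotation, method = c("direct", "edge", "sie_oms"),
                          ...) {
  method <- match.arg(method)
  switch(method,
    direct = direct_stimulus(annotation$image),
    edge = edge_stimulus(annotation$image, ...),
    sie_oms = {
      kept <- stack_instances(filter_instances(annotation$instances))
      oms <- render_oms(kept, dim(annotation$image), ...)
      compose_sie_oms(oms, annotation$edge_map)
    })
}
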