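# Scene annotation container and on-disk interchange: 8-bit grayscale PNGs
# for images/edges, a label PNG (or per-instance binary PNGs when masks
# overlap) for instance masks, and a JSON sidecar for labels and scores.

#' The six indoor room categories
#' @export
room_labels <- c("bathroom", "bedroom", "dining_room", "kitchen",
                 "living_room", "office")

#' Assemble a scene annotation
#'
#' The unit of data the pipeline consumes: one scene image plus its instance
#' segmentation (labels, confidence scores, binary masks), structural-edge
#' map, and room category. Detector outputs and the synthetic generator both
#' produce this container.
#'
#' @param scene_id identifier string.
#' @param room_label one of [room_labels].
#' @param image luminance matrix in \[0, 1\].
#' @param instances list of [object_instance()].
#' @param edge_map structural-edge probability matrix in \[0, 1\], same shape
#'   as `image`.
#' @param image_path optional source file reference.
#' @return a `scene_annotation`.
#' @export
scene_annotation <- function(scene_id, room_label, image, instances = list(),
                             edge_map = NULL, image_path = NA_character_) {
  if (is.null(edge_map)) edge_map <- matrix(0, nrow(image), ncol(image))
  ann <- structure(list(scene_id = as.character(scene_id),
                        room_label = as.character(room_label),
                        image = image, instances = instances,
                        edge_map = edge_map, image_path = image_path),
                   class = "scene_annotation")
  bad <- validate_annotation(ann)
  if (length(bad)) spv_input_error(paste(bad, collapse = "; "))
  ann
}

#' @export
print.scene_annotation <- function(x, ...) {
  cat(sprintf("Scene '%s' (%s): %d x %d, %d instance(s)\n", x$scene_id,
              x$room_label, nrow(x$image), ncol(x$image), length(x$instances)))
  for (inst in x$instances) {
    cat("  "); print(inst)
  }
  invisible(x)
}

#' Validate a scene annotation against the data-model invariants
#'
#' @param ann a `scene_annotation` (or a bare list with the same fields).
#' @return character vector of violations; empty when the annotation is valid.
#' @export
validate_annotation <- function(ann) {
  v <- character()
  if (!ann$room_label %in% room_labels)
    v <- c(v, sprintf("room_label '%s' is not one of: %s", ann$room_label,
                      paste(room_labels, collapse = ", ")))
  if (!is.matrix(ann$image) || length(ann$image) == 0L)
    v <- c(v, "image must be a nonempty matrix")
  else if (anyNA(ann$image) || min(ann$image) < 0 || max(ann$image) > 1)
    v <- c(v, "image values must lie in [0, 1]")
  if (!is.null(ann$edge_map)) {
    if (!identical(dim(ann$edge_map), dim(ann$image)))
      v <- c(v, "edge_map shape differs from image")
    if (anyNA(ann$edge_map) || min(ann$edge_map) < 0 || max(ann$edge_map) > 1)
      v <- c(v, "edge_map values must lie in [0, 1]")
  }
  for (k in seq_along(ann$instances)) {
    inst <- ann$instances[[k]]
    who <- sprintf("instance %d ('%s')", k, inst$label)
    if (is.na(inst$score) || inst$score < 0 || inst$score > 1)
      v <- c(v, paste(who, "score outside [0, 1]"))
    if (!identical(dim(inst$mask), dim(ann$image)))
      v <- c(v, paste(who, "mask shape differs from image"))
    if (!any(inst$mask)) v <- c(v, paste(who, "mask is empty"))
  }
  v
}

write_gray_png <- function(m, path) {
  png::writePNG(m, path)
  path
}

read_gray_png <- function(path) {
  if (!file.exists(path))
    spv_error(paste("missing file:", path), "spv_missing_file_error")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

# Label values are stored as id/255 in an 8-bit PNG; a 16-bit label PNG
# (id/65535) is also recognized on read.
read_label_png <- function(path) {
  x <- read_gray_png(path)
  ids <- round(x * 255)
  if (max(abs(x * 255 - ids)) > 1e-3) ids <- round(x * 65535)
  matrix(as.integer(ids), nrow(x), ncol(x))
}

#' Write a scene annotation to a directory
#'
#' Produces `image.png`, `edges.png`, `meta.json` and the instance masks as
#' a single label image `masks.png` (pixel value = mask id) when no two masks
#' overlap, or as per-instance binary PNGs under `masks/` when they do (a
#' label image cannot express overlap).
#'
#' @param ann a `scene_annotation`.
#' @param dir parent directory; the scene is written to `dir/<scene_id>/`.
#' @return the scene directory path, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  sdir <- file.path(dir, ann$scene_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  write_gray_png(ann$image, file.path(sdir, "image.png"))
  write_gray_png(ann$edge_map, file.path(sdir, "edges.png"))

  n <- length(ann$instances)
  meta <- list(scene_id = ann$scene_id, room_label = ann$room_label,
               instances = lapply(seq_len(n), function(k) {
                 inst <- ann$instances[[k]]
                 list(label = inst$label,
                      score = round(inst$score, 6), mask_id = k)
               }))
  if (n > 0L) {
    masks <- lapply(ann$instances, `[[`, "mask")
    overlap <- n > 1L && max(Reduce(`+`, lapply(masks, `*`, 1))) > 1
    if (overlap) {
      mdir <- file.path(sdir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (k in seq_len(n))
        write_gray_png(masks[[k]] * 1, file.path(mdir, sprintf("mask_%03d.png", k)))
    } else {
      lab <- Reduce(`+`, lapply(seq_len(n), function(k) masks[[k]] * k))
      write_gray_png(lab / 255, file.path(sdir, "masks.png"))
    }
  }
  jsonlite::write_json(meta, file.path(sdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}

#' Read a scene annotation from a directory
#'
#' Inverse of [write_annotation()]; accepts both mask dialects. Errors carry
#' distinct condition classes: `spv_missing_file_error`,
#' `spv_malformed_json_error` and `spv_mask_mismatch_error` (a sidecar
#' `mask_id` with no pixels in the label image).
#'
#' @param sdir scene directory written by [write_annotation()].
#' @return a `scene_annotation`.
#' @export
read_annotation <- function(sdir) {
  mpath <- file.path(sdir, "meta.json")
  if (!file.exists(mpath))
    spv_error(paste("missing file:", mpath), "spv_missing_file_error")
  meta <- tryCatch(jsonlite::read_json(mpath),
                   error = function(e)
                     spv_error(paste("malformed JSON in", mpath),
                               "spv_malformed_json_error"))
  img <- read_gray_png(file.path(sdir, "image.png"))
  edges <- read_gray_png(file.path(sdir, "edges.png"))

  n <- length(meta$instances)
  insts <- list()
  if (n > 0L) {
    lab_path <- file.path(sdir, "masks.png")
    per_dir <- file.path(sdir, "masks")
    lab <- if (file.exists(lab_path)) read_label_png(lab_path) else NULL
    insts <- lapply(seq_len(n), function(k) {
      mi <- meta$instances[[k]]
      mask <- if (!is.null(lab)) {
        lab == mi$mask_id
      } else {
        read_gray_png(file.path(per_dir,
                                sprintf("mask_%03d.png", mi$mask_id))) > 0.5
      }
      if (!any(mask))
        spv_error(sprintf("mask_id %d of scene '%s' has no pixels",
                          mi$mask_id, meta$scene_id), "spv_mask_mismatch_error")
      object_instance(mi$label, mi$score, mask, index = k)
    })
  }
  scene_annotation(meta$scene_id, meta$room_label, img, insts, edges,
                   image_path = file.path(sdir, "image.png"))
}

#' Load a scene image as luminance, optionally resizing
#'
#' Reads a PNG scene and converts it to luminance; when `short_side` is given
#' the image is resized so its shorter side matches it — the working
#' resolution for processing real scenes, chosen to comfortably exceed the
#' phosphene grid resolution.
#'
#' @param path PNG file.
#' @param short_side target short side in pixels, or `NULL` to keep the
#'   native size (default 512).
#' @return luminance matrix in \[0, 1\].
#' @export
load_scene <- function(path, short_side = 512L) {
  if (!file.exists(path))
    spv_error(paste("missing file:", path), "spv_missing_file_error")
  x <- to_luminance(png::readPNG(path))
  if (!is.null(short_side) && min(dim(x)) != short_side) {
    f <- short_side / min(dim(x))
    x <- clamp01(EBImage::resize(x, round(nrow(x) * f), round(ncol(x) * f)))
  }
  x
}
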