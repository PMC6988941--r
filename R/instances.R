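# Segmented object instances: constructor, class filtering, occlusion-aware
# stacking order.

#' Default indoor object classes kept for schematic stimuli
#'
#' The classes a detector is allowed to contribute to a stimulus: large
#' indoor objects whose silhouette is identifiable at implant scale. Clearly
#' small objects (scissors, bananas, ...) and non-indoor classes (cars,
#' trees, ...) are excluded.
#' @export
indoor_object_classes <- c("chair", "table", "couch", "toilet", "bath",
                           "sink", "bed", "oven", "microwave",
                           "refrigerator", "laptop")

#' One segmented object instance
#'
#' @param label class name.
#' @param score detector confidence in \[0, 1\]. Confidence correlates
#'   negatively with occlusion (occluded objects present incomplete shapes),
#'   which is what makes score-based stacking a usable depth proxy.
#' @param mask binary matrix (0/1 or logical), same shape as the scene.
#' @param index integer input order, used to break score ties stably.
#' @return an `object_instance`.
#' @export
object_instance <- function(label, score, mask, index = 1L) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    spv_input_error("instance label must be a non-empty string")
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score > 1)
    spv_input_error("instance score must lie in [0, 1]")
  mask <- (as.matrix(mask) > 0)
  if (length(mask) == 0L || !any(mask))
    spv_input_error("instance mask is empty")
  structure(list(label = label, score = as.numeric(score), mask = mask,
                 index = as.integer(index)),
            class = "object_instance")
}

#' @export
print.object_instance <- function(x, ...) {
  cat(sprintf("<%s> score %.3f, %d px mask (%d x %d)\n", x$label, x$score,
              sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Keep only instances of allowed object classes
#'
#' @param instances list of [object_instance()].
#' @param allowed character vector of permitted class names; defaults to
#'   [indoor_object_classes].
#' @return the filtered list, input order preserved.
#' @export
filter_instances <- function(instances, allowed = indoor_object_classes) {
  Filter(function(inst) inst$label %in% allowed, instances)
}

#' Order instances for occlusion-aware painting
#'
#' Sorts ascending by detector score (painter's order: later = on top), so the
#' most confident — typically least occluded, frontmost — instances overwrite
#' the rest. Ties keep ascending input `index` (stable).
#'
#' @param instances list of [object_instance()].
#' @return the same instances, sorted.
#' @export
stack_instances <- function(instances) {
  if (length(instances) < 2L) return(instances)
  scores <- vapply(instances, `[[`, numeric(1), "score")
  idx <- vapply(instances, `[[`, integer(1), "index")
  instances[order(scores, idx)]
}
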