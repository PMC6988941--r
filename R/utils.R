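# Shared internal helpers: classed errors, seeded RNG scoping, raster checks.

spv_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "spv_error"), call = call))
}

spv_input_error <- function(msg) spv_error(msg, "spv_input_error")
spv_config_error <- function(msg) spv_error(msg, "spv_config_error")

#' Evaluate an expression with a local, seeded RNG state
#'
#' The global `.Random.seed` is saved and restored, so package functions that
#' consume a `seed` argument never perturb the caller's RNG stream.
#'
#' @param seed non-negative integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    spv_input_error("`seed` must be a single non-negative integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# keeps dim attributes (pmin/pmax with a scalar first argument drops them)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round() in R rounds half to even; scoring tables use conventional half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# A raster here is a plain numeric matrix, row = image row (top to bottom).
check_raster01 <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    spv_input_error(sprintf("%s must be a numeric matrix", what))
  if (length(x) == 0L) spv_input_error(sprintf("%s is empty", what))
  if (anyNA(x)) spv_input_error(sprintf("%s contains NA", what))
  if (min(x) < 0 || max(x) > 1)
    spv_input_error(sprintf("%s values must lie in [0, 1]", what))
  invisible(x)
}

# Flat disc structuring element of the given radius (radius 0 = identity).
disc_brush <- function(radius) {
  if (radius <= 0) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

binary_dilate <- function(m, radius) {
  if (radius <= 0) return(m)
  (EBImage::dilate(m, disc_brush(radius)) > 0) * 1
}

binary_erode <- function(m, radius) {
  if (radius <= 0) return(m)
  (EBImage::erode(m, disc_brush(radius)) > 0) * 1
}

#' Convert a color or gray raster to luminance
#'
#' Color arrays (H x W x 3) are converted with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); gray matrices pass through.
#'
#' @param x numeric matrix or H x W x 3 array with values in \[0, 1\].
#' @return numeric matrix of luminance in \[0, 1\].
#' @export
to_luminance <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] < 3L) x <- matrix(x[, , 1L], dim(x)[1], dim(x)[2])
    else x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
  }
  check_raster01(x, "scene")
  x
}
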