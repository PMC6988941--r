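# Phosphene simulator: tile sampling -> level quantization -> dropout ->
# Gaussian dot rendering. A processed stimulus image goes in, a simulated
# percept comes out.

#' Sample per-electrode intensities from a stimulus image
#'
#' The image is partitioned into `rows x cols` rectangular tiles (edge tiles
#' absorb the remainder when the image size is not divisible) and each
#' electrode receives the arithmetic mean luminance of its tile — the intensity
#' of a phosphene is taken from the corresponding region of the processed
#' image.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param config a [phosphene_config()].
#' @return a `rows x cols` numeric matrix of mean intensities in \[0, 1\].
#' @export
sample_activations <- function(image, config = phosphene_config()) {
  check_raster01(image)
  A_r <- tile_mean_matrix(nrow(image), config$rows)
  A_c <- tile_mean_matrix(ncol(image), config$cols)
  A_r %*% image %*% t(A_c)
}

# k x n row-stochastic matrix averaging n pixels into k tiles. Tile size is
# floor(n/k); the last tile absorbs the remainder. If n < k each tile reads
# its nearest pixel.
tile_mean_matrix <- function(n, k) {
  A <- matrix(0, k, n)
  if (n >= k) {
    step <- n %/% k
    tile <- pmin((seq_len(n) - 1L) %/% step + 1L, k)
    A[cbind(tile, seq_len(n))] <- 1
    A / rowSums(A)
  } else {
    A[cbind(seq_len(k), ceiling((seq_len(k) - 0.5) * n / k))] <- 1
    A
  }
}

#' Quantize electrode intensities to discrete luminance levels
#'
#' Maps intensity x in \[0, 1\] to `round(x * (n_levels - 1))` with halves
#' rounded up, giving integer levels 0 .. n_levels - 1. The map is monotone and
#' idempotent on already-quantized values.
#'
#' @param intensities numeric matrix in \[0, 1\].
#' @param config a [phosphene_config()] (supplies `n_levels`).
#' @return an `activation_grid`: integer level matrix plus its config.
#' @export
quantize_levels <- function(intensities, config = phosphene_config()) {
  validate_config(config)
  check_raster01(intensities, "intensities")
  lv <- matrix(as.integer(floor(intensities * (config$n_levels - 1L) + 0.5)),
               nrow(intensities), ncol(intensities))
  structure(list(levels = lv, config = config), class = "activation_grid")
}

#' @export
print.activation_grid <- function(x, ...) {
  cat(sprintf("Activation grid %d x %d, levels 0..%d (%d active)\n",
              nrow(x$levels), ncol(x$levels), x$config$n_levels - 1L,
              sum(x$levels > 0L)))
  invisible(x)
}

#' Draw a random electrode dropout mask
#'
#' Each electrode is independently dead with probability `dropout_rate`.
#' Dead electrodes model implant sites that elicit no phosphene; the mask is a
#' property of the implant, so one mask is drawn per session (per seed) and
#' reused for every stimulus, not resampled per frame. Fully reproducible given
#' `(config, seed)`.
#'
#' @param config a [phosphene_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a `dropout_mask`: logical `rows x cols` matrix `alive` plus the seed.
#' @export
make_dropout <- function(config = phosphene_config(), seed = config$seed) {
  validate_config(config)
  alive <- with_seed(seed, {
    matrix(runif(config$rows * config$cols) >= config$dropout_rate,
           config$rows, config$cols)
  })
  structure(list(alive = alive, seed = as.integer(seed)),
            class = "dropout_mask")
}

#' @export
print.dropout_mask <- function(x, ...) {
  cat(sprintf("Dropout mask %d x %d: %d dead (%.1f%%), seed %d\n",
              nrow(x$alive), ncol(x$alive), sum(!x$alive),
              100 * mean(!x$alive), x$seed))
  invisible(x)
}

# Phosphene lattice centers (pixel coordinates, 0.5 = center of first pixel).
grid_centers <- function(config) {
  spacing <- config$output_px / max(config$rows, config$cols)
  off_r <- (config$output_px - config$rows * spacing) / 2
  off_c <- (config$output_px - config$cols * spacing) / 2
  list(row = off_r + (seq_len(config$rows) - 0.5) * spacing,
       col = off_c + (seq_len(config$cols) - 0.5) * spacing,
       spacing = spacing)
}

#' Render an activation grid as a phosphene image
#'
#' Each alive electrode with level l > 0 draws an isotropic Gaussian dot at its
#' lattice point: peak luminance l / (n_levels - 1), sigma and truncation
#' radius scaling linearly with level (size and brightness proportional to the
#' sampled intensity). Dead or level-0 electrodes draw nothing. Overlapping
#' dots combine by pointwise maximum, so luminance never exceeds 1; beyond
#' `truncate_sigmas` sigma the background is exactly 0.
#'
#' @param grid an `activation_grid` from [quantize_levels()].
#' @param mask a `dropout_mask` from [make_dropout()]; `NULL` for no dropout.
#' @param config a [phosphene_config()]; defaults to the grid's.
#' @return a `phosphene_image`: `output_px x output_px` matrix in \[0, 1\].
#' @export
render_phosphenes <- function(grid, mask = NULL, config = grid$config) {
  if (!inherits(grid, "activation_grid"))
    spv_input_error("`grid` must be an activation_grid")
  validate_config(config)
  lv <- grid$levels
  if (nrow(lv) != config$rows || ncol(lv) != config$cols)
    spv_input_error("activation grid shape does not match config")
  if (!is.null(mask)) {
    if (!identical(dim(mask$alive), dim(lv)))
      spv_input_error("dropout mask shape does not match grid")
    lv <- lv * mask$alive
  }

  n <- config$output_px
  out <- matrix(0, n, n)
  g <- grid_centers(config)
  sig_max <- config$sigma_fraction * g$spacing
  lmax <- config$n_levels - 1L
  px <- seq_len(n) - 0.5

  idx <- which(lv > 0L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    scale <- lv[i, j] / lmax
    sig <- sig_max * scale
    rad <- config$truncate_sigmas * sig
    cr <- g$row[i]; cc <- g$col[j]
    rr <- which(px >= cr - rad & px <= cr + rad)
    cc_i <- which(px >= cc - rad & px <= cc + rad)
    if (!length(rr) || !length(cc_i)) next
    d2 <- outer((px[rr] - cr)^2, (px[cc_i] - cc)^2, `+`)
    dot <- scale * exp(-d2 / (2 * sig^2))
    dot[d2 > rad^2] <- 0
    out[rr, cc_i] <- pmax(out[rr, cc_i], dot)
  }
  structure(list(pixels = out, config = config), class = "phosphene_image")
}

#' @export
print.phosphene_image <- function(x, ...) {
  cat(sprintf("Phosphene image %d x %d px, %d lit pixels, max %.3f\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels > 0),
              max(x$pixels)))
  invisible(x)
}

#' @export
plot.phosphene_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5)); on.exit(graphics::par(op))
  image(t(x$pixels[nrow(x$pixels):1, ]), col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = 1, zlim = c(0, 1), ...)
  invisible(x)
}

#' Simulate the full phosphene percept of a stimulus image
#'
#' Composition of the simulator stages: per-electrode tile sampling,
#' quantization to discrete luminance levels, electrode dropout, and Gaussian
#' dot rendering.
#'
#' @param stimulus a `stimulus_image` or numeric matrix in \[0, 1\].
#' @param config a [phosphene_config()].
#' @param mask optional precomputed `dropout_mask` (one per session); by
#'   default a mask is drawn from `config$seed`.
#' @return a `phosphene_image`.
#' @examples
#' stim <- direct_stimulus(matrix(runif(64^2), 64))
#' percept <- simulate_phosphenes(stim, phosphene_config(output_px = 128))
#' @export
simulate_phosphenes <- function(stimulus, config = phosphene_config(),
                                mask = make_dropout(config)) {
  img <- if (inherits(stimulus, "stimulus_image")) stimulus$pixels else stimulus
  act <- sample_activations(img, config)
  grid <- quantize_levels(act, config)
  render_phosphenes(grid, mask, config)
}
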