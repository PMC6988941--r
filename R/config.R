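#' Phosphene grid configuration
#'
#' Bundles every parameter of the phosphene simulator: the electrode grid, the
#' number of discrete luminance levels, the electrode dropout rate, and the
#' rendering geometry. The defaults follow standard simulated-prosthetic-vision
#' practice for current retinal implants: a 32 x 32 array (1024 electrodes),
#' 8 luminance levels including off, 10\% electrode dropout, and a 20 degree
#' simulated field of view.
#'
#' @param rows,cols electrode grid dimensions (default 32 x 32).
#' @param n_levels number of luminance levels including off (default 8).
#' @param dropout_rate probability in \[0, 1\] that an electrode is dead
#'   (default 0.10).
#' @param field_of_view_deg simulated field of view in degrees (default 20).
#'   Geometry metadata only; rendering works in pixels.
#' @param output_px side length in pixels of the rendered square percept
#'   (default 512).
#' @param sigma_fraction Gaussian sigma of a max-level dot as a fraction of the
#'   inter-phosphene spacing (default 0.25, so adjacent max-level dots just
#'   touch at 2 sigma).
#' @param truncate_sigmas cutoff radius of each dot in units of its sigma
#'   (default 3); beyond it the background is exactly zero.
#' @param seed non-negative integer seed used for electrode dropout.
#'
#' @return an object of class `phosphene_config`.
#' @examples
#' cfg <- phosphene_config()
#' cfg$rows * cfg$cols  # 1024 electrodes
#' @export
phosphene_config <- function(rows = 32L, cols = 32L, n_levels = 8L,
                             dropout_rate = 0.10, field_of_view_deg = 20,
                             output_px = 512L, sigma_fraction = 0.25,
                             truncate_sigmas = 3, seed = 0L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              n_levels = as.integer(n_levels),
              dropout_rate = as.numeric(dropout_rate),
              field_of_view_deg = as.numeric(field_of_view_deg),
              output_px = as.integer(output_px),
              sigma_fraction = as.numeric(sigma_fraction),
              truncate_sigmas = as.numeric(truncate_sigmas),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "phosphene_config")
}

validate_config <- function(cfg) {
  if (cfg$rows < 1L || cfg$cols < 1L)
    spv_config_error("grid must have at least one row and one column")
  if (cfg$n_levels < 2L)
    spv_config_error("n_levels must be at least 2 (off plus one level)")
  if (is.na(cfg$dropout_rate) || cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    spv_config_error("dropout_rate must lie in [0, 1]")
  if (cfg$output_px < max(cfg$rows, cfg$cols))
    spv_config_error("output_px must be at least max(rows, cols)")
  if (cfg$sigma_fraction <= 0 || cfg$truncate_sigmas <= 0)
    spv_config_error("sigma_fraction and truncate_sigmas must be positive")
  if (cfg$seed < 0L) spv_config_error("seed must be non-negative")
  invisible(cfg)
}

#' @export
print.phosphene_config <- function(x, ...) {
  cat(sprintf(
    "Phosphene grid: %d x %d (%d electrodes), %d luminance levels\n",
    x$rows, x$cols, x$rows * x$cols, x$n_levels))
  cat(sprintf(
    "  dropout %.0f%%, FOV %g deg, render %d px, sigma %.2f spacing (cut %g sigma), seed %d\n",
    100 * x$dropout_rate, x$field_of_view_deg, x$output_px,
    x$sigma_fraction, x$truncate_sigmas, x$seed))
  invisible(x)
}

#' Read or write a phosphene configuration as a flat YAML file
#'
#' @param path file path.
#' @return `read_config()` returns a `phosphene_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) spv_error(paste("no such file:", path),
                                    "spv_missing_file_error")
  vals <- yaml::read_yaml(path)
  do.call(phosphene_config, vals[names(vals) %in% names(formals(phosphene_config))])
}

#' @rdname read_config
#' @param config a `phosphene_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
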