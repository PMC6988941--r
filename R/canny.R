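# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, hysteresis thresholding.
# Defaults mirror the common reference implementation: sigma = 1 and hysteresis
# thresholds 0.1 / 0.2 on gradient magnitude for images in [0, 1].

gaussian_taps <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g / sum(g)
}

# Replicate-padded shift of a matrix by (dr, dc).
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(h, pmax(1L, seq_len(h) + dr))
  ci <- pmin(w, pmax(1L, seq_len(w) + dc))
  m[ri, ci, drop = FALSE]
}

# Direct (non-FFT) separable convolution with replicate boundary. Exact
# summation keeps the symmetric two-pixel plateaus of step edges exactly
# tied, which the non-maximum suppression tie-break relies on.
conv_sep <- function(m, taps) {
  r <- (length(taps) - 1L) %/% 2L
  row_pass <- 0
  for (k in seq_along(taps))
    row_pass <- row_pass + taps[k] * shift_replicate(m, k - r - 1L, 0L)
  out <- 0
  for (k in seq_along(taps))
    out <- out + taps[k] * shift_replicate(row_pass, 0L, k - r - 1L)
  out
}

#' Canny edge detection
#'
#' @param image numeric luminance matrix in \[0, 1\].
#' @param sigma standard deviation of the Gaussian smoothing kernel
#'   (default 1).
#' @param low,high hysteresis thresholds on gradient magnitude (defaults 0.1
#'   and 0.2): pixels above `high` seed edges; pixels above `low` are kept only
#'   when 8-connected to a seed.
#' @return logical matrix of edge pixels, same shape as `image`.
#' @export
canny <- function(image, sigma = 1, low = 0.1, high = 0.2) {
  check_raster01(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) return(matrix(FALSE, h, w))

  sm <- conv_sep(image, gaussian_taps(sigma))

  # Sobel, separable: smooth [1 2 1] across, differentiate [1 0 -1] along
  sobel <- function(m, along_rows) {
    smooth <- c(1, 2, 1) / 4; diff <- c(1, 0, -1) / 2
    if (along_rows) {
      a <- 0; for (k in 1:3) a <- a + diff[k] * shift_replicate(m, k - 2L, 0L)
      out <- 0; for (k in 1:3) out <- out + smooth[k] * shift_replicate(a, 0L, k - 2L)
    } else {
      a <- 0; for (k in 1:3) a <- a + diff[k] * shift_replicate(m, 0L, k - 2L)
      out <- 0; for (k in 1:3) out <- out + smooth[k] * shift_replicate(a, k - 2L, 0L)
    }
    out
  }
  gx <- sobel(sm, FALSE)   # d/dcol
  gy <- sobel(sm, TRUE)    # d/drow
  mag <- sqrt(gx^2 + gy^2)

  nms <- nonmax_suppress(mag, gx, gy)
  hysteresis(nms, low, high)
}

# Keep pixels that are local maxima of gradient magnitude along the gradient
# direction, quantized to horizontal / vertical / the two diagonals.
nonmax_suppress <- function(mag, gx, gy) {
  h <- nrow(mag); w <- ncol(mag)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mag
  shift <- function(dr, dc) pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]

  ang <- atan2(gy, gx)                # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi   # fold to [0, pi)
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: gradient ~ horizontal -> compare left/right neighbours
  # sector 1: diagonal dr=+1,dc=+1; sector 2: vertical; sector 3: dr=+1,dc=-1
  n1 <- shift(0, 1); n2 <- shift(0, -1)
  d1 <- shift(1, 1); d2 <- shift(-1, -1)
  v1 <- shift(1, 0); v2 <- shift(-1, 0)
  a1 <- shift(1, -1); a2 <- shift(-1, 1)
# ties on symmetric two-pixel plateaus (sharp step edges) are broken
  # asymmetrically so exactly one side of the plateau survives
  keep <- (sector == 0L & mag >= n1 & mag > n2) |
          (sector == 1L & mag >= d1 & mag > d2) |
          (sector == 2L & mag >= v1 & mag > v2) |
          (sector == 3L & mag >= a1 & mag > a2)
  out <- mag
  out[!keep] <- 0
  out
}

# Strong pixels (> high) seed edges; weak pixels (> low) survive only in
# 8-connected components that contain a strong pixel.
hysteresis <- function(nms, low, high) {
  weak <- nms > low
  strong <- nms > high
  if (!any(strong)) return(matrix(FALSE, nrow(nms), ncol(nms)))
  lab <- label8(weak)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  matrix(lab %in% keep_ids, nrow(nms), ncol(nms)) & weak
}

# 8-connected labelling: 4-connected components from EBImage::bwlabel, then
# labels touching diagonally are merged with union-find.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (nl < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}
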