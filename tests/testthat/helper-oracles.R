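# Brute-force oracles, deliberately written as plain loops so they stay
# independent of the vectorized implementation paths they check.

# Per-tile mean by explicit pixel loops; tile size floor(n/k), last absorbs.
oracle_tile_means <- function(image, rows, cols) {
  h <- nrow(image); w <- ncol(image)
  hs <- h %/% rows; ws <- w %/% cols
  out <- matrix(NA_real_, rows, cols)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    r0 <- (i - 1) * hs + 1; r1 <- if (i == rows) h else i * hs
    c0 <- (j - 1) * ws + 1; c1 <- if (j == cols) w else j * ws
    acc <- 0; n <- 0
    for (r in r0:r1) for (cc in c0:c1) { acc <- acc + image[r, cc]; n <- n + 1 }
    out[i, j] <- acc / n
  }
  out
}

# Per-pixel max-over-electrodes Gaussian dot renderer.
oracle_render <- function(levels, alive, cfg) {
  n <- cfg$output_px
  spacing <- n / max(cfg$rows, cfg$cols)
  off_r <- (n - cfg$rows * spacing) / 2
  off_c <- (n - cfg$cols * spacing) / 2
  sig_max <- cfg$sigma_fraction * spacing
  lmax <- cfg$n_levels - 1
  out <- matrix(0, n, n)
  for (pr in seq_len(n)) for (pc in seq_len(n)) {
    best <- 0
    for (i in seq_len(cfg$rows)) for (j in seq_len(cfg$cols)) {
      l <- levels[i, j]
      if (l == 0 || !alive[i, j]) next
      s <- l / lmax
      sig <- sig_max * s
      d2 <- (pr - 0.5 - (off_r + (i - 0.5) * spacing))^2 +
            (pc - 0.5 - (off_c + (j - 0.5) * spacing))^2
      if (d2 > (cfg$truncate_sigmas * sig)^2) next
      v <- s * exp(-d2 / (2 * sig^2))
      if (v > best) best <- v
    }
    out[pr, pc] <- best
  }
  out
}

# Chebyshev-window morphology (3x3-square structuring element, radius rad),
# outside pixels treated as background.
oracle_band <- function(mask, rad) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    rr <- max(1, r - rad):min(h, r + rad)
    cw <- max(1, cc - rad):min(w, cc + rad)
    any_in <- any(mask[rr, cw])
    all_in <- all(mask[rr, cw]) &&
      (r - rad >= 1 && r + rad <= h && cc - rad >= 1 && cc + rad <= w)
    out[r, cc] <- any_in && !all_in
  }
  out
}

# Z-buffer OMS compositor: per pixel, the last instance in painter's order
# whose support (mask or contour band) covers it decides the value.
oracle_oms <- function(instances, shape, band_rad = 1,
                       mask_level = 0.5, contour_level = 1.0) {
  bands <- lapply(instances, function(inst) oracle_band(inst$mask, band_rad))
  out <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
    v <- 0
    for (k in seq_along(instances)) {
      if (bands[[k]][r, cc]) v <- contour_level
      else if (instances[[k]]$mask[r, cc]) v <- mask_level
    }
    out[r, cc] <- v
  }
  out
}

# Confusion tally by explicit counting loops.
oracle_room_tally <- function(actual, predicted) {
  rooms <- spvtools::room_labels
  counts <- matrix(0L, 6, 7, dimnames = list(rooms, c(rooms, "na")))
  for (k in seq_along(actual)) {
    p <- if (is.na(predicted[k])) "na" else predicted[k]
    counts[actual[k], p] <- counts[actual[k], p] + 1L
  }
  counts
}

toy_mask <- function(shape, r0, r1, c0, c1) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:r1, c0:c1] <- TRUE
  m
}

toy_annotation <- function(seed = 1, shape = c(16, 16), n_inst = 2,
                           overlap = FALSE) {
  set.seed(seed)
  insts <- lapply(seq_len(n_inst), function(k) {
    r0 <- sample(2:8, 1); c0 <- sample(2:8, 1)
    m <- if (overlap && k > 1) toy_mask(shape, r0, r0 + 6, c0, c0 + 6)
         else toy_mask(shape, r0, r0 + 3, ((k - 1) %% 2) * 8 + 2,
                       ((k - 1) %% 2) * 8 + 5)
    object_instance(sample(indoor_object_classes, 1), round(runif(1), 6),
                    m, k)
  })
  edge <- matrix(0, shape[1], shape[2]); edge[1, ] <- 1
  scene_annotation(sprintf("toy_%03d", seed), sample(room_labels, 1),
                   matrix(runif(prod(shape)), shape[1]), insts, edge)
}
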