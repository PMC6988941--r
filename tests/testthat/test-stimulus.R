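# Stimulus methods: direct luminance, Canny edge baseline, OMS compositing
# and SIE-OMS composition.

test_that("direct stimulus is luminance pass-through", {
  expect_equal(direct_stimulus(matrix(0.5, 8, 8))$pixels, matrix(0.5, 8, 8))
  expect_equal(direct_stimulus(matrix(1, 8, 8))$pixels, matrix(1, 8, 8))
  red <- array(0, c(8, 8, 3)); red[, , 1] <- 1
  expect_equal(direct_stimulus(red)$pixels, matrix(0.299, 8, 8))
})

test_that("edge stimulus is zero on constant images and outlines a square", {
  for (v in c(0, 0.3, 1))
    expect_equal(sum(edge_stimulus(matrix(v, 40, 40))$pixels), 0)

  img <- matrix(0, 64, 64); img[20:44, 20:44] <- 1
  e <- canny(img)
  lab <- spvtools:::label8(e)
  expect_identical(length(setdiff(unique(as.vector(lab)), 0)), 1L)
  # closed: every contour pixel continues in at least two directions
  pad <- matrix(FALSE, 66, 66); pad[2:65, 2:65] <- e
  deg <- Reduce(`+`, lapply(
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
    function(d) pad[2:65 + d[1], 2:65 + d[2]]))
  expect_gte(min(deg[e]), 2)

  # dilation with a radius-1 disc widens a 1-px line to 3 px
  line <- matrix(0, 9, 9); line[5, 2:8] <- 1
  widths <- colSums(spvtools:::binary_dilate(line, 1))[2:8]
  expect_true(all(widths == 3))
})

test_that("instance filtering keeps only allowed classes, preserving order", {
  expect_identical(filter_instances(list()), list())
  m <- toy_mask(c(16, 16), 2, 5, 2, 5)
  toilet <- object_instance("toilet", 0.9, m, 1)
  banana <- object_instance("banana", 0.8, m, 2)
  kept <- filter_instances(list(toilet, banana))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$label, "toilet")
  all_allowed <- list(toilet, object_instance("bed", 0.2, m, 2))
  expect_identical(filter_instances(all_allowed), all_allowed)
})

test_that("stacking sorts ascending by score with stable ties", {
  m <- toy_mask(c(16, 16), 2, 5, 2, 5)
  insts <- list(object_instance("bed", 0.9, m, 1),
                object_instance("chair", 0.6, m, 2),
                object_instance("table", 0.8, m, 3))
  got <- vapply(stack_instances(insts), `[[`, numeric(1), "score")
  expect_equal(got, c(0.6, 0.8, 0.9))

  ties <- list(object_instance("bed", 0.5, m, 1),
               object_instance("chair", 0.5, m, 2))
  expect_identical(vapply(stack_instances(ties), `[[`, character(1), "label"),
                   c("bed", "chair"))
  expect_identical(stack_instances(insts[1]), insts[1])

  # permutation: nothing lost or duplicated
  set.seed(2)
  many <- lapply(1:10, function(k)
    object_instance("chair", runif(1), m, k))
  expect_setequal(vapply(stack_instances(many), `[[`, integer(1), "index"),
                  1:10)
})

test_that("OMS compositing matches the z-buffer oracle on toy masks", {
  shape <- c(16, 16)
  # two overlapping squares: the higher-score instance owns the overlap
  lo <- object_instance("chair", 0.6, toy_mask(shape, 3, 9, 3, 9), 1)
  hi <- object_instance("table", 0.9, toy_mask(shape, 6, 12, 6, 12), 2)
  stacked <- stack_instances(list(hi, lo))
  out <- render_oms(stacked, shape, smooth_radius = 0)$pixels
  overlap <- toy_mask(shape, 6, 9, 6, 9)
  hi_support <- hi$mask | oracle_band(hi$mask, 1)
  expect_true(all(out[overlap & hi_support] %in% c(0.5, 1)))
  # interior-of-overlap pixels take the winner's gray, not the loser's band
  inner <- toy_mask(shape, 8, 9, 8, 9)
  expect_true(all(out[inner] == 0.5))

  set.seed(21)
  for (rep in 1:8) {
    insts <- lapply(1:3, function(k) {
      r0 <- sample(3:8, 1); c0 <- sample(3:8, 1)
      object_instance("chair", runif(1),
                      toy_mask(shape, r0, r0 + sample(2:5, 1),
                               c0, c0 + sample(2:5, 1)), k)
    })
    stacked <- stack_instances(insts)
    got <- render_oms(stacked, shape, smooth_radius = 0)$pixels
    expect_equal(got, oracle_oms(stacked, shape), tolerance = 1e-12)
  }
})

test_that("OMS ordering is idempotent and rejects mismatched masks", {
  shape <- c(16, 16)
  set.seed(7)
  insts <- lapply(1:3, function(k)
    object_instance("bed", runif(1), toy_mask(shape, k + 2, k + 7, 3, 11), k))
  a <- render_oms(stack_instances(insts), shape, smooth_radius = 0)$pixels
  b <- render_oms(stack_instances(rev(insts)), shape, smooth_radius = 0)$pixels
  expect_equal(a, b)

  small <- object_instance("bed", 0.5, toy_mask(c(8, 8), 2, 4, 2, 4), 1)
  expect_error(render_oms(list(small), shape), class = "spv_input_error")
  expect_equal(render_oms(list(), shape)$pixels, matrix(0, 16, 16))
})

test_that("SIE-OMS composition keeps objects in the foreground", {
  shape <- c(24, 24)
  sie <- matrix(0, 24, 24); sie[12, ] <- 1          # horizontal layout edge
  inst <- object_instance("couch", 0.8, toy_mask(shape, 8, 16, 8, 16), 1)
  oms <- render_oms(list(inst), shape, smooth_radius = 0)
  comp <- compose_sie_oms(oms, sie)$pixels

  expect_identical(comp[oms$pixels > 0], oms$pixels[oms$pixels > 0])
  # the edge survives only outside the object's support
  edge_cols_outside <- which(oms$pixels[12, ] == 0)
  expect_true(all(comp[12, edge_cols_outside] == 1))

  # degenerate layers
  empty_oms <- render_oms(list(), shape)
  pure_edge <- compose_sie_oms(empty_oms, sie)$pixels
  expect_true(all(pure_edge[comp_support <- sie > 0] >= 0))
  expect_gt(sum(pure_edge), 0)
  no_sie <- compose_sie_oms(oms, matrix(0, 24, 24))$pixels
  expect_equal(no_sie, oms$pixels)

  expect_error(compose_sie_oms(oms, matrix(0, 10, 10)),
               class = "spv_input_error")
})

test_that("all three methods return [0,1] rasters of the input shape", {
  ann <- generate_scene(room_spec("living_room", seed = 4, image_px = 96))
  for (m in c("direct", "edge", "sie_oms")) {
    s <- process_scene(ann, m)
    expect_identical(dim(s$pixels), dim(ann$image))
    expect_true(all(s$pixels >= 0 & s$pixels <= 1))
  }
})
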