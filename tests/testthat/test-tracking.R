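test_that("direction sampling follows the max-|dot| rule and the volume-fraction cut", {
  grid <- voxel_grid(c(3L, 3L, 3L), 1)
  f <- fibre_field(grid)
  v <- world_to_linear(grid, c(1, 1, 1))
  f <- field_add_population(f, v, c(1, 0, 0), f = 0.6, dispersion = 0)
  p <- tracking_params()
  set.seed(1)
  expect_equal(sample_direction(f, v, c(1, 0, 0), p), c(1, 0, 0))
  ## axial sign disambiguation
  expect_equal(sample_direction(f, v, c(-1, 0, 0), p), c(-1, 0, 0))
  ## subsidiary population below the 1% volume-fraction threshold is ignored
  f2 <- fibre_field(grid)
  f2 <- field_add_population(f2, v, c(1, 0, 0), f = 0.005, dispersion = 0)
  expect_null(sample_direction(f2, v, c(1, 0, 0), p))
  ## two crossing populations: previous direction picks its own bundle
  f3 <- field_add_population(f, v, c(0, 1, 0), f = 0.4, dispersion = 0)
  expect_equal(sample_direction(f3, v, c(0, 1, 0), p), c(0, 1, 0))
  expect_equal(sample_direction(f3, v, c(0.9, 0.1, 0) / sqrt(0.82), p)[1], 1)
})

test_that("a zero-dispersion streamline spans a straight tube", {
  sc <- tube_scene()
  set.seed(2)
  s <- propagate(sc$field, c(15.5, 15.5, 15.5))
  dd <- diff(s$points)
  expect_true(all(abs(sqrt(rowSums(dd^2)) - 0.5) < 1e-9))
  expect_true(all(s$reasons == "no-fibre"))
  expect_lt(min(s$points[, 1]), 4)
  expect_gt(max(s$points[, 1]), 27)
  expect_true(all(abs(s$points[, 2] - 15.5) < 1e-9))
})

test_that("a 90-degree forced turn terminates with reason curvature", {
  grid <- voxel_grid(c(9L, 9L, 9L), 1)
  f <- fibre_field(grid)
  ctr <- all_voxel_centres(grid)
  seg1 <- which(ctr[, 1] <= 4 & ctr[, 2] == 4 & ctr[, 3] == 4)
  seg2 <- which(ctr[, 1] > 4 & ctr[, 2] == 4 & ctr[, 3] == 4)
  f <- field_add_population(f, seg1, c(1, 0, 0), 0.6)
  f <- field_add_population(f, seg2, c(0, 1, 0), 0.6)
  set.seed(3)
  s <- propagate(f, c(1, 4, 4))
  expect_true("curvature" %in% s$reasons)
})

test_that("a looping circular field terminates at max_steps", {
  grid <- voxel_grid(c(24L, 24L, 24L), 1)
  f <- fibre_field(grid)
  ctr <- all_voxel_centres(grid)
  cx <- 11.5; cy <- 11.5
  r <- sqrt((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2)
  ring <- which(abs(r - 7) <= 2 & abs(ctr[, 3] - 11.5) <= 1.5)
  tang <- cbind(-(ctr[ring, 2] - cy), ctr[ring, 1] - cx, 0)
  tang <- tang / sqrt(rowSums(tang^2))
  f <- field_add_population(f, ring, tang, 0.6)
  p <- tracking_params(max_steps = 50L)
  set.seed(4)
  s <- propagate(f, c(18.5, 11.5, 11.5), p)
  expect_true(all(s$reasons == "max-steps"))
  expect_equal(nrow(s$points), 101L)  # 50 per half + seed
})

test_that("endpoint protocol on a straight tube validates every streamline", {
  sc <- tube_scene()
  prt <- make_protocol_for_bundle(sc, "tube")
  pd <- track_protocol(sc$field, prt, quick_params())
  expect_equal(pd$n_valid, pd$n_total)
  pdn <- normalise(pd)
  expect_true(all(pdn$values >= 0) && all(pdn$values <= 1))
  gt1 <- mask_dilate1(sc$ground_truth_masks$tube)
  expect_gte(sum(pdn$values[gt1$values]) / sum(pdn$values), 0.99)
})

test_that("an exclusion plane bisecting the tube voids all streamlines", {
  sc <- tube_scene()
  prt <- make_protocol_for_bundle(sc, "tube")
  plane <- array(FALSE, dim = sc$grid$shape)
  plane[16, , ] <- TRUE
  prt$exclusions <- list(binary_mask(sc$grid, plane))
  pd <- track_protocol(sc$field, prt, quick_params())
  expect_equal(pd$n_valid, 0L)
  expect_warning(pdn <- normalise(pd), "no valid")
  expect_true(all(pdn$values == 0))
})

test_that("a stop mask truncates propagation with no mass beyond it", {
  sc <- tube_scene()
  prt <- make_protocol_for_bundle(sc, "tube")
  ## stop plane just past the target cap
  stopm <- array(FALSE, dim = sc$grid$shape)
  stopm[27, , ] <- TRUE
  prt$stop <- binary_mask(sc$grid, stopm)
  pd <- track_protocol(sc$field, prt, quick_params())
  expect_gt(pd$n_valid, 0)
  beyond <- pd$values[28:32, , ]
  expect_true(all(beyond == 0))
})

test_that("normalisation divides by the valid-streamline count", {
  g <- voxel_grid(c(2L, 2L, 2L), 1)
  pd <- path_distribution(g, array(c(4, 2, 0, 0, 0, 0, 0, 0), c(2, 2, 2)),
                          n_valid = 4L)
  pdn <- normalise(pd)
  expect_equal(pdn$values[1, 1, 1], 1)
  expect_equal(pdn$values[2, 1, 1], 0.5)
  expect_error(normalise(pdn), "already")
})

test_that("tracking is bit-reproducible for a fixed seed", {
  sc <- tube_scene(n = 20L, dispersion = 10)
  prt <- make_protocol_for_bundle(sc, "tube")
  a <- track_protocol(sc$field, prt, quick_params(n_streams = 20L, seed = 9L))
  b <- track_protocol(sc$field, prt, quick_params(n_streams = 20L, seed = 9L))
  expect_identical(a$values, b$values)
  expect_identical(a$n_valid, b$n_valid)
  c_ <- track_protocol(sc$field, prt, quick_params(n_streams = 20L, seed = 10L))
  expect_false(identical(a$values, c_$values))
})

test_that("retained step pairs never exceed the curvature threshold", {
  sc <- tube_scene(n = 20L, dispersion = 25)
  costhr <- cos(80 * pi / 180)
  set.seed(11)
  for (i in 1:20) {
    s <- propagate(sc$field, c(9.5 + runif(1, -1, 1), 9.5, 9.5),
                   tracking_params(max_steps = 100L))
    if (nrow(s$points) < 3) next
    d <- diff(s$points)
    d <- d / sqrt(rowSums(d^2))
    dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
    if (s$seed_index > 1L) dots <- dots[-(s$seed_index - 1L)]  # half join is free
    expect_true(all(dots >= costhr - 1e-9))
  }
})

test_that("symmetric runs average the two normalised maps", {
  sc <- tube_scene()
  prt <- make_protocol_for_bundle(sc, "tube", style = "symmetric")
  pd <- run_symmetric(sc$field, prt, quick_params(n_streams = 10L))
  expect_true(pd$normalised)
  ## deterministic tube: forward and reverse runs see the same tube, so the
  ## averaged map is still essentially the tube membership map
  gt1 <- mask_dilate1(sc$ground_truth_masks$tube)
  expect_gte(sum(pd$values[gt1$values]) / sum(pd$values), 0.99)
  expect_error(run_symmetric(sc$field, make_protocol_for_bundle(sc, "tube"),
                             quick_params()), "symmetric flag")

  ## one-way-passable setting: the target is a fibre-free plane just past
  ## the tube cap. Forward streamlines exit the cap into the plane (valid);
  ## the swapped run seeds in the plane, finds no fibre, and yields zero
  ## valid streamlines -- so the symmetric average equals forward / 2.
  grid <- voxel_grid(c(16L, 16L, 16L), 1)
  f <- fibre_field(grid)
  ctr <- all_voxel_centres(grid)
  tubev <- which(abs(ctr[, 2] - 7.5) <= 1 & abs(ctr[, 3] - 7.5) <= 1 &
                   ctr[, 1] >= 3 & ctr[, 1] <= 12)
  f <- field_add_population(f, tubev, c(1, 0, 0), 0.6)
  seedm <- mask_from_linear(grid, tubev[ctr[tubev, 1] <= 3.5])
  plane <- array(FALSE, dim = grid$shape)
  plane[14, , ] <- TRUE  # 0-based x = 13, one voxel beyond the tube
  targm <- binary_mask(grid, plane)
  prt2 <- protocol("oneway", seed = seedm, targets = list(targm),
                   symmetric = TRUE)
  fwd <- suppressWarnings(normalise(track_protocol(f, prt2,
                                                   quick_params(n_streams = 10L))))
  expect_equal(fwd$n_valid, fwd$n_total)
  pd2 <- suppressWarnings(run_symmetric(f, prt2, quick_params(n_streams = 10L)))
  expect_equal(pd2$values, fwd$values / 2)
})
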