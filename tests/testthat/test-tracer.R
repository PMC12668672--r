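box_mask <- function(grid, xr, yr, zr) {
  ctr <- all_voxel_centres(grid)
  mask_from_linear(grid, which(ctr[, 1] >= xr[1] & ctr[, 1] <= xr[2] &
                                 ctr[, 2] >= yr[1] & ctr[, 2] <= yr[2] &
                                 ctr[, 3] >= zr[1] & ctr[, 3] <= zr[2]))
}

test_that("termination probabilities are in-mask counts over label totals", {
  grid <- voxel_grid(c(8L, 8L, 8L), 1)
  mask <- box_mask(grid, c(2, 5), c(2, 5), c(2, 5))
  ## 3 terminations in one voxel, 1 in another (single label)
  tab <- termination_table(data.frame(x = c(3, 3, 3, 4), y = 3, z = 3),
                           label = "frontal")
  tm <- termination_probability(tab, mask)
  v <- tm$maps$frontal
  expect_equal(v[4, 4, 4], 0.75)  # world (3,3,3) -> index 4
  expect_equal(v[5, 4, 4], 0.25)
  expect_equal(sum(v), 1)
  ## all terminations in one voxel
  tab1 <- termination_table(data.frame(x = 2, y = 2, z = 2), label = "parietal")
  expect_equal(max(termination_probability(tab1, mask)$maps$parietal), 1)
  ## out-of-mask terminations are dropped but the in-mask sum is still 1
  tab2 <- termination_table(data.frame(x = c(3, 7.4), y = c(3, 7.4), z = 3),
                            label = "temporal")
  tm2 <- termination_probability(tab2, mask)
  expect_equal(sum(tm2$maps$temporal), 1)
  expect_equal(unname(tm2$dropped["temporal"]), 1L)
  ## a label without in-mask terminations warns and yields zeros
  tab3 <- termination_table(data.frame(x = c(3, 7), y = c(3, 7), z = c(3, 7)),
                            label = c("a", "b"))
  expect_warning(tm3 <- termination_probability(tab3, mask), "no in-mask")
  expect_equal(sum(tm3$maps$b), 0)
  expect_error(termination_probability(tab, binary_mask(grid)), "empty")
  expect_error(termination_table(data.frame(x = Inf, y = 0, z = 0), label = "a"),
               "finite")
})

test_that("spline smoothing spreads point mass, conserves totals, keeps constants", {
  grid <- voxel_grid(c(5L, 5L, 5L), 1)
  mask <- binary_mask(grid, array(TRUE, dim = grid$shape))
  tab <- termination_table(data.frame(x = 2, y = 2, z = 2), label = "L")
  tm <- termination_probability(tab, mask)
  sm <- smooth_map(tm, smoothing_scale = 1)
  ## mass spreads off the central voxel but is conserved
  expect_lt(sm$maps$L[3, 3, 3], 1)
  expect_gt(sm$maps$L[2, 3, 3], 0)
  expect_equal(sum(sm$maps$L), 1, tolerance = 1e-9)
  ## matches a direct convolution oracle on the full 5^3 grid
  b3 <- function(t) { t <- abs(t)
    ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
           ifelse(t < 2, (2 - t)^3 / 6, 0)) }
  w <- b3(-2:2); w <- w / sum(w)
  oracle <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    oracle[i, j, k] <- w[abs(i - 3) + 3] * w[abs(j - 3) + 3] * w[abs(k - 3) + 3]
  oracle <- oracle / sum(oracle)
  expect_equal(sm$maps$L, oracle, tolerance = 1e-9)
  ## a constant map stays constant (up to edge renormalisation)
  tmc <- tm
  tmc$maps$L <- array(1 / 125, c(5, 5, 5))
  smc <- smooth_map(tmc, smoothing_scale = 0.5)
  expect_equal(sum(smc$maps$L), 1, tolerance = 1e-9)
  ## vanishing scale approaches the identity
  sm0 <- smooth_map(tm, smoothing_scale = 1e-3)
  expect_equal(sm0$maps$L, tm$maps$L, tolerance = 1e-9)
  expect_error(smooth_map(sm, 1), "already")
  expect_error(smooth_map(tm, -1), "> 0")
})

test_that("dominant labels follow maxima with declared-order tie breaks", {
  grid <- voxel_grid(c(4L, 4L, 4L), 1)
  mask <- binary_mask(grid, array(TRUE, dim = grid$shape))
  a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 0.5
  b <- array(0, c(4, 4, 4)); b[3:4, , ] <- 0.5
  dl <- dominant_label(list(first = a, second = b), mask)
  expect_true(all(dl$index[1:2, , ] == 1L))
  expect_true(all(dl$index[3:4, , ] == 2L))
  ## exact ties go to the first declared label
  tie <- dominant_label(list(first = a, second = a), mask)
  expect_true(all(tie$index[1:2, , ] == 1L))
  ## zero everywhere stays unlabelled
  expect_true(all(tie$index[3:4, , ] == 0L))
  ## single label covers the whole mask support
  one <- dominant_label(list(only = a + 0.01), mask)
  expect_true(all(one$index == 1L))
  expect_error(dominant_label(list(), mask), "empty")
})

test_that("stratified-nucleus phantom: tract and tracer layer orders agree", {
  ## four bundles from distinct cortical sources terminate in stacked
  ## z-layers of a nucleus; the dominant-label map of the tract path
  ## distributions inside the nucleus must reproduce the layer order, and a
  ## tracer-style map built from ground-truth terminations must agree.
  grid <- voxel_grid(c(24L, 24L, 24L), 1)
  labels <- c("frontal", "sensorimotor", "parietal", "temporal")
  zs <- c(8, 10, 12, 14)
  specs <- lapply(seq_along(labels), function(i)
    bundle_spec(labels[i], centreline_line(c(3, 11.5, zs[i]), c(17, 11.5, zs[i])),
                radius = 1, dispersion = 0))
  nucleus <- box_mask(grid, c(14, 19), c(9, 14), c(7, 15))
  sc <- make_scene(specs, grid, rng_seed = 2,
                   nuclei = list(nucleus = nucleus))
  pars <- quick_params(n_streams = 20L)
  pds <- lapply(labels, function(lb)
    normalise(track_protocol(sc$field, make_protocol_for_bundle(sc, lb), pars)))
  names(pds) <- labels
  dl_tract <- dominant_label(lapply(pds, `[[`, "values"), nucleus)

  ## tracer table: terminations at each bundle's end, in its own layer
  set.seed(2)
  pts <- do.call(rbind, lapply(seq_along(labels), function(i)
    data.frame(x = runif(30, 15, 18), y = runif(30, 10.5, 12.5),
               z = zs[i] + runif(30, -0.4, 0.4), label = labels[i])))
  tab <- termination_table(pts, label_set = labels)
  tm <- smooth_map(termination_probability(tab, nucleus))
  dl_tracer <- dominant_label(tm)

  ## per z-layer modal label must match the generating order for both routes
  modal <- function(dl, z) {
    sl <- dl$index[, , z + 1L]
    sl <- sl[sl > 0]
    as.integer(names(sort(table(sl), decreasing = TRUE))[1])
  }
  for (i in seq_along(zs)) {
    expect_equal(modal(dl_tract, zs[i]), i)
    expect_equal(modal(dl_tracer, zs[i]), i)
  }
  ## per-label tracer mass sums to 1 before and after smoothing
  tm_raw <- termination_probability(tab, nucleus)
  for (lb in labels) {
    expect_equal(sum(tm_raw$maps[[lb]]), 1, tolerance = 1e-9)
    expect_equal(sum(tm$maps[[lb]]), 1, tolerance = 1e-9)
  }
})
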