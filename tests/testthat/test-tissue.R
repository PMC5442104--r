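test_that("closed-disk rasterization matches exhaustive enumeration", {
  expect_identical(length(rasterize_disk(50, 600)), 7845L)
  expect_identical(length(rasterize_disk(0, 11)), 1L)
  expect_identical(length(rasterize_disk(2, 21)), 13L)
  for (r in c(1L, 3L, 7L, 15L))
    expect_identical(length(rasterize_disk(r, 101)),
                     oracle_disk_count(r))
  expect_error(rasterize_disk(300, 600), "does not fit")
})

test_that("initialization respects geometry densities and determinism", {
  geom <- geometry_params()
  st <- init_tissue(geom, seed = 7)
  cs <- count_states(st)
  expect_identical(sum(cs), 600L * 600L)
  # vessel density within binomial noise of 3.8% (5 sd)
  p_hat <- cs[["VESSEL"]] / 600^2
  expect_lt(abs(p_hat - 0.038), 5 * sqrt(0.038 * 0.962 / 600^2))
  # leak keys are exactly the vessel sites, all initialized to 1
  expect_setequal(as.integer(names(st$leak)),
                  which(st$grid == PIXEL_STATES[["VESSEL"]]))
  expect_true(all(st$leak == 1))
  # disk footprint: tumour plus overlaid vessels accounts for all 7845
  disk <- rasterize_disk(geom$tumour_radius_px, geom$grid_side)
  expect_identical(sum(st$grid[disk] %in% c(1L, 4L)), 7845L)

  expect_identical(init_tissue(geom, seed = 7)$grid, st$grid)

  st0 <- init_tissue(geometry_params(vessel_density = 0), seed = 1)
  expect_identical(count_states(st0)[["VESSEL"]], 0L)
  expect_equal(max(compute_oxygen_map(st0, oxygen_params())), 0)
  stn <- init_tissue(geometry_params(normal_fraction = 0), seed = 1)
  expect_identical(count_states(stn)[["NORMAL"]], 0L)
})

test_that("single cells divide or die by mitotic catastrophe", {
  geom <- geometry_params(grid_side = 21L, tumour_radius_px = 1L,
                          normal_fraction = 0, vessel_density = 0,
                          n_layers = 1L)
  g <- matrix(0L, 21, 21); g[11, 11] <- 1L
  set.seed(1)
  out <- grow_step(bare_state(g), geom)
  expect_identical(sum(out$grid == 1L), 2L)

  g5 <- matrix(0L, 21, 21); g5[11, 11] <- 5L
  set.seed(1)
  out5 <- grow_step(bare_state(g5), geom)
  expect_identical(sum(out5$grid != 0L), 0L)
})

test_that("growth never escapes the n-layer dilation and is monotone in n_layers", {
  set.seed(42)
  for (n in 1:3) {
    geom <- geometry_params(grid_side = 50L, tumour_radius_px = 6L,
                            normal_fraction = 0, vessel_density = 0,
                            n_layers = n)
    st <- init_tissue(geom, seed = n)
    before <- st$grid %in% c(1L, 2L, 5L)
    dim(before) <- dim(st$grid)
    reach <- before
    for (k in seq_len(n)) reach <- oracle_dilate(reach)
    out <- grow_step(st, geom)
    newcells <- (out$grid %in% c(1L, 2L, 5L)) & !before
    expect_true(all(reach[newcells]))
  }
  # per-step growth increases with the number of dividing layers
  growth <- vapply(1:4, function(n) {
    geom <- geometry_params(grid_side = 60L, tumour_radius_px = 8L,
                            normal_fraction = 0, vessel_density = 0,
                            n_layers = n)
    st <- init_tissue(geom, seed = 5)
    n0 <- viable_count(st)
    set.seed(99)
    viable_count(grow_step(st, geom)) - n0
  }, numeric(1))
  expect_true(all(diff(growth) >= 0))
})

test_that("optimized growth step matches the naive per-pixel loop oracle", {
  geom1 <- geometry_params(grid_side = 50L, tumour_radius_px = 5L,
                           n_layers = 3L)
  for (case in 1:100) {
    set.seed(1000 + case)
    g <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, 3L, 4L, 5L), 2500,
                       replace = TRUE), 50, 50)
    set.seed(case)
    fast <- grow_step(bare_state(g), geom1)$grid
    set.seed(case)
    slow <- oracle_grow_step(g, 3L)
    expect_identical(fast, slow)
  }
})

test_that("oxygen reclassification is an elementwise threshold", {
  geom <- scaled_geometry()
  st <- init_tissue(geom, seed = 3)
  set.seed(11)
  o2 <- matrix(runif(150 * 150, 0, 0.05), 150, 150)
  out <- reclassify_oxygen_types(st, o2, 0.002)
  vi <- which(st$grid == 1L | st$grid == 2L)
  expect_identical(out$grid[vi],
                   ifelse(o2[vi] < 0.002, 2L, 1L))
  # non-tumour states untouched
  expect_identical(out$grid[-vi], st$grid[-vi])
  # uniform extremes
  hi <- reclassify_oxygen_types(st, matrix(0.05, 150, 150), 0.002)
  expect_true(all(hi$grid[vi] == 1L))
  lo <- reclassify_oxygen_types(st, matrix(0, 150, 150), 0.002)
  expect_true(all(lo$grid[vi] == 2L))
  expect_error(reclassify_oxygen_types(st, matrix(0, 10, 10), 0.002),
               "shape")
})

test_that("census is conserved and empty grids count as empty", {
  st <- bare_state(matrix(0L, 40, 40))
  cs <- count_states(st)
  expect_identical(cs[["EMPTY"]], 1600L)
  expect_identical(sum(cs), 1600L)
  geom <- scaled_geometry()
  st2 <- init_tissue(geom, seed = 2)
  set.seed(8)
  st3 <- grow_step(st2, geom)
  expect_identical(sum(count_states(st3)), 150L * 150L)
})
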