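test_that("region radius follows the area formula with floor 8", {
  expect_equal(compute_region_radius(1), 8L)
  expect_equal(compute_region_radius(100), 8L)
  expect_equal(compute_region_radius(101), 11L)
  expect_equal(compute_region_radius(250), 14L)
  radii <- vapply(1:600, compute_region_radius, 0L)
  expect_true(all(diff(radii) >= 0))  # nondecreasing in area
  expect_true(all(radii >= 8L))
  expect_error(compute_region_radius(0))
})

test_that("seed and threshold come from the surface CT range", {
  tp <- compute_threshold_params(c(-950L, -920L, -900L))
  expect_equal(tp$seed, -950L)
  expect_equal(tp$threshold, 51L)
  tp0 <- compute_threshold_params(rep(-1000L, 12))
  expect_equal(tp0$seed, -1000L)
  expect_equal(tp0$threshold, 1L)
  set.seed(31)
  for (rep in 1:10) {
    hu <- sample(-1100:-700, sample(1:40, 1), replace = TRUE)
    tp <- compute_threshold_params(hu)
    expect_equal(tp$seed, min(hu))
    expect_equal(tp$threshold, max(hu) - min(hu) + 1L)
  }
  expect_error(compute_threshold_params(integer(0)), "empty")
})

test_that("seed surfaces partition the candidate mask by 26-connectivity", {
  shape <- c(10, 10, 10)
  vol <- ct_volume(array(-1000L, shape))
  expect_length(extract_seed_surfaces(array(FALSE, shape), vol), 0)
  corner <- array(FALSE, shape)
  corner[4, 4, 4] <- corner[5, 5, 5] <- TRUE
  expect_length(extract_seed_surfaces(corner, vol), 1)
  set.seed(32)
  hu <- array(sample(-1100:-800, prod(shape), replace = TRUE), shape)
  vol <- ct_volume(hu)
  m <- array(runif(prod(shape)) < 0.15, shape)
  surfs <- extract_seed_surfaces(m, vol)
  lab <- flood_label_oracle(m, 26)
  expect_length(surfs, max(lab))
  seen <- array(FALSE, shape)
  for (s in surfs) {
    expect_equal(s$area, nrow(s$voxels))
    expect_length(unique(lab[s$voxels]), 1)  # one oracle component each
    expect_identical(s$hu, hu[s$voxels])
    expect_false(any(seen[s$voxels]))
    seen[s$voxels] <- TRUE
  }
  expect_identical(seen, m)  # disjoint union equals the mask
  expect_error(extract_seed_surfaces(array(FALSE, c(2, 2, 2)), vol), "shape")
})

test_that("wall enhancement raises a thin bright plane and nothing else", {
  const <- array(-1000L, c(7, 7, 7))
  expect_identical(enhance_walls(const, 300L), const)
  plane <- array(-1000L, c(7, 7, 7))
  plane[, , 4] <- -400L
  out <- enhance_walls(plane, 300L)
  expect_true(all(out[, , 4] == -100L))
  expect_identical(out[, , -4], plane[, , -4])
  # zero strength is the identity, twice over
  expect_identical(enhance_walls(enhance_walls(plane, 0L), 0L), plane)
  expect_error(enhance_walls(array(0L, c(2, 5, 5))), "3 voxels")
})

test_that("quasi-sphere algebra holds exactly", {
  shape <- c(25, 25, 25)
  P <- array(FALSE, shape)
  P[13, 13, 13] <- TRUE
  ctx <- structure(list(R = 8L, T = array(-1000L, shape), P_area0 = P),
                   class = "region_context")
  qs <- build_quasi_sphere(ctx)
  expect_equal(sum(qs$region), sum(sphere_element(8)))  # pure ball limit
  inner <- dilate_mask(P, 7)
  expect_identical(qs$shell, qs$region & !inner)
  expect_false(any(qs$shell & inner))
  expect_true(all(qs$restricted[!qs$region] == -2048L))
  expect_true(all(qs$restricted[qs$region] == -1000L))
  # a flat plate dilates to more than a ball
  P2 <- array(FALSE, shape)
  P2[12:14, 12:14, 13] <- TRUE
  ctx2 <- structure(list(R = 8L, T = array(-1000L, shape), P_area0 = P2),
                    class = "region_context")
  qs2 <- build_quasi_sphere(ctx2)
  expect_gt(sum(qs2$region), sum(sphere_element(8)))
  expect_identical(qs2$region, dilate_oracle(P2, airwayseg:::sphere_offsets(8)))
})

test_that("init_region composes radius, window, crop and forbidden mask", {
  shape <- c(40, 40, 40)
  set.seed(33)
  hu <- array(sample(-1020:-980, prod(shape), replace = TRUE), shape)
  vol <- ct_volume(hu)
  m <- array(FALSE, shape)
  m[14:20, 14:20, 20] <- TRUE  # area 49 -> R = 8
  surf <- extract_seed_surfaces(m, vol)[[1]]
  cfg <- airway_config(region = list(enhance = FALSE))
  global <- array(FALSE, shape)
  ctx <- init_region(surf, vol, global, cfg)
  expect_equal(ctx$R, 8L)
  expect_identical(ctx$box$lo, c(6L, 6L, 12L))
  expect_identical(ctx$box$hi, c(28L, 28L, 28L))
  expect_equal(ctx$Seed, min(hu[m]))
  expect_equal(ctx$Threshold, max(hu[m]) - min(hu[m]) + 1L)
  expect_equal(ctx$Threshold0, ctx$Threshold)
  expect_equal(sum(ctx$P_area0), 49)
  # a surface at the volume corner clamps its crop
  m2 <- array(FALSE, shape)
  m2[1:3, 1:3, 1] <- TRUE
  ctx2 <- init_region(extract_seed_surfaces(m2, vol)[[1]], vol, global, cfg)
  expect_identical(ctx2$box$lo, c(1L, 1L, 1L))
  # enhancement changes the image only at marked voxels, never the window
  cfg_e <- airway_config(region = list(enhance = TRUE))
  ctx_e <- init_region(surf, vol, global, cfg_e)
  expect_equal(ctx_e$Seed, ctx$Seed)
  expect_equal(ctx_e$Threshold, ctx$Threshold)
  d <- ctx_e$T - ctx$T
  expect_true(all(d %in% c(0L, cfg_e$region$enhance_strength)))
})

test_that("bootstrap and override windows follow the configuration", {
  shape <- c(30, 30, 30)
  vol <- ct_volume(array(-1000L, shape))
  m <- array(FALSE, shape)
  m[15, 15, 15] <- TRUE
  surf <- extract_seed_surfaces(m, vol)[[1]]
  global <- array(FALSE, shape)
  ctx <- init_region(surf, vol, global, airway_config())
  expect_true(ctx$bootstrap)
  expect_equal(ctx$Threshold, 100L)  # initial_threshold_override
  ctx2 <- init_region(surf, vol, global, airway_config("leak_stress"))
  expect_equal(ctx2$Threshold, 170L)  # global override
})
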