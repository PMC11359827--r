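# build a minimal hand-made region context around an explicit image
manual_ctx <- function(hu, P, R = 8L, seed_hu = NULL, threshold = 51L,
                      forbidden = NULL, area = sum(P), bootstrap = FALSE) {
  if (is.null(seed_hu)) seed_hu <- min(hu[P])
  if (is.null(forbidden)) forbidden <- array(FALSE, dim(hu))
  structure(list(K = 1L, R = as.integer(R), Seed = as.integer(seed_hu),
                 Threshold = as.integer(threshold),
                 Threshold0 = as.integer(threshold),
                 box = crop_box(c(1, 1, 1), dim(hu), dim(hu)),
                 T = hu, T_raw = hu, P_area0 = P, forbidden = forbidden,
                 surface_area = area, bootstrap = bootstrap),
            class = "region_context")
}

test_that("one propagation step accepts exactly the windowed face neighbours", {
  hu <- array(-1000L, c(9, 9, 9))
  P <- array(FALSE, c(9, 9, 9)); P[5, 5, 5] <- TRUE
  ctx <- manual_ctx(hu, P, threshold = 51L)
  qs <- build_quasi_sphere(ctx)
  acc <- propagate_step(P, qs, ctx$Seed, ctx$Threshold, ctx$forbidden)
  expect_equal(sum(acc), 6)
  expect_identical(acc, dilate_mask(P, 1) & !P)
})

test_that("voxels outside the region are rejected by membership, not window", {
  # restricted image blanks off-region voxels to -2048, which would pass a
  # lower-bound-free window; region membership must reject them
  hu <- array(-1000L, c(9, 9, 9))
  P <- array(FALSE, c(9, 9, 9)); P[5, 5, 5] <- TRUE
  ctx <- manual_ctx(hu, P, R = 8L)
  qs <- build_quasi_sphere(ctx)
  qs$region[, , 6:9] <- FALSE  # artificially truncate the region
  qs$restricted[, , 6:9] <- -2048L
  acc <- propagate_step(P, qs, ctx$Seed, 51L, ctx$forbidden)
  expect_equal(sum(acc), 5)  # the +z neighbour is out of region
  expect_false(acc[5, 5, 6])
})

test_that("propagation step equals an exhaustive enumeration oracle", {
  set.seed(41)
  for (rep in 1:10) {
    hu <- array(sample(-1100:-900, 9^3, replace = TRUE), c(9, 9, 9))
    X <- array(runif(9^3) < 0.1, c(9, 9, 9))
    if (!any(X)) X[5, 5, 5] <- TRUE
    ctx <- manual_ctx(hu, X, R = 5L, seed_hu = -1050L, threshold = 100L)
    qs <- build_quasi_sphere(ctx)
    forb <- array(runif(9^3) < 0.05, c(9, 9, 9))
    acc <- propagate_step(X, qs, -1050L, 100L, forb)
    # oracle: every face neighbour of X, window + region + forbidden rules
    expected <- array(FALSE, c(9, 9, 9))
    nb <- neigh_offsets(6)
    for (i in which(X)) {
      co <- arrayInd(i, c(9L, 9L, 9L))
      for (k in 1:6) {
        u <- co + nb[k, ]
        if (any(u < 1) || any(u > 9)) next
        if (X[u[1], u[2], u[3]] || forb[u[1], u[2], u[3]]) next
        if (!qs$region[u[1], u[2], u[3]]) next
        if (qs$restricted[u[1], u[2], u[3]] - (-1050L) >= 100L) next
        expected[u[1], u[2], u[3]] <- TRUE
      }
    }
    expect_identical(acc, expected)
  }
})

test_that("in-region segmentation equals BFS threshold growing when leak rules are off", {
  set.seed(42)
  cfg <- airway_config(region = list(enhance = FALSE),
                       wavefront = list(leak_rules = FALSE,
                                        fill_holes = FALSE))
  for (rep in 1:10) {
    hu <- array(sample(-1100:-850, 20^3, replace = TRUE), c(20, 20, 20))
    P <- array(FALSE, c(20, 20, 20))
    P[9:11, 9:11, 10] <- TRUE
    ctx <- manual_ctx(hu, P, R = 8L, threshold = sample(30:150, 1))
    qs <- build_quasi_sphere(ctx)
    res <- segment_region(ctx, qs, cfg)
    oracle <- bfs_growing_oracle(qs$restricted, qs$region, ctx$forbidden,
                                 which(P), ctx$Seed, ctx$Threshold)
    expect_identical(res$X, oracle)
    expect_false(res$leak_detected)
    # containment and window invariants
    expect_true(all(res$X <= qs$region))
    grown <- res$X & !P
    expect_true(all(hu[grown] - ctx$Seed < ctx$Threshold))
  }
})

test_that("monotone growth: each iteration only adds voxels", {
  fx <- tube_region_fixture(config = airway_config(
    region = list(enhance = FALSE), wavefront = list(leak_rules = FALSE)))
  X <- fx$ctx$P_area0
  for (i in 1:10) {
    acc <- propagate_step(X, fx$qs, fx$ctx$Seed, fx$ctx$Threshold,
                          fx$ctx$forbidden)
    X2 <- X | acc
    expect_true(all(X <= X2))
    X <- X2
  }
})

test_that("the growth leak rule fires, decays the threshold, and can abandon", {
  # a tiny seed in a wide-open dark space: the front grows much faster than
  # 2.5 x area(seed), so every attempt leaks and the threshold decays to 0
  hu <- array(-1000L, c(21, 21, 21))
  P <- array(FALSE, c(21, 21, 21)); P[11, 11, 11] <- P[11, 12, 11] <- TRUE
  ctx <- manual_ctx(hu, P, R = 9L, threshold = 40L)
  qs <- build_quasi_sphere(ctx)
  res <- segment_region(ctx, qs, airway_config())
  expect_true(res$leak_detected)
  expect_identical(res$X, P)  # reset to the seed set
  expect_equal(res$threshold_used, 0L)
  expect_equal(res$leak_events, 40L)  # one decay per attempt
  expect_false(is.null(res$X_leak))
  expect_gt(sum(res$X_leak), sum(P))
})

test_that("bifurcation counting is the boundary component count", {
  shape <- c(20, 20, 20)
  shell <- array(FALSE, shape); shell[, , 18] <- TRUE
  X <- array(FALSE, shape)
  X[4:6, 4:6, 10:16] <- TRUE
  expect_equal(count_bifurcations(X, shell), 0)  # never reaches the shell
  X[4:6, 4:6, 17:19] <- TRUE
  expect_equal(count_bifurcations(X, shell), 1)
  X[12:14, 12:14, 10:19] <- TRUE
  expect_equal(count_bifurcations(X, shell), 2)
  expect_error(count_bifurcations(X, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("a straight tube keeps its radius and yields one next surface", {
  fx <- tube_region_fixture()
  out <- adapt_radius(fx$ctx, fx$qs, fx$config)
  expect_equal(out$ctx$R, fx$ctx$R)  # count 1 immediately, no adaptation
  expect_equal(out$result$bifurcation_count, 1)
  expect_length(out$result$next_surfaces, 1)
  s <- out$result$next_surfaces[[1]]
  # next surface lives on the shell, mapped back to parent coordinates
  local <- sweep(s$voxels, 2L, out$ctx$box$lo - 1L)
  expect_true(all(out$qs$shell[local]))
  expect_true(all(out$result$X[local]))
})

test_that("a dead-end pouch reduces the radius to the floor and terminates", {
  # tube ends inside the region: bifurcation count 0 at every radius
  fx <- tube_region_fixture(z_surface = 44)  # at the capped tube end
  out <- adapt_radius(fx$ctx, fx$qs, fx$config)
  expect_equal(out$ctx$R, 8L)
  expect_equal(out$result$bifurcation_count, 0)
  expect_length(out$result$next_surfaces, 0)
})

test_that("radius adaptation resolves a double bifurcation", {
  spec <- phantom_spec(shape = c(80, 80, 72), generations = 3L,
                       root_radius = 5, root_length = 12, length_decay = 0.9,
                       branch_angle = 45, wall_thickness = 3L, noise_sd = 5)
  b <- generate_phantom(spec)
  cfg <- airway_config(region = list(enhance = FALSE))
  # a radius spanning both bifurcation generations
  ctx <- cross_section_ctx(b, 13, 24L, cfg)
  qs <- build_quasi_sphere(ctx)
  first <- segment_region(ctx, qs, cfg)
  expect_gt(first$bifurcation_count, 2)
  out <- adapt_radius(ctx, qs, cfg)
  expect_true(out$result$bifurcation_count %in% c(1L, 2L) || out$ctx$R == 8L)
  expect_lt(out$ctx$R, 24L)
})

test_that("oversized boundary surfaces are dropped by the area rule", {
  fx <- tube_region_fixture(config = airway_config(
    "leak_stress", wavefront = list(area_factor = 0.01)))
  res <- segment_region(fx$ctx, fx$qs, fx$config)
  expect_gt(res$bifurcation_count, 0)
  expect_length(res$next_surfaces, 0)  # all surfaces exceed 0.01 x area
})

test_that("segmentation within a region is deterministic", {
  fx <- tube_region_fixture()
  r1 <- segment_region(fx$ctx, fx$qs, fx$config)
  r2 <- segment_region(fx$ctx, fx$qs, fx$config)
  expect_identical(r1$X, r2$X)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$threshold_used, r2$threshold_used)
})
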