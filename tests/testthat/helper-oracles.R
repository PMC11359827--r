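# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's morphology kernels: plain R loops and queue-based
# flood fills.

# 6- or 26-neighbourhood offsets as an n x 3 matrix
neigh_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# flood-fill component labelling, scan-order labels
flood_label_oracle <- function(mask, connectivity) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nb <- neigh_offsets(connectivity)
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(nb))) {
        u <- co + nb[k, ]
        if (any(u < 1L) || any(u > dims)) next
        ui <- u[1] + (u[2] - 1L) * dims[1] + (u[3] - 1L) * dims[1] * dims[2]
        if (mask[ui] && lab[ui] == 0L) { lab[ui] <- cur; queue <- c(queue, ui) }
      }
    }
  }
  lab
}

# brute-force binary dilation with an offset set
dilate_oracle <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (i in which(mask)) {
    co <- arrayInd(i, dims)
    for (k in seq_len(nrow(offsets))) {
      u <- co + offsets[k, ]
      if (all(u >= 1L) && all(u <= dims)) out[u[1], u[2], u[3]] <- TRUE
    }
  }
  out
}

erode_oracle <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (i in which(mask)) {
    co <- arrayInd(i, dims)
    keep <- TRUE
    for (k in seq_len(nrow(offsets))) {
      u <- co + offsets[k, ]
      if (any(u < 1L) || any(u > dims) || !mask[u[1], u[2], u[3]]) {
        keep <- FALSE; break
      }
    }
    if (keep) out[co[1], co[2], co[3]] <- TRUE
  }
  out
}

# background voxels 6-connected to the border (for hole-filling checks)
border_flood_oracle <- function(mask) {
  dims <- dim(mask)
  vis <- array(FALSE, dims)
  nb <- neigh_offsets(6)
  queue <- integer()
  for (i in seq_len(prod(dims))) {
    co <- arrayInd(i, dims)
    if (any(co == 1L) || any(co == dims)) {
      if (!mask[i] && !vis[i]) { vis[i] <- TRUE; queue <- c(queue, i) }
    }
  }
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    co <- arrayInd(v, dims)
    for (k in seq_len(nrow(nb))) {
      u <- co + nb[k, ]
      if (any(u < 1L) || any(u > dims)) next
      ui <- u[1] + (u[2] - 1L) * dims[1] + (u[3] - 1L) * dims[1] * dims[2]
      if (!mask[ui] && !vis[ui]) { vis[ui] <- TRUE; queue <- c(queue, ui) }
    }
  }
  vis
}

# plain BFS threshold region growing confined to `region`: the independent
# reference for the wavefront core (preallocated queue, head pointer)
bfs_growing_oracle <- function(hu, region, forbidden, seeds, seed_hu,
                               threshold) {
  dims <- dim(hu)
  X <- array(FALSE, dims)
  X[seeds] <- TRUE
  queue <- integer(prod(dims))
  queue[seq_along(which(X))] <- which(X)
  head <- 1L; tail <- sum(X)
  nb <- neigh_offsets(6)
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    co <- arrayInd(v, dims)
    for (k in seq_len(nrow(nb))) {
      u <- co + nb[k, ]
      if (any(u < 1L) || any(u > dims)) next
      ui <- u[1] + (u[2] - 1L) * dims[1] + (u[3] - 1L) * dims[1] * dims[2]
      if (X[ui] || !region[ui] || forbidden[ui]) next
      if (hu[ui] - seed_hu >= threshold) next
      X[ui] <- TRUE
      tail <- tail + 1L
      queue[tail] <- ui
    }
  }
  X
}

# a single-region context built around a cross-section of a straight-tube
# phantom, for wavefront/sealing unit tests
tube_region_fixture <- function(gaps = list(), z_surface = 22,
                                config = airway_config("leak_stress"),
                                shape = c(64, 64, 64), noise_sd = 10) {
  spec <- phantom_spec(shape = shape, generations = 1L, root_radius = 7,
                       root_length = 30, noise_sd = noise_sd, gaps = gaps)
  bundle <- generate_phantom(spec)
  disk <- array(FALSE, shape)
  disk[, , z_surface] <- bundle$lumen[, , z_surface]
  surf <- extract_seed_surfaces(disk, bundle$volume)[[1]]
  global <- array(FALSE, shape)
  global[, , 1:(z_surface - 1)] <- bundle$lumen[, , 1:(z_surface - 1)]
  ctx <- init_region(surf, bundle$volume, global, config)
  qs <- build_quasi_sphere(ctx)
  list(bundle = bundle, surface = surf, ctx = ctx, qs = qs, config = config)
}

# a region context around a lumen cross-section with an explicit radius and
# a crop box matching it (for radius-adaptation fixtures)
cross_section_ctx <- function(bundle, z_surface, R,
                              config = airway_config(region = list(enhance = FALSE))) {
  shape <- dim(bundle$volume$data)
  global <- array(FALSE, shape)
  global[, , 1:(z_surface - 1)] <- bundle$lumen[, , 1:(z_surface - 1)]
  disk <- array(FALSE, shape)
  disk[, , z_surface] <- bundle$lumen[, , z_surface]
  surf <- extract_seed_surfaces(disk, bundle$volume)[[1]]
  ctx <- init_region(surf, bundle$volume, global, config)
  box <- expand_box(surf$bbox, R, shape)
  P <- array(FALSE, box$hi - box$lo + 1L)
  P[sweep(surf$voxels, 2L, box$lo - 1L)] <- TRUE
  ctx$R <- as.integer(R)
  ctx$box <- box
  ctx$T <- ctx$T_raw <- crop(bundle$volume, box)$data
  ctx$P_area0 <- P
  ctx$forbidden <- crop(global, box) & !P
  ctx
}

# Chebyshev distance from each row of `pts` to the nearest row of `ref`
max_chebyshev_to_set <- function(pts, ref) {
  if (nrow(pts) == 0L) return(0L)
  max(vapply(seq_len(nrow(pts)), function(i) {
    min(apply(abs(sweep(ref, 2L, pts[i, ])), 1L, max))
  }, 0))
}
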