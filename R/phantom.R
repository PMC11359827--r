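#' Synthetic airway phantom specification
#'
#' Describes a branching-tube CT phantom: a binary tree of straight
#' cylindrical segments with a dark lumen, a bright thin wall (with
#' spherical end caps), parenchyma background, optional Gaussian noise and
#' deliberately inserted low-brightness wall gaps. HU defaults respect the
#' certainty bands used for small-airway analysis: lumen at or below
#' -950 HU (definite airway), parenchyma strictly inside (-950, -775)
#' (uncertain band, where leakage originates), wall above it.
#'
#' @param shape Volume dimensions in voxels, default `c(96, 96, 96)`.
#' @param generations Number of branching generations (>= 1); the tree has
#'   `2^generations - 1` straight segments.
#' @param root_radius Lumen radius of the trachea segment, voxels (>= 2).
#' @param radius_decay Child/parent radius ratio in (0, 1].
#' @param branch_angle Half-opening angle at a bifurcation, degrees.
#' @param root_length Trachea segment length, voxels.
#' @param length_decay Child/parent length ratio in (0, 1].
#' @param wall_thickness Wall shell thickness, voxels (>= 1).
#' @param lumen_hu,wall_hu,parenchyma_hu Tissue HU values
#'   (`lumen_hu < parenchyma_hu < wall_hu`).
#' @param noise_sd Gaussian noise standard deviation, HU (0 disables).
#' @param gaps List of [gap_spec()] objects.
#' @param rng_seed Integer seed making noise (the only random element)
#'   reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), generations = 3L,
                         root_radius = 7, radius_decay = 0.75,
                         branch_angle = 40, root_length = 26,
                         length_decay = 0.8, wall_thickness = 4L,
                         lumen_hu = -1000L, wall_hu = -400L,
                         parenchyma_hu = -880L, noise_sd = 10,
                         gaps = list(), rng_seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (generations < 1L) stop("phantom_spec: generations must be >= 1")
  if (root_radius < 2) stop("phantom_spec: root_radius must be >= 2")
  if (wall_thickness < 1) stop("phantom_spec: wall_thickness must be >= 1")
  if (radius_decay <= 0 || radius_decay > 1 || length_decay <= 0 ||
      length_decay > 1)
    stop("phantom_spec: decay factors must be in (0, 1]")
  if (!(lumen_hu < parenchyma_hu && parenchyma_hu < wall_hu))
    stop("phantom_spec: need lumen_hu < parenchyma_hu < wall_hu")
  if (lumen_hu > -950)
    stop("phantom_spec: lumen_hu must be <= -950 (definite-airway band)")
  if (parenchyma_hu <= -950 || parenchyma_hu >= -775)
    stop("phantom_spec: parenchyma_hu must lie in (-950, -775)")
  for (g in gaps) stopifnot(inherits(g, "gap_spec"))
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  structure(list(shape = shape, generations = as.integer(generations),
                 root_radius = root_radius, radius_decay = radius_decay,
                 branch_angle = branch_angle, root_length = root_length,
                 length_decay = length_decay,
                 wall_thickness = wall_thickness,
                 lumen_hu = as.integer(lumen_hu),
                 wall_hu = as.integer(wall_hu),
                 parenchyma_hu = as.integer(parenchyma_hu),
                 noise_sd = noise_sd, gaps = gaps,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Wall gap specification
#'
#' A low-brightness channel pierced radially through the wall of one branch:
#' the wall voxels within a cylinder of diameter `extent` around a radial
#' ray from the branch axis get HU `gap_hu`. Gaps up to 3 voxels wide are
#' the sealable range of the closing-based gap localization; wider gaps
#' (for negative tests) require `allow_oversize = TRUE`.
#'
#' @param branch_id Branch to pierce (1 = trachea; children of branch `i`
#'   are `2i` and `2i + 1`).
#' @param axial_position Fraction in \[0, 1\] along the branch axis.
#' @param extent Gap diameter in voxels; 1-3 unless `allow_oversize`.
#' @param gap_hu HU written into the gap voxels (a low-brightness wall;
#'   must satisfy `lumen_hu < gap_hu < wall_hu`).
#' @param azimuth Angle (degrees) of the radial ray around the branch axis.
#' @param allow_oversize Permit `extent > 3`.
#' @return A `gap_spec` list.
#' @export
gap_spec <- function(branch_id, axial_position, extent, gap_hu = -900L,
                     azimuth = 0, allow_oversize = FALSE) {
  extent <- as.integer(extent)
  if (extent < 1L) stop("gap_spec: extent must be >= 1")
  if (extent > 3L && !allow_oversize)
    stop("gap_spec: extent > 3 exceeds the sealable range; ",
         "set allow_oversize = TRUE for negative tests")
  if (axial_position < 0 || axial_position > 1)
    stop("gap_spec: axial_position must be in [0, 1]")
  structure(list(branch_id = as.integer(branch_id),
                 axial_position = axial_position, extent = extent,
                 gap_hu = as.integer(gap_hu), azimuth = azimuth),
            class = "gap_spec")
}

rotate_about <- function(v, axis, theta) {
  # Rodrigues rotation of v about unit axis
  axis <- axis / sqrt(sum(axis^2))
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic binary tree of straight segments. Branch ids follow heap
# numbering: root 1, children of i are 2i and 2i+1.
build_tree <- function(spec) {
  branches <- vector("list", 2L^spec$generations - 1L)
  start0 <- c(floor(spec$shape[1] / 2), floor(spec$shape[2] / 2),
              round(spec$root_radius + spec$wall_thickness + 3))
  grow <- function(id, gen, start, dir) {
    len <- spec$root_length * spec$length_decay^(gen - 1)
    radius <- spec$root_radius * spec$radius_decay^(gen - 1)
    end <- start + dir * len
    branches[[id]] <<- list(id = id, gen = gen, start = start, end = end,
                            dir = dir, length = len, radius = radius)
    if (gen < spec$generations) {
      theta <- spec$branch_angle * pi / 180
      ref <- if (gen %% 2L == 1L) c(0, 1, 0) else c(1, 0, 0)
      axis <- pracma_cross(dir, ref)
      if (sqrt(sum(axis^2)) < 1e-8) axis <- pracma_cross(dir, c(1, 0, 0))
      grow(2L * id, gen + 1L, end, rotate_about(dir, axis, theta))
      grow(2L * id + 1L, gen + 1L, end, rotate_about(dir, axis, -theta))
    }
  }
  grow(1L, 1L, start0, c(0, 0, 1))
  branches
}

# mark voxels of the sub-box around a capsule (segment with end caps)
# whose distance to the segment is <= radius; returns linear indices
capsule_voxels <- function(start, end, radius, shape) {
  lo <- pmax(1L, floor(pmin(start, end) - radius - 1))
  hi <- pmin(shape, ceiling(pmax(start, end) + radius + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  d <- end - start
  len2 <- sum(d^2)
  wx <- px - start[1]; wy <- py - start[2]; wz <- pz - start[3]
  t <- (wx * d[1] + wy * d[2] + wz * d[3]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- wx - t * d[1]; dy <- wy - t * d[2]; dz <- wz - t * d[3]
  keep <- dx * dx + dy * dy + dz * dz <= radius^2
  (px + (py - 1L) * shape[1] + (pz - 1L) * shape[1] * shape[2])[keep]
}

centerline_voxels <- function(branch, shape) {
  n <- max(2L, ceiling(branch$length * 4))
  t <- seq(0, 1, length.out = n)
  pts <- round(cbind(branch$start[1] + t * (branch$end[1] - branch$start[1]),
                     branch$start[2] + t * (branch$end[2] - branch$start[2]),
                     branch$start[3] + t * (branch$end[3] - branch$start[3])))
  pts <- unique(pts)
  as.integer(pts[, 1] + (pts[, 2] - 1) * shape[1] +
               (pts[, 3] - 1) * shape[1] * shape[2])
}

#' Generate a synthetic branching-tube CT phantom
#'
#' Rasterizes the tree described by a [phantom_spec()]: the volume starts at
#' `parenchyma_hu`, the wall shell (capsule of radius lumen + wall around
#' each segment, minus the lumen) is set to `wall_hu`, the lumen to
#' `lumen_hu`; gaps are applied, then rounded Gaussian noise is added and
#' values are clamped to the -2048 HU floor. Deterministic given
#' `rng_seed`; the caller's RNG state is preserved.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_bundle` list: `volume` ([ct_volume()]), logical masks
#'   `lumen`, `wall`, `centerline`, per-branch geometry `branches` (each with
#'   its own centerline indices), `gaps` (each with its realized `voxels`),
#'   `branch_count`, `tree_length_voxels`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  branches <- build_tree(spec)
  margin <- spec$wall_thickness + 1
  for (b in branches) {
    lo <- pmin(b$start, b$end) - b$radius - margin
    hi <- pmax(b$start, b$end) + b$radius + margin
    if (any(lo < 1) || any(hi > shape))
      stop("generate_phantom: branch ", b$id, " exceeds the volume bounds")
  }
  n <- prod(shape)
  lumen <- logical(n); wallzone <- logical(n); cl <- logical(n)
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    lumen[capsule_voxels(b$start, b$end, b$radius, shape)] <- TRUE
    wallzone[capsule_voxels(b$start, b$end, b$radius + spec$wall_thickness,
                            shape)] <- TRUE
    branches[[i]]$centerline <- centerline_voxels(b, shape)
    cl[branches[[i]]$centerline] <- TRUE
  }
  wall <- wallzone & !lumen
  vol <- rep(spec$parenchyma_hu, n)
  vol[wall] <- spec$wall_hu
  vol[lumen] <- spec$lumen_hu
  dim(vol) <- shape
  wall_arr <- array(wall, dim = shape)
  volume <- ct_volume(vol)
  gaps <- spec$gaps
  for (i in seq_along(gaps)) {
    res <- apply_gap(volume, wall_arr, gaps[[i]],
                     branches[[gaps[[i]]$branch_id]])
    volume <- res$volume
    gaps[[i]]$voxels <- res$gap_voxels
  }
  if (spec$noise_sd > 0) {
    seed_keep <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(seed_keep)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", seed_keep, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$rng_seed)
    noisy <- volume$data + as.integer(round(rnorm(n, 0, spec$noise_sd)))
    noisy[noisy < HU_FLOOR] <- HU_FLOOR
    volume <- ct_volume(array(noisy, dim = shape))
  }
  structure(list(volume = volume,
                 lumen = array(lumen, dim = shape),
                 wall = wall_arr,
                 centerline = array(cl, dim = shape),
                 branches = branches, gaps = gaps,
                 branch_count = length(branches),
                 tree_length_voxels = sum(vapply(branches, `[[`, 0, "length")),
                 spec = spec),
            class = "phantom_bundle")
}

#' Pierce a low-brightness gap through a branch wall
#'
#' Overwrites with `gap_hu` exactly the wall voxels inside a cylinder of
#' diameter `extent` around the radial ray leaving the branch axis at
#' `axial_position` in direction `azimuth`. No other voxel changes.
#'
#' @param volume A [ct_volume()].
#' @param wall Logical wall mask matching `volume`.
#' @param gap A [gap_spec()].
#' @param branch Branch geometry record (from a `phantom_bundle`):
#'   a list with `start`, `end`, `dir`.
#' @return List with the modified `volume` and `gap_voxels`, an n x 3
#'   integer matrix of the changed voxels.
#' @export
apply_gap <- function(volume, wall, gap, branch) {
  stopifnot(inherits(volume, "ct_volume"), inherits(gap, "gap_spec"))
  if (!identical(dim(wall), dim(volume$data)))
    stop("apply_gap: wall mask shape mismatch")
  d <- branch$dir / sqrt(sum(branch$dir^2))
  ref <- c(0, 0, 1)
  b1 <- pracma_cross(d, ref)
  if (sqrt(sum(b1^2)) < 1e-8) b1 <- pracma_cross(d, c(1, 0, 0))
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- pracma_cross(d, b1)
  az <- gap$azimuth * pi / 180
  u <- cos(az) * b1 + sin(az) * b2
  # snap to the lattice so thin (extent 1) channels hit voxel columns
  centre <- round(branch$start + gap$axial_position * (branch$end - branch$start))
  wv <- which(wall, arr.ind = TRUE)
  if (nrow(wv) == 0L) stop("apply_gap: wall mask is empty")
  w <- sweep(wv, 2L, centre)
  s <- as.vector(w %*% u)
  lat2 <- rowSums(w^2) - s^2
  sel <- s >= 0 & lat2 <= (gap$extent / 2)^2
  if (!any(sel))
    stop("apply_gap: no wall voxels at the requested gap position ",
         "(branch ", gap$branch_id, ", t = ", gap$axial_position, ")")
  gv <- wv[sel, , drop = FALSE]
  data <- volume$data
  data[gv] <- gap$gap_hu
  list(volume = ct_volume(data, volume$spacing, volume$origin),
       gap_voxels = matrix(as.integer(gv), ncol = 3L))
}
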