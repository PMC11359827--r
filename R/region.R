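#' Extract seed surfaces from a candidate mask
#'
#' Splits a binary mask into its 26-connected components, each becoming one
#' seed surface for a later segmentation stage. Components are labelled in
#' deterministic column-major scan order. Surface HU values are read from
#' the (unenhanced) volume.
#'
#' @param candidate Logical 3D mask, same shape as `volume`.
#' @param volume A [ct_volume()].
#' @return List of `seed_surface` objects, each with `voxels` (n x 3 matrix,
#'   parent coordinates), `area`, `hu` (surface CT values) and `bbox`.
#' @export
extract_seed_surfaces <- function(candidate, volume) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!identical(dim(candidate), dim(volume$data)))
    stop("extract_seed_surfaces: mask shape does not match the volume")
  lab <- label_components(candidate, 26L)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  idx <- which(lab > 0L)
  ord <- order(lab[idx], idx)
  idx <- idx[ord]
  labs <- lab[idx]
  shape <- dim(candidate)
  coords <- arrayInd(idx, shape)
  hu <- volume$data[idx]
  lapply(seq_len(nlab), function(k) {
    sel <- labs == k
    new_seed_surface(matrix(as.integer(coords[sel, , drop = FALSE]),
                            ncol = 3L),
                     hu[sel], shape)
  })
}

new_seed_surface <- function(voxels, hu, parent_shape, K = NA_integer_) {
  structure(list(K = K, voxels = voxels, area = nrow(voxels),
                 hu = as.integer(hu),
                 bbox = bbox_of_voxels(voxels, parent_shape)),
            class = "seed_surface")
}

#' Region radius from the seed-surface area
#'
#' The seed surface approximates the airway cross-section, so its voxel
#' count stands in for the cross-sectional area:
#' `R = 3 * ceiling(area / 100) + 5`, floored at the minimum radius 8.
#'
#' @param surface A `seed_surface`, or directly an integer area.
#' @return Integer radius in voxels (>= 8).
#' @export
compute_region_radius <- function(surface) {
  area <- if (inherits(surface, "seed_surface")) surface$area else surface
  if (area < 1) stop("compute_region_radius: area must be >= 1")
  max(8L, 3L * as.integer(ceiling(area / 100)) + 5L)
}

#' Seed and threshold from the seed-surface CT values
#'
#' `Seed` is the minimum CT value on the surface and `Threshold` the width
#' of its CT range plus one, so the initial acceptance window exactly covers
#' the surface values.
#'
#' @param surface A `seed_surface`, or directly an integer vector of HU
#'   values.
#' @return List with integer `seed` (HU) and `threshold` (HU width >= 1).
#' @export
compute_threshold_params <- function(surface) {
  hu <- if (inherits(surface, "seed_surface")) surface$hu else as.integer(surface)
  if (length(hu) == 0L) stop("compute_threshold_params: empty surface")
  list(seed = min(hu), threshold = max(hu) - min(hu) + 1L)
}

#' Tracheal wall enhancement
#'
#' Marks, along each axis, voxels that are a local brightness maximum with
#' at least one axis neighbour more than `min_gradient` HU darker (a tissue
#' interface); the per-axis marked runs are thinned to their first brightest
#' voxel along that axis, and `strength` HU is added to the union of the
#' thinned sheets. On a constant image the output is identical to the input.
#'
#' @param T 3D integer array (a cropped CT image), at least 3 voxels per
#'   axis.
#' @param strength HU added to the enhanced wall sheet.
#' @param min_gradient Smallest axis difference (HU) treated as an
#'   interface; differences below it (e.g. plain noise) are ignored.
#' @return Array of the same shape with enhanced walls.
#' @export
enhance_walls <- function(T, strength = 300L, min_gradient = 100L) {
  shape <- dim(T)
  if (any(shape < 3L)) stop("enhance_walls: need at least 3 voxels per axis")
  if (strength == 0L) return(T)
  marked <- array(FALSE, dim = shape)
  Td <- T + 0.0  # double copy; NA padding marks "no neighbour"
  for (ax in 1:3) {
    lower <- shift_arr(Td, ax, +1L, fill = NA_real_)
    upper <- shift_arr(Td, ax, -1L, fill = NA_real_)
    # local max along the axis with at least one steep dark side
    is_max <- (is.na(lower) | Td >= lower) & (is.na(upper) | Td >= upper)
    steep <- (!is.na(lower) & Td - lower >= min_gradient) |
      (!is.na(upper) & Td - upper >= min_gradient)
    m <- is_max & steep
    m[is.na(m)] <- FALSE
    # thin: drop a marked voxel whose predecessor along the axis is marked
    # and at least as bright (keeps the sheet one voxel wide across its
    # normal without eroding it laterally)
    prev_m <- shift_arr(m, ax, +1L, fill = FALSE)
    drop <- prev_m & !is.na(lower) & lower >= Td
    m <- m & !drop
    marked <- marked | m
  }
  out <- T
  out[marked] <- out[marked] + as.integer(strength)
  out
}

# shift an array by `by` voxels along axis `ax` (positive: values move to
# higher indices), padding with `fill`
shift_arr <- function(a, ax, by, fill) {
  out <- array(fill, dim = dim(a))
  n <- dim(a)[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) 1L:(n - by) else (1L - by):n
  dst <- if (by > 0L) (1L + by):n else 1L:(n + by)
  if (ax == 1L) out[dst, , ] <- a[src, , ]
  else if (ax == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

#' Initialize a quasi-spherical constraint region
#'
#' Composes the initialization steps for one seed surface: region radius
#' from the surface area, `Seed`/`Threshold` from the surface CT values
#' (with the configured overrides), crop box expanded by `R` and clamped to
#' the volume, optional wall enhancement of the cropped image, and the
#' forbidden mask of already-segmented voxels. The single-voxel bootstrap
#' surface (the user seed) has no meaningful CT range, so its window width
#' comes from `region$initial_threshold_override`.
#'
#' @param surface A `seed_surface` in parent coordinates.
#' @param volume The full [ct_volume()].
#' @param global_segmented Logical mask of all voxels already segmented.
#' @param config An [airway_config()].
#' @return A `region_context`: `K`, `R`, `Seed`, `Threshold`, `Threshold0`,
#'   `box`, `T` (cropped, possibly enhanced image), `P_area0` and
#'   `forbidden` (logical arrays in crop coordinates), `surface_area`,
#'   `bootstrap` flag.
#' @export
init_region <- function(surface, volume, global_segmented,
                        config = airway_config()) {
  stopifnot(inherits(surface, "seed_surface"), inherits(volume, "ct_volume"))
  R <- compute_region_radius(surface)
  tp <- compute_threshold_params(surface)
  bootstrap <- surface$area == 1L
  threshold <- tp$threshold
  if (bootstrap)
    threshold <- as.integer(config$region$initial_threshold_override)
  if (!is.null(config$region$threshold_override))
    threshold <- as.integer(config$region$threshold_override)
  box <- expand_box(surface$bbox, R, dim(volume$data))
  T_raw <- crop(volume, box)$data
  Tc <- T_raw
  if (isTRUE(config$region$enhance))
    Tc <- enhance_walls(Tc, config$region$enhance_strength,
                        config$region$enhance_min_gradient)
  cs <- box_shape(box)
  local_vox <- sweep(surface$voxels, 2L, box$lo - 1L)
  P <- array(FALSE, dim = cs)
  P[local_vox] <- TRUE
  forb <- crop(global_segmented, box) & !P
  structure(list(K = surface$K, R = R, Seed = tp$seed,
                 Threshold = threshold, Threshold0 = threshold,
                 box = box, T = Tc, T_raw = T_raw, P_area0 = P,
                 forbidden = forb,
                 surface_area = surface$area, bootstrap = bootstrap),
            class = "region_context")
}

#' Build the quasi-spherical region, its boundary shell and restricted image
#'
#' The constraint region is the dilation of the seed-surface matrix by the
#' spherical element of radius `R`; the shell is that region minus the
#' dilation by `Sphere(R - 1)` (the outermost layer); the restricted image
#' equals the cropped CT inside the region and the CT floor (-2048 HU)
#' outside it, so propagation can never leave the region.
#'
#' @param ctx A `region_context` from [init_region()].
#' @return A `quasi_sphere`: logical arrays `region` and `shell`, integer
#'   array `restricted`, and the radius `R` used.
#' @export
build_quasi_sphere <- function(ctx) {
  stopifnot(inherits(ctx, "region_context"))
  region <- dilate_mask(ctx$P_area0, ctx$R)
  inner <- dilate_mask(ctx$P_area0, ctx$R - 1L)
  shell <- region & !inner
  restricted <- ctx$T
  restricted[!region] <- HU_FLOOR
  structure(list(region = region, shell = shell, restricted = restricted,
                 R = ctx$R),
            class = "quasi_sphere")
}
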