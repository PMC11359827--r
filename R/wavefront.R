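#' One wavefront propagation step
#'
#' Computes the candidate layer `XΔ = dilate(X, Sphere(1)) - X` and applies
#' the threshold judgment: a candidate is rejected when its restricted CT
#' value minus `Seed` reaches `Threshold`; voxels outside the constraint
#' region (blanked to -2048 in the restricted image) are rejected by region
#' membership, and voxels in `forbidden` (already segmented elsewhere) are
#' rejected as well. Note the window has no lower bound: voxels darker than
#' the seed-surface minimum are more surely airway.
#'
#' @param X Logical mask of the current segmentation state (crop
#'   coordinates).
#' @param qs A `quasi_sphere` from [build_quasi_sphere()].
#' @param Seed,Threshold Integer HU seed value and window width.
#' @param forbidden Logical mask of voxels that may never be accepted.
#' @return Logical mask of the accepted candidates only.
#' @export
propagate_step <- function(X, qs, Seed, Threshold, forbidden = NULL) {
  if (is.null(forbidden)) forbidden <- array(FALSE, dim = dim(X))
  cand <- dilate_mask(X, 1L) & !X
  cand & qs$region & !forbidden & (qs$restricted - Seed < Threshold)
}

#' Segment within one constraint region
#'
#' Runs the iterative wavefront from the seed-surface matrix until the
#' front stops growing, with two leak rules: the iteration count is bounded
#' by the region radius (`2R + iteration_slack`), and each iteration may
#' accept at most `growth_factor * area(P_area0)` voxels (airway width
#' decreases gradually; a faster-growing front is leakage). When a rule
#' fires, the segmentation resets to the seed surface and the threshold
#' decays by 1; at threshold 0 the region is abandoned
#' (`leak_detected = TRUE`). On success interior holes are filled,
#' boundary-shell components are counted as bifurcations, and next-stage
#' seed surfaces are extracted. Both leak rules are skipped for the
#' single-voxel bootstrap region, whose seed area carries no width
#' information.
#'
#' @param ctx A `region_context`.
#' @param qs Matching `quasi_sphere`.
#' @param config An [airway_config()].
#' @return A `region_result`: `X` (logical, crop coordinates),
#'   `iterations`, `leak_detected`, `leak_events` (number of leak-rule
#'   firings during threshold decay), `threshold_used`,
#'   `bifurcation_count`, `next_surfaces` (parent coordinates),
#'   `radius_used`.
#' @export
segment_region <- function(ctx, qs, config = airway_config()) {
  stopifnot(inherits(ctx, "region_context"), inherits(qs, "quasi_sphere"))
  wf <- config$wavefront
  seeds <- which(ctx$P_area0)
  dims <- as.integer(dim(ctx$P_area0))
  use_rules <- isTRUE(wf$leak_rules) && !isTRUE(ctx$bootstrap)
  cap_iters <- if (use_rules) 2L * ctx$R + as.integer(wf$iteration_slack) else -1L
  growth_cap <- if (use_rules) wf$growth_factor * ctx$surface_area else -1
  threshold <- ctx$Threshold
  leak_events <- 0L
  X_leak <- NULL
  repeat {
    at <- cpp_segment_attempt(ctx$T, qs$region, ctx$forbidden, seeds, dims,
                              ctx$Seed, threshold, cap_iters, growth_cap)
    if (at$leak == 0L) break
    leak_events <- leak_events + 1L
    # first leaking attempt (widest window) is kept as the leaky
    # segmentation: gap localization needs the full leak blob
    if (is.null(X_leak)) X_leak <- array(at$X, dim = dims)
    threshold <- threshold - 1L
    if (threshold <= 0L) {
      return(new_region_result(ctx$P_area0, 0L, TRUE, leak_events, 0L,
                               0L, list(), ctx$R, X_leak))
    }
  }
  X <- array(at$X, dim = dims)
  if (isTRUE(wf$fill_holes)) X <- fill_holes(X)
  boundary <- X & qs$shell
  bif <- max(label_components(boundary, 26L))
  nxt <- extract_next_surfaces(boundary, ctx, config)
  new_region_result(X, at$iterations, FALSE, leak_events, threshold,
                    bif, nxt, ctx$R, X_leak)
}

new_region_result <- function(X, iterations, leak_detected, leak_events,
                              threshold_used, bifurcation_count,
                              next_surfaces, radius_used, X_leak = NULL) {
  structure(list(X = X, iterations = iterations,
                 leak_detected = leak_detected, leak_events = leak_events,
                 threshold_used = threshold_used,
                 bifurcation_count = bifurcation_count,
                 next_surfaces = next_surfaces, radius_used = radius_used,
                 X_leak = X_leak),
            class = "region_result")
}

#' Count airway bifurcations at the region boundary
#'
#' The number of 26-connected components of the intersection between a
#' segmentation and the region's boundary shell. One component means the
#' airway crossed the boundary without branching; two means a single
#' bifurcation; zero means the segmentation never reached the boundary.
#'
#' @param X Logical segmentation mask.
#' @param shell Logical boundary shell (same shape).
#' @return Integer component count.
#' @export
count_bifurcations <- function(X, shell) {
  if (!identical(dim(X), dim(shell)))
    stop("count_bifurcations: shape mismatch")
  max(label_components(X & shell, 26L))
}

# boundary components -> next-stage seed surfaces in parent coordinates;
# surfaces violating the area leak rule are dropped (logged via attribute)
extract_next_surfaces <- function(boundary, ctx, config) {
  lab <- label_components(boundary, 26L)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  area_cap <- if (isTRUE(ctx$bootstrap)) Inf
              else config$wavefront$area_factor * ctx$surface_area
  idx <- which(lab > 0L)
  coords <- arrayInd(idx, dim(boundary))
  labs <- lab[idx]
  out <- list()
  for (k in seq_len(nlab)) {
    sel <- labs == k
    vox_local <- coords[sel, , drop = FALSE]
    if (nrow(vox_local) > area_cap) next  # boundary-area leak rule
    vox_parent <- sweep(vox_local, 2L, ctx$box$lo - 1L, `+`)
    hu <- ctx$T_raw[vox_local]  # threshold statistics use the unenhanced CT
    out[[length(out) + 1L]] <-
      new_seed_surface(matrix(as.integer(vox_parent), ncol = 3L), hu,
                       ctx$box$parent_shape)
  }
  out
}

#' Adapt the region radius to the single-branching principle
#'
#' Re-runs the in-region segmentation while the boundary bifurcation count
#' is 0 (the front never reached the boundary: the region is too large for
#' a terminal or stalled airway) or greater than 2 (multiple bifurcations
#' inside one region), shrinking the radius by `radius_step` each time,
#' down to the fixed floor of 8 voxels. Stops as soon as the count is 1 or
#' 2, or the floor is reached, or the region was abandoned for leakage.
#'
#' @param ctx A `region_context`.
#' @param qs Matching `quasi_sphere`.
#' @param config An [airway_config()].
#' @return List with the final `ctx`, `qs` and `result`.
#' @export
adapt_radius <- function(ctx, qs, config = airway_config()) {
  repeat {
    result <- segment_region(ctx, qs, config)
    n <- result$bifurcation_count
    if (result$leak_detected || n %in% c(1L, 2L) || ctx$R <= 8L) break
    ctx$R <- max(8L, ctx$R - as.integer(config$wavefront$radius_step))
    qs <- build_quasi_sphere(ctx)
  }
  list(ctx = ctx, qs = qs, result = result)
}
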