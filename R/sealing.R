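#' Locate tracheal wall gaps by closing-operation differencing
#'
#' When segmentation has leaked through a low-brightness wall gap, the
#' combined segmentation consists of the airway lumen and a leak blob
#' separated by the thin wall, which appears as a narrow background slit.
#' The first closing fills that slit: `D1 = close(X) - X` recovers the wall
#' sheet, pierced exactly where the leak crossed. A second closing of the
#' sheet fills the pierced hole, so `close(D1) - D1` gives the location and
#' size of the gap. Spurious closing responses are discarded by three
#' filters: a gap voxel either stayed in the retained segmentation or was
#' never segmented (voxels only in the leak blob are its collar, not wall
#' passage); each gap component must touch definite wall (CT at or above
#' `wall_level`) — a gap is a hole in an otherwise bright wall; and each
#' component must bridge the wall, touching the retained segmentation on
#' one side and the leak blob on the other. Gaps wider than the closing can
#' bridge (about `2 * close_radius` voxels) are not recovered.
#'
#' @param X_combined Logical mask: leaky segmentation, retained
#'   segmentation, previous-round segmentation and seed set combined (crop
#'   coordinates).
#' @param close_radius Radius of the spherical closing element, voxels.
#' @param hu Integer array of CT values matching `X_combined` (the cropped,
#'   possibly already partially sealed image).
#' @param wall_level CT value (HU) at or above which a voxel counts as
#'   definite wall for the adjacency filter.
#' @param clean Optional logical mask of the retained (non-leak)
#'   segmentation plus previously segmented territory; with `leak`, enables
#'   the bridge filter.
#' @param leak Optional logical mask of the leak blob
#'   (leaky minus retained segmentation). A gap is the passage the leak
#'   crossed, so each gap component must touch both sides; with no leak
#'   there is no gap and the result is empty.
#' @param sealed Optional logical mask of voxels sealed in earlier rounds;
#'   adjacency to them is accepted in place of leak adjacency (a wide gap
#'   is sealed from the rim inward over successive rounds).
#' @return Integer n x 3 matrix of gap voxel coordinates (possibly 0 rows).
#' @export
locate_gaps <- function(X_combined, close_radius, hu, wall_level,
                        clean = NULL, leak = NULL, sealed = NULL) {
  none <- matrix(integer(0), ncol = 3L)
  bridge <- !is.null(clean) && !is.null(leak)
  if (bridge && !any(leak) && (is.null(sealed) || !any(sealed))) return(none)
  off <- sphere_offsets(close_radius)
  Xc <- as_mask(X_combined)
  D1 <- close_mask(Xc, offsets = off) & !Xc
  # the wall sheet: the closing response between the two masses plus the
  # definitely-bright wall; the gap is the pierced hole the second closing
  # fills in this sheet
  bright <- hu >= wall_level
  sheet <- D1 | bright
  cand <- close_mask(sheet, offsets = off) & !sheet
  if (!any(cand)) return(none)
  # a wall passage either stayed in the retained segmentation or was never
  # segmented; voxels only in the leak blob are its collar, not the gap
  if (bridge) cand <- cand & (clean | !Xc)
  if (!any(cand)) return(none)
  # a gap voxel sits inside the wall, i.e. within the closing of the bright
  # wall itself (which virtually fills bridgeable holes); voxels at the gap
  # mouth, outside the wall envelope, are not wall passage
  cand <- cand & close_mask(bright, offsets = off)
  if (!any(cand)) return(none)
  lab <- label_components(cand, 26L)
  n26 <- sphere_offsets_26()
  # component-level: a gap borders normal (bright) wall ...
  ok <- seq_len(max(lab)) %in% unique(lab[lab > 0L &
                                            dilate_mask(bright, offsets = n26)])
  # ... and bridges the wall: it touches the retained segmentation on one
  # side and the leak blob on the other
  if (bridge) {
    near_clean <- dilate_mask(clean, offsets = n26)
    evidence <- leak
    if (!is.null(sealed)) evidence <- evidence | sealed
    # envelope trimming keeps mid-wall voxels, so leak evidence may sit up
    # to a closing radius away
    near_evidence <- dilate_mask(evidence, offsets = off)
    ok <- ok & seq_along(ok) %in% unique(lab[lab > 0L & near_clean]) &
      seq_along(ok) %in% unique(lab[lab > 0L & near_evidence])
  }
  keep <- array(lab > 0L & ok[pmax(lab, 1L)], dim = dim(lab))
  if (!any(keep)) return(none)
  idx <- which(keep)
  matrix(as.integer(arrayInd(idx, dim(keep))), ncol = 3L)
}

sphere_offsets_26 <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  matrix(as.integer(g[rowSums(abs(g)) > 0L, ]), ncol = 3L)
}

#' Seal gap voxels by raising their CT value
#'
#' Writes `fill_hu` into exactly the given voxels; every other voxel of the
#' image is left bit-identical. Raising the CT value turns a low-brightness
#' wall gap back into wall that fails the acceptance window.
#'
#' @param T 3D integer array (cropped CT image).
#' @param gap_voxels Integer n x 3 coordinate matrix.
#' @param fill_hu CT value to write; must exceed the current value at every
#'   gap voxel (sealing only ever brightens).
#' @return The modified array.
#' @export
seal <- function(T, gap_voxels, fill_hu) {
  if (nrow(gap_voxels) == 0L) return(T)
  cur <- T[gap_voxels]
  bad <- cur >= fill_hu
  if (any(bad)) {
    off <- gap_voxels[bad, , drop = FALSE]
    stop("seal: fill_hu (", fill_hu, ") not above current value at ",
         sum(bad), " voxel(s), e.g. (",
         paste(off[1, ], collapse = ","), ") = ", cur[bad][1])
  }
  T[gap_voxels] <- as.integer(fill_hu)
  T
}

#' Seal-and-resegment loop for one constraint region
#'
#' Repeatedly localizes wall gaps in the combined segmentation, seals them
#' with `Seed + Threshold0 + fill_margin` HU (outside every window the loop
#' can reach), raises the working threshold by 1 and re-runs the in-region
#' segmentation. The loop continues while gaps keep being found or the
#' latest segmentation still shows leak evidence (its decay machinery
#' fired) — for gaps too wide to seal, threshold adaptation is the only
#' remaining control — and exits with `capped = TRUE` once the working
#' threshold exceeds `Threshold0` by more than the 200 HU wall/lumen
#' contrast. The returned segmentation is the last non-leaking result.
#'
#' @param ctx A `region_context` (its image `T` is sealed cumulatively).
#' @param qs Matching `quasi_sphere`.
#' @param result The `region_result` of the initial segmentation of this
#'   region.
#' @param config An [airway_config()].
#' @return List with `ctx`, the final `result`, and `report`: a
#'   `gap_report` with `gap_voxels` (crop coordinates), `fill_hu`, `rounds`,
#'   `threshold_final` and `capped`.
#' @export
sealing_loop <- function(ctx, qs, result, config = airway_config()) {
  cap <- airway_constants()$sealing_cap
  fill_hu <- ctx$Seed + ctx$Threshold0 + as.integer(config$sealing$fill_margin)
  wall_level <- ctx$Seed + ctx$Threshold0 + as.integer(config$sealing$wall_contrast)
  gap_all <- matrix(integer(0), ncol = 3L)
  sealed_mask <- array(FALSE, dim = dim(ctx$P_area0))
  best <- result
  current <- result
  rounds <- 0L
  capped <- FALSE
  working <- ctx$Threshold0
  repeat {
    rounds <- rounds + 1L
    # the combined mask holds the leaky segmentation (if any attempt
    # leaked), the retained result, and the previously segmented territory
    clean <- best$X | current$X | ctx$forbidden | ctx$P_area0
    leakm <- if (!is.null(current$X_leak)) current$X_leak & !clean
             else array(FALSE, dim = dim(clean))
    Xc <- clean | leakm
    gv <- locate_gaps(Xc, config$sealing$close_radius, ctx$T, wall_level,
                      clean = clean, leak = leakm, sealed = sealed_mask)
    # sealing only brightens: voxels already at/above the fill level are
    # wall-like and need no seal
    if (nrow(gv)) gv <- gv[ctx$T[gv] < fill_hu, , drop = FALSE]
    leak_evidence <- current$leak_events > 0L || current$leak_detected
    if (nrow(gv) == 0L && !leak_evidence) break
    working <- working + 1L
    if (working - ctx$Threshold0 > cap) { capped <- TRUE; break }
    if (nrow(gv)) {
      ctx$T <- seal(ctx$T, gv, fill_hu)
      gap_all <- unique(rbind(gap_all, gv))
      sealed_mask[gv] <- TRUE
      qs <- build_quasi_sphere(ctx)  # refresh the restricted image
    }
    ctx$Threshold <- working
    current <- segment_region(ctx, qs, config)
    if (!current$leak_detected) best <- current
  }
  # sealed voxels are wall, never lumen, in the final result
  if (nrow(gap_all)) best$X[gap_all] <- FALSE
  structure_report <- structure(
    list(gap_voxels = gap_all, fill_hu = fill_hu, rounds = rounds,
         threshold_final = working, capped = capped),
    class = "gap_report")
  list(ctx = ctx, result = best, report = structure_report)
}
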