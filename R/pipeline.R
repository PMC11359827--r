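#' Segment the airway tree from a single trachea seed
#'
#' Whole-tree driver: the user seed becomes a single-voxel bootstrap
#' surface; surfaces are processed LIFO from a stack, each through region
#' initialization ([init_region()]), quasi-sphere construction, radius
#' adaptation ([adapt_radius()]) and, when enabled, the gap-sealing loop
#' ([sealing_loop()]); the accepted voxels merge into the global mask and
#' the next-stage surfaces are pushed. Segmentation ends when no surfaces
#' remain (or at the `run$max_regions` safeguard, with a warning).
#'
#' @param volume A [ct_volume()].
#' @param seed Integer (x, y, z) voxel inside the trachea (1-based). A seed
#'   at or above -775 HU (definitely non-airway) triggers a warning.
#' @param config An [airway_config()].
#' @return Logical mask of the segmented tree, with attributes:
#'   `regions` — a data frame logging K, radius, Seed, Threshold, iterations,
#'   leak/seal events per region; `explored` — the union of all constraint
#'   regions (leakage, if any, is contained in it); `sealed` — all voxels
#'   sealed as wall gaps.
#' @export
segment_airway_tree <- function(volume, seed, config = airway_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  shape <- dim(volume$data)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > shape))
    stop("segment_airway_tree: seed outside the volume")
  seed_hu <- volume$data[seed[1], seed[2], seed[3]]
  if (seed_hu >= -775L)
    warning("segment_airway_tree: seed HU (", seed_hu,
            ") is in the definitely-non-airway band (>= -775)")
  global <- array(FALSE, dim = shape)
  explored <- array(FALSE, dim = shape)
  sealed <- array(FALSE, dim = shape)
  boot <- new_seed_surface(matrix(seed, ncol = 3L), seed_hu, shape)
  stack <- list(boot)
  logs <- list()
  K <- 0L
  while (length(stack) > 0L) {
    if (K >= config$run$max_regions) {
      warning("segment_airway_tree: max_regions (", config$run$max_regions,
              ") reached; segmentation truncated")
      break
    }
    surf <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    K <- K + 1L
    surf$K <- K
    ctx <- init_region(surf, volume, global, config)
    qs <- build_quasi_sphere(ctx)
    ad <- adapt_radius(ctx, qs, config)
    ctx <- ad$ctx; qs <- ad$qs; res <- ad$result
    seal_rounds <- 0L; capped <- FALSE; sealed_n <- 0L
    if (isTRUE(config$sealing$enabled)) {
      sl <- sealing_loop(ctx, qs, res, config)
      ctx <- sl$ctx; res <- sl$result
      seal_rounds <- sl$report$rounds
      capped <- sl$report$capped
      sealed_n <- nrow(sl$report$gap_voxels)
      if (sealed_n > 0L) {
        gp <- sweep(sl$report$gap_voxels, 2L, ctx$box$lo - 1L, `+`)
        sealed[gp] <- TRUE
      }
    }
    box <- ctx$box
    sub <- crop(global, box) | res$X
    global <- uncrop(global, sub, box)
    explored <- uncrop(explored, crop(explored, box) | qs$region, box)
    for (s in rev(res$next_surfaces)) stack[[length(stack) + 1L]] <- s
    logs[[K]] <- data.frame(
      K = K, R = ctx$R, seed_hu = ctx$Seed, threshold0 = ctx$Threshold0,
      threshold_used = res$threshold_used, iterations = res$iterations,
      iteration_cap = 2L * ctx$R + as.integer(config$wavefront$iteration_slack),
      voxels = sum(res$X), bifurcations = res$bifurcation_count,
      leak_detected = res$leak_detected, leak_events = res$leak_events,
      seal_rounds = seal_rounds, sealed_voxels = sealed_n, capped = capped)
    log_msg(config, sprintf(
      "region K=%d R=%d Seed=%d Thr=%d iters=%d voxels=%d bif=%d leaks=%d seals=%d%s",
      K, ctx$R, ctx$Seed, res$threshold_used, res$iterations, sum(res$X),
      res$bifurcation_count, res$leak_events, seal_rounds,
      if (capped) " CAPPED" else ""))
  }
  structure(global, regions = do.call(rbind, logs), explored = explored,
            sealed = sealed)
}

#' EXACT09-style evaluation against phantom ground truth
#'
#' Computes the seven challenge parameters from a predicted mask and a
#' phantom bundle: branch count and percentage of branches whose
#' ground-truth centerline overlaps the prediction for more than the
#' 1 mm-equivalent length; detected tree length (overlapping centerline
#' voxels of detected branches) and its percentage of the total; leakage
#' volume (predicted voxels outside the ground-truth lumen dilated by one
#' voxel), leakage count (26-connected leakage components adjacent to the
#' correct segmentation) and false positive rate (leakage volume over
#' correctly detected volume).
#'
#' @param pred Logical predicted mask.
#' @param truth A `phantom_bundle` from [generate_phantom()].
#' @return List of class `eval_metrics` with fields `branch_count`,
#'   `branch_detected_pct`, `tree_length`, `tree_length_detected_pct`,
#'   `leakage_count`, `leakage_volume`, `false_positive_rate_pct`
#'   (voxel units; mm via the volume spacing where applicable).
#' @export
evaluate <- function(pred, truth) {
  stopifnot(inherits(truth, "phantom_bundle"))
  pred <- as_mask(pred)
  if (!identical(dim(pred), dim(truth$lumen)))
    stop("evaluate: prediction shape does not match the phantom")
  spacing <- truth$volume$spacing
  min_len <- ceiling(1 / mean(spacing))  # the "> 1 mm" detection rule
  overlaps <- vapply(truth$branches,
                     function(b) sum(pred[b$centerline]), 0L)
  total_cl <- vapply(truth$branches, function(b) length(b$centerline), 0L)
  detected <- overlaps > min_len
  tol <- dilate_mask(truth$lumen, 1L)
  leak <- pred & !tol
  correct <- pred & tol
  leak_n <- 0L
  if (any(leak)) {
    lab <- label_components(leak, 26L)
    near_correct <- dilate_mask(correct, 1L, offsets = sphere_offsets_26())
    leak_n <- length(unique(lab[lab > 0L & near_correct]))
  }
  correct_vol <- sum(correct)
  structure(list(
    branch_count = sum(detected),
    branch_detected_pct = 100 * sum(detected) / length(detected),
    tree_length = sum(overlaps[detected]),
    tree_length_detected_pct = 100 * sum(overlaps[detected]) / sum(total_cl),
    leakage_count = leak_n,
    leakage_volume = sum(leak),
    false_positive_rate_pct =
      if (correct_vol > 0L) 100 * sum(leak) / correct_vol else 0
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Branch Count:            %d\n",
    "Branch Detected:         %.1f %%\n",
    "Tree Length:             %d voxels\n",
    "Tree Length Detected:    %.1f %%\n",
    "Leakage Count:           %d\n",
    "Leakage Volume:          %d voxels\n",
    "False Positive Rate:     %.2f %%\n"),
    x$branch_count, x$branch_detected_pct, x$tree_length,
    x$tree_length_detected_pct, x$leakage_count, x$leakage_volume,
    x$false_positive_rate_pct))
  invisible(x)
}
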