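#' Segmentation configuration
#'
#' Builds the nested configuration list consumed by [segment_airway_tree()]
#' and the lower-level region operations. Fields follow the algorithm's
#' module structure:
#'
#' * `region`: seed-surface initialization. `enhance` toggles tracheal wall
#'   enhancement; `enhance_strength` (HU) is added to the thinned wall sheet;
#'   `enhance_min_gradient` (HU) is the smallest axis difference treated as a
#'   tissue interface; `initial_threshold_override` (HU) is the window width
#'   of the single-voxel bootstrap round, for which Eq.-style min/max
#'   statistics are undefined; `threshold_override` (HU or `NULL`) fixes the
#'   window width of *every* region, emulating the wide acceptance windows
#'   that partial volume produces in clinical CT.
#' * `wavefront`: `growth_factor` (per-iteration accepted-voxel cap as a
#'   multiple of the seed-surface area), `area_factor` (next-surface area cap,
#'   same scale), `radius_step` (voxels removed per radius adaptation),
#'   `iteration_slack` (iteration cap is `2R + iteration_slack`),
#'   `leak_rules` / `fill_holes` toggles (both on; turning them off yields the
#'   plain constrained threshold growth used for oracle checks).
#' * `sealing`: `enabled`, `close_radius` (voxels, gap-localization closing),
#'   `fill_margin` (sealed voxels get `Seed + Threshold0 + fill_margin` HU so
#'   they fail every window the loop can reach), `wall_contrast` (HU above
#'   `Seed + Threshold0` considered definite wall when filtering gap
#'   candidates). The 200 HU threshold cap and radius floor 8 are fixed
#'   constants, see [airway_constants()].
#' * `run`: `max_regions` safety bound and `verbose` logging.
#'
#' @param preset `"default"` for the standard settings; `"leak_stress"` for
#'   the wide-window configuration used to study leakage and gap sealing on
#'   sharp-edged phantoms (fixes `threshold_override = 170`, disables wall
#'   enhancement).
#' @param ... Named nested overrides, e.g. `sealing = list(enabled = FALSE)`.
#' @return Nested configuration list of class `airway_config`.
#' @export
airway_config <- function(preset = c("default", "leak_stress"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    region = list(
      enhance = TRUE,
      enhance_strength = 300L,
      enhance_min_gradient = 100L,
      initial_threshold_override = 100L,
      threshold_override = NULL
    ),
    wavefront = list(
      growth_factor = 2.5,
      area_factor = 1.5,
      radius_step = 2L,
      iteration_slack = 4L,
      leak_rules = TRUE,
      fill_holes = TRUE
    ),
    sealing = list(
      enabled = TRUE,
      close_radius = 2L,
      fill_margin = 201L,
      wall_contrast = 200L
    ),
    run = list(
      max_regions = 10000L,
      verbose = FALSE
    )
  )
  if (preset == "leak_stress") {
    cfg$region$threshold_override <- 170L
    cfg$region$enhance <- FALSE
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("airway_config: unknown section(s): ",
                          paste(bad, collapse = ", "))
    for (sec in names(overrides)) {
      unknown <- setdiff(names(overrides[[sec]]), names(cfg[[sec]]))
      if (length(unknown)) stop("airway_config: unknown key(s) in `", sec,
                                "`: ", paste(unknown, collapse = ", "))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], overrides[[sec]])
    }
  }
  structure(cfg, class = "airway_config")
}

#' Read a configuration from a YAML file
#'
#' Reads nested overrides from YAML and applies them on top of a preset via
#' [airway_config()].
#'
#' @param path YAML file. A top-level `preset:` key selects the base preset.
#' @return An `airway_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "default"
  y$preset <- NULL
  do.call(airway_config, c(list(preset = preset), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(config, ...) {
  if (isTRUE(config$run$verbose)) message(...)
  invisible(NULL)
}
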