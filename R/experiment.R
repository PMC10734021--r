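#' Experiment configuration
#'
#' Bundles everything needed to reproduce one phantom experiment end to end:
#' phantom geometry, flow, acquisition, pipeline parameters, analysis windows
#' and the seed. Every output written by [run_experiment()] records the seed
#' and parameters in its manifest.
#'
#' @param name Experiment name (used in file names and the manifest).
#' @param phantom List describing the geometry: `type` ("bifurcation" or
#'   "trifurcation") plus the arguments of [build_bifurcation()] /
#'   [build_trifurcation()].
#' @param flow List with `inlet_flow_rate` (mL/min) and `split_rule`.
#' @param acquisition Named list of [acquisition_config()] arguments.
#' @param pipeline Named list of [ulm_localize()] arguments, plus
#'   `min_track_frames` (default 10) and `max_link_distance` (`NULL`:
#'   derived from the fastest channel via [link_gate()]).
#' @param analysis List with `n_frames_saturation` (default min(3000,
#'   n_frames)), `n_frames_velocity` (default all frames) and `roi_segments`,
#'   a named character vector of segments to place saturation ROIs on
#'   (default main and branch daughters where present).
#' @param seed Integer seed for the simulation.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(name = "experiment",
                              phantom = list(type = "bifurcation",
                                             main_width_um = 300,
                                             branch_width_um = 300,
                                             angle_deg = 45),
                              flow = list(inlet_flow_rate = 0.02,
                                          split_rule = "symmetric"),
                              acquisition = list(),
                              pipeline = list(),
                              analysis = list(),
                              seed = 1L) {
  cfg <- structure(list(name = name, phantom = phantom, flow = flow,
                        acquisition = acquisition, pipeline = pipeline,
                        analysis = analysis, seed = as.integer(seed)),
                   class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid experiment config: ", field, " ", why, call. = FALSE)
  }
  if (!is.list(cfg$phantom) || is.null(cfg$phantom$type)) {
    fail("phantom$type", "is missing")
  }
  if (!cfg$phantom$type %in% c("bifurcation", "trifurcation")) {
    fail("phantom$type", "must be 'bifurcation' or 'trifurcation'")
  }
  if (is.null(cfg$flow$inlet_flow_rate) ||
      !is.finite(cfg$flow$inlet_flow_rate) || cfg$flow$inlet_flow_rate < 0) {
    fail("flow$inlet_flow_rate", "must be a non-negative number")
  }
  if (!is.null(cfg$flow$split_rule) &&
      !cfg$flow$split_rule %in% c("symmetric", "resistance")) {
    fail("flow$split_rule", "must be 'symmetric' or 'resistance'")
  }
  bad_acq <- setdiff(names(cfg$acquisition),
                     names(formals(acquisition_config)))
  if (length(bad_acq) > 0) {
    fail(paste0("acquisition$", bad_acq[1]), "is not an acquisition field")
  }
  known_pipe <- c("upsample_factor", "n_remove", "hp_order", "hp_cutoff",
                  "min_separation", "k", "window", "min_track_frames",
                  "max_link_distance")
  bad_pipe <- setdiff(names(cfg$pipeline), known_pipe)
  if (length(bad_pipe) > 0) {
    fail(paste0("pipeline$", bad_pipe[1]), "is not a pipeline field")
  }
  invisible(cfg)
}

build_phantom <- function(phantom) {
  if (phantom$type == "bifurcation") {
    args <- phantom[names(phantom) %in% names(formals(build_bifurcation))]
    do.call(build_bifurcation, args)
  } else {
    args <- phantom[names(phantom) %in% names(formals(build_trifurcation))]
    do.call(build_trifurcation, args)
  }
}

default_roi_segments <- function(network) {
  ids <- network$segments$id
  if (all(c("main_out", "branch") %in% ids)) {
    c(main = "main_out", branch = "branch")
  } else if ("branch_mid" %in% ids) {
    c(main = "inlet", branch = "branch_mid")
  } else if ("mid" %in% ids) {
    c(main = "inlet", branch = "mid")
  } else {
    stats::setNames(ids[1], ids[1])
  }
}

#' Named experiment recipes
#'
#' Pre-configured experiments matching the study designs the simulator
#' emulates: 300/300 um bifurcations at 25/45/55 degrees, width contrasts
#' (300 -> 100 um and 500 -> 200 um, resistance split), trifurcations at 30
#' degrees (open and converging), and a B-mode run with background
#' scatterers. `scale = "tiny"` uses a 64 x 64 grid and 300 frames (seconds
#' to run; the test scale); `scale = "full"` uses a 128 x 128 grid with
#' 9000-frame velocity runs and 3000-frame saturation analysis.
#'
#' @param name Recipe name; see Details. `ulm_recipes()` lists all names.
#' @param scale `"tiny"` or `"full"`.
#' @param seed Integer seed.
#' @return An [experiment_config()].
#' @export
ulm_recipe <- function(name, scale = c("tiny", "full"), seed = 1L) {
  scale <- match.arg(scale)
  recipes <- list(
    "bifurcation-25" = list(phantom = list(type = "bifurcation",
      main_width_um = 300, branch_width_um = 300, angle_deg = 25)),
    "bifurcation-45" = list(phantom = list(type = "bifurcation",
      main_width_um = 300, branch_width_um = 300, angle_deg = 45)),
    "bifurcation-55" = list(phantom = list(type = "bifurcation",
      main_width_um = 300, branch_width_um = 300, angle_deg = 55)),
    "width-300-100" = list(phantom = list(type = "bifurcation",
      main_width_um = 300, branch_width_um = 100, angle_deg = 45),
      flow = list(inlet_flow_rate = 0.02, split_rule = "resistance")),
    "width-500-200" = list(phantom = list(type = "bifurcation",
      main_width_um = 500, branch_width_um = 200, angle_deg = 45),
      flow = list(inlet_flow_rate = 0.02, split_rule = "resistance")),
    "trifurcation" = list(phantom = list(type = "trifurcation",
      width_um = 300, angle_deg = 30, converging = FALSE)),
    "trifurcation-converging" = list(phantom = list(type = "trifurcation",
      width_um = 300, angle_deg = 30, converging = TRUE)),
    "bmode-scatterers" = list(phantom = list(type = "bifurcation",
      main_width_um = 300, branch_width_um = 300, angle_deg = 45),
      acquisition = list(mode = "BMODE", scatterer_density = 0.005))
  )
  if (!name %in% names(recipes)) {
    stop("unknown recipe '", name, "'; available: ",
         paste(names(recipes), collapse = ", "), call. = FALSE)
  }
  rc <- recipes[[name]]
  if (scale == "tiny") {
    acq <- list(rows = 64, cols = 64, n_frames = 300, block_size = 750)
    lengths <- if (rc$phantom$type == "bifurcation") c(0.6, 0.8) else
      c(0.45, 0.45, 0.3)
  } else {
    acq <- list(rows = 128, cols = 128, n_frames = 9000)
    lengths <- if (rc$phantom$type == "bifurcation") c(1.5, 1.5) else
      c(1, 1, 0.8)
  }
  rc$phantom$lengths_mm <- lengths
  acq <- utils::modifyList(acq, rc$acquisition %||% list())
  experiment_config(
    name = name,
    phantom = rc$phantom,
    flow = rc$flow %||% list(inlet_flow_rate = 0.02,
                             split_rule = "symmetric"),
    acquisition = acq,
    analysis = if (scale == "full") list(n_frames_saturation = 3000,
                                          n_frames_velocity = 9000) else
      list(),
    seed = seed
  )
}

#' @rdname ulm_recipe
#' @export
ulm_recipes <- function() {
  c("bifurcation-25", "bifurcation-45", "bifurcation-55", "width-300-100",
    "width-500-200", "trifurcation", "trifurcation-converging",
    "bmode-scatterers")
}

#' Run a full simulate -> process -> analyze experiment
#'
#' Simulates the configured phantom acquisition, runs the ULM chain, links
#' and filters tracks, accumulates density and velocity maps, computes
#' saturation curves and exponential fits for the configured ROIs, and (if
#' `out_dir` is given) writes the frame stack, localization and track
#' tables, maps, saturation curves, a summary table and a manifest recording
#' versions, seed and parameters.
#'
#' @param config An [experiment_config()] (e.g. from [ulm_recipe()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list: `network`, `sim`, `localizations`, `tracks`,
#'   `steps`, `maps`, `curves`, `fits`, `summary` (a tibble), `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  validate_experiment_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  network <- build_phantom(config$phantom)
  fc <- flow_config(config$flow$inlet_flow_rate,
                    config$flow$split_rule %||% "symmetric")
  acq <- do.call(acquisition_config,
                 utils::modifyList(config$acquisition,
                                   list(rng_seed = config$seed)))
  network <- flow_split(network, fc)
  sim <- generate_sequence(network, fc, acq)

  pipe <- config$pipeline
  loc <- ulm_localize(
    sim$stack,
    upsample_factor = pipe$upsample_factor %||% 2L,
    n_remove = pipe$n_remove %||% 2L,
    hp_order = pipe$hp_order %||% 2L,
    hp_cutoff = pipe$hp_cutoff %||% 0.01,
    min_separation = pipe$min_separation %||% 4,
    k = pipe$k %||% 4,
    window = pipe$window %||% 5,
    block_size = acq$block_size
  )
  sv <- segment_velocities(network)
  gate <- pipe$max_link_distance %||%
    link_gate(1.5 * max(sv$mean_v_mm_s), acq$frame_rate,
              attr(loc, "pixel_size_mm"))
  tracks <- filter_tracks(link_tracks(loc, gate),
                          pipe$min_track_frames %||% 10)

  factor <- pipe$upsample_factor %||% 2L
  n_vel <- config$analysis$n_frames_velocity %||% acq$n_frames
  steps <- compute_velocities(tracks[tracks$frame <= n_vel, ], acq$frame_rate)
  maps <- accumulate_maps(tracks[tracks$frame <= n_vel, ],
                          c(acq$rows, acq$cols) * factor, acq$frame_rate)

  pitch_u <- attr(loc, "pixel_size_mm")
  origin_u <- attr(loc, "origin")
  n_sat <- config$analysis$n_frames_saturation %||% min(3000, acq$n_frames)
  roi_segments <- config$analysis$roi_segments %||%
    default_roi_segments(network)
  curves <- list(); fits <- list()
  for (nm in names(roi_segments)) {
    roi <- roi_after_junction(network, roi_segments[[nm]], origin_u, pitch_u)
    # mask of the one vessel passing through this ROI
    mask_u <- channel_mask(network, acq$rows * factor, acq$cols * factor,
                           origin_u, pitch_u,
                           segments = roi_segments[[nm]])
    curves[[nm]] <- saturation_curve(loc, roi, mask_u, acq$frame_rate,
                                     n_frames = n_sat)
    fits[[nm]] <- tryCatch(
      withCallingHandlers(fit_exponential(curves[[nm]]),
                          warning = function(w) {
                            message("[", config$name, ":", nm, "] ",
                                    conditionMessage(w))
                            invokeRestart("muffleWarning")
                          }),
      error = function(e) NULL)
  }

  smry <- purrr::map_dfr(names(roi_segments), function(nm) {
    tibble::tibble(
      experiment = config$name, channel = nm,
      segment = unname(roi_segments[[nm]]),
      tau_s = if (is.null(fits[[nm]])) NA_real_ else fits[[nm]]$tau,
      r2 = if (is.null(fits[[nm]])) NA_real_ else fits[[nm]]$r_squared,
      n_vessel_px = attr(curves[[nm]], "n_vessel_px"),
      n_localizations = nrow(loc),
      n_tracks = dplyr::n_distinct(tracks$track_id),
      mean_track_speed_mm_s = if (nrow(steps) > 0)
        mean(track_summary(steps)$mean_speed_mm_s) else NA_real_,
      seed = config$seed
    )
  })

  res <- list(network = network, sim = sim, localizations = loc,
              tracks = tracks, steps = steps, maps = maps, curves = curves,
              fits = fits, summary = smry, config = config)
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  invisible(res)
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  write_frame_stack(res$sim$stack, p("frames.tif"))
  write_ground_truth(res$sim$truth, p("ground_truth.csv"))
  write_network(res$network, p("network.yaml"))
  write_localizations(res$localizations, p("localizations.csv"))
  write_tracks(res$tracks, p("tracks.csv"),
               attr(res$localizations, "frame_rate"))
  write_maps(res$maps, p("map"))
  for (nm in names(res$curves)) {
    write_saturation(res$curves[[nm]], p("saturation_", nm, ".csv"),
                     res$fits[[nm]])
  }
  readr::write_csv(res$summary, p("summary.csv"))
  yaml::write_yaml(list(
    package = "ulmphantom",
    package_version = as.character(utils::packageVersion("ulmphantom")),
    r_version = as.character(getRversion()),
    seed = res$config$seed,
    config = rapply(unclass(res$config), identity, how = "list")
  ), p("manifest.yaml"))
  invisible(out_dir)
}

#' Build fixture configurations (and optionally their data)
#'
#' `tiny` fixtures use a 64 x 64 grid and 300 frames and build in seconds;
#' they are what the test suite exercises. `full` fixtures reproduce the
#' full-scale design: 9000-frame velocity-map runs with 3000-frame
#' saturation analysis on a 128 x 128 grid.
#'
#' @param scale `"tiny"` or `"full"`.
#' @param out_dir If given, simulates each fixture and writes its frame
#'   stack and ground truth there (simulation only; no analysis).
#' @param recipes Recipe names to include.
#' @param seed Integer seed.
#' @return Named list of [experiment_config()]s, invisibly when writing.
#' @export
make_fixtures <- function(scale = c("tiny", "full"), out_dir = NULL,
                          recipes = c("bifurcation-45", "width-300-100"),
                          seed = 1L) {
  scale <- match.arg(scale)
  cfgs <- lapply(stats::setNames(recipes, recipes), ulm_recipe,
                 scale = scale, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(cfgs)) {
      cfg <- cfgs[[nm]]
      fc <- flow_config(cfg$flow$inlet_flow_rate,
                        cfg$flow$split_rule %||% "symmetric")
      network <- flow_split(build_phantom(cfg$phantom), fc)
      acq <- do.call(acquisition_config,
                     utils::modifyList(cfg$acquisition,
                                       list(rng_seed = cfg$seed)))
      sim <- generate_sequence(network, fc, acq)
      write_frame_stack(sim$stack, file.path(out_dir, paste0(nm, ".tif")))
      write_ground_truth(sim$truth,
                         file.path(out_dir, paste0(nm, "_truth.csv")))
    }
  }
  invisible(cfgs)
}
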