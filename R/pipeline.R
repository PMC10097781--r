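#' Run configuration for single cases and helix-map sweeps
#'
#' Bundles everything one simulation campaign needs: geometry (a spec or a
#' prebuilt mesh), the helix grid, the driver mode, constitutive/circulation
#' parameters, the volume waveform, the metric list and the output
#' directory. Validation ensures the driver has the inputs it needs
#' (volume-constrained needs a waveform; coupled needs circulation
#' parameters).
#'
#' @param geometry an [lv_geometry_spec()] or an `lv_mesh`.
#' @param tau_bar,tau_diff helix grid vectors, degrees (defaults: the swept
#'   range -90..180 at 15 degree spacing).
#' @param driver "volume_constrained" or "coupled".
#' @param passive,active,circulation parameter objects.
#' @param waveform a `volume_waveform` or [waveform_spec()].
#' @param solver [solver_config()].
#' @param mesh_args list passed to [generate_idealized_lv()].
#' @param metrics metric names to report.
#' @param output_dir output directory (NULL: nothing written).
#' @param resume skip already-computed grid points when sweeping.
#' @export
run_config <- function(geometry = lv_geometry_spec("symmetric"),
                       tau_bar = seq(-90, 180, by = 15),
                       tau_diff = seq(-90, 180, by = 15),
                       driver = c("volume_constrained", "coupled"),
                       passive = passive_params(), active = active_params(),
                       circulation = NULL, waveform = waveform_spec(),
                       solver = solver_config(), mesh_args = list(),
                       metrics = c("stroke_work", "peak_myofiber_stress",
                                   "deform_burden", "strain_variance"),
                       output_dir = NULL, resume = FALSE) {
  driver <- match.arg(driver)
  if (inherits(waveform, "waveform_spec")) waveform <- generate_volume_waveform(waveform)
  if (driver == "volume_constrained" && is.null(waveform))
    stop_lv("volume_constrained driver requires a waveform")
  if (driver == "coupled" && is.null(circulation))
    stop_lv("coupled driver requires circulation parameters")
  structure(list(geometry = geometry, tau_bar = tau_bar, tau_diff = tau_diff,
                 driver = driver, passive = passive, active = active,
                 circulation = circulation, waveform = waveform,
                 solver = solver, mesh_args = mesh_args, metrics = metrics,
                 output_dir = output_dir, resume = resume),
            class = "run_config")
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical (recursively name-sorted) JSON serialization, so the
#' hash is invariant to key ordering.
#' @param cfg any serializable R object.
#' @export
config_hash <- function(cfg) {
  sort_rec <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, sort_rec)
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
    }
    x
  }
  plain <- rapply(cfg, function(v) v, how = "replace")
  js <- jsonlite::toJSON(sort_rec(plain), auto_unbox = TRUE, digits = 12,
                         force = TRUE, null = "null")
  tf <- tempfile()
  writeLines(js, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

# build mesh + transmural coordinate + frames once per geometry (shared
# across all helix grid points of a sweep)
build_run_context <- function(cfg) {
  mesh <- if (inherits(cfg$geometry, "lv_mesh")) cfg$geometry
          else do.call(generate_idealized_lv, c(list(cfg$geometry), cfg$mesh_args))
  e <- solve_transmural_coordinate(mesh)
  frames <- build_local_frames(mesh, e, cfg$solver$apex_cap_frac)
  list(mesh = mesh, e = e, frames = frames)
}

point_tag <- function(point) {
  sprintf("tb%+05.0f_td%+05.0f", point$tau_bar * 10, point$tau_diff * 10)
}

#' Run one helix-configuration case
#'
#' Builds (or reuses) the mesh and frames, assigns the helix fiber field,
#' runs the configured cycle driver, computes the biomechanics metrics, and
#' (when an output directory is set) writes the PV loop, a per-step state
#' summary, and the metric row as CSV.
#'
#' @param cfg a [run_config()].
#' @param point a [helix_config()].
#' @param context optional shared context from a sweep.
#' @return list with `metrics`, `cycle` and `paths`.
#' @export
run_case <- function(cfg, point, context = NULL) {
  context <- context %||% build_run_context(cfg)
  fib <- assign_helix_field(context$mesh, context$frames, point)
  cycle <- if (cfg$driver == "volume_constrained") {
    run_volume_constrained_cycle(context$mesh, fib, cfg$passive, cfg$active,
                                 cfg$waveform, cfg$solver)
  } else {
    run_coupled_cycle(context$mesh, fib, cfg$passive, cfg$active,
                      cfg$circulation, cfg$solver)
  }
  met <- compute_biomech_metrics(cycle)
  paths <- list()
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- point_tag(point)
    paths$pv <- file.path(cfg$output_dir, paste0("pv_", tag, ".csv"))
    write.csv(cycle$pv, paths$pv, row.names = FALSE)
    paths$metrics <- file.path(cfg$output_dir, paste0("metrics_", tag, ".csv"))
    write.csv(cbind(data.frame(tau_bar = point$tau_bar,
                               tau_diff = point$tau_diff),
                    as.data.frame(met)), paths$metrics, row.names = FALSE)
  }
  list(metrics = met, cycle = cycle, paths = paths)
}

#' Sweep the helix grid of a run configuration
#'
#' Runs [run_case()] at every (tau_bar, tau_diff) node, masking failures,
#' optionally resuming from already-written metric files, and returns the
#' metric maps with located optima and a run manifest.
#'
#' @param cfg a [run_config()].
#' @param progress print progress.
#' @return list with `maps` (helix_map per metric), `optima`, `manifest`.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  context <- build_run_context(cfg)
  status <- matrix("pending", length(cfg$tau_bar), length(cfg$tau_diff))
  evaluate <- function(point) {
    i <- match(point$tau_bar, cfg$tau_bar)
    j <- match(point$tau_diff, cfg$tau_diff)
    if (cfg$resume && !is.null(cfg$output_dir)) {
      f <- file.path(cfg$output_dir, paste0("metrics_", point_tag(point), ".csv"))
      if (file.exists(f)) {
        status[i, j] <<- "done"
        return(as.list(read.csv(f))[cfg$metrics])
      }
    }
    r <- tryCatch(run_case(cfg, point, context), error = function(e) e)
    if (inherits(r, "error")) {
      status[i, j] <<- "failed"
      stop(r)
    }
    status[i, j] <<- "done"
    r$metrics[cfg$metrics]
  }
  maps <- sweep_helix_map(evaluate, cfg$tau_bar, cfg$tau_diff,
                          metrics = cfg$metrics, progress = progress)
  status[status == "failed"] <- "masked"
  directions <- c(stroke_work = "max", peak_myofiber_stress = "max",
                  deform_burden = "min", strain_variance = "min")
  optima <- lapply(names(maps), function(m) {
    dir <- directions[m]
    if (is.na(dir)) dir <- "max"
    tryCatch(find_optimal_point(maps[[m]], dir), error = function(e) NULL)
  })
  names(optima) <- names(maps)
  manifest <- list(config_hash = config_hash(list(
                     tau_bar = cfg$tau_bar, tau_diff = cfg$tau_diff,
                     driver = cfg$driver, metrics = cfg$metrics)),
                   status = status,
                   n_done = sum(status == "done"),
                   n_masked = sum(status == "masked"),
                   n_total = length(status),
                   version = as.character(utils::packageVersion("lvhelix")))
  if (!is.null(cfg$output_dir)) {
    for (m in names(maps))
      write_helix_map(maps[[m]],
                      path_csv = file.path(cfg$output_dir, paste0("map_", m, ".csv")),
                      path_json = file.path(cfg$output_dir, paste0("map_", m, ".json")),
                      optimum = optima[[m]])
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(maps = maps, optima = optima, manifest = manifest)
}
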