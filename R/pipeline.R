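# Batch pipeline: contour -> mesh -> deformation -> seasonal population
# evolution, driven by a single JSON-able configuration with one top-level
# seed, writing all artifacts plus a manifest sufficient to reproduce the
# run.

#' Assemble a pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()]. Each block may be
#' given partially; unset fields take the defaults below. The `outline` and
#' `mask` blocks accept either a generator recipe (fields of
#' [make_outline()] / [make_mask()]) or `list(file = path)` pointing to a
#' key-points JSON / PNG file.
#'
#' @param outline Outline source (default: the maple recipe).
#' @param mask Mask source (default: the dark-edge recipe).
#' @param meshing List with `n_boundary` (boundary samples, default 48),
#'   `iterations` (optimization passes, default 40) and `target_edge`
#'   (refinement target, default 0.2; zero or negative disables interior
#'   refinement).
#' @param deformation List with the [sim_config()] fields plus `force`
#'   (length-3 external force vector), `n_steps` (default 200),
#'   `snapshot_every` (default 50), `petiole` and `anchor_radius`.
#' @param seasons List with `spec` (either `list(n_states =)` for
#'   [make_default_spec()] or `list(file = path)`), `schedule` (list of
#'   epochs with `temperature`, `humidness`, `duration`; default four
#'   seasons) and `population` (default 500).
#' @param seed Top-level seed feeding every stochastic stage (default 1).
#' @param out_dir Output directory (default `"leafcycle_out"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outline = list(), mask = list(),
                            meshing = list(), deformation = list(),
                            seasons = list(), seed = 1L,
                            out_dir = "leafcycle_out") {
  merge_defaults <- function(given, defaults) {
    for (nm in names(defaults)) {
      if (is.null(given[[nm]])) given[[nm]] <- defaults[[nm]]
    }
    given
  }
  outline <- merge_defaults(as.list(outline), list(
    shape = "maple", a = 2, b = 1.6, n_keypoints = 24, lobes = 5,
    lobe_depth = 0.45, sharpness = 1
  ))
  mask <- merge_defaults(as.list(mask), list(
    pattern = "dark-edge", width = 64, height = 64, value = 128,
    dark = 16, bright = 200
  ))
  meshing <- merge_defaults(as.list(meshing), list(
    n_boundary = 48, iterations = 40, target_edge = 0.2
  ))
  deformation <- merge_defaults(as.list(deformation), list(
    dt = 0.005, tau_c = 0.1, stiffness = 50, damping = 0.1,
    force = c(0, 0, -1), n_constraint_passes = 20, n_steps = 200,
    snapshot_every = 50, petiole = NULL, anchor_radius = NULL
  ))
  seasons <- merge_defaults(as.list(seasons), list(
    spec = list(n_states = 4),
    schedule = list(
      list(temperature = 0.55, humidness = 0.70, duration = 10),
      list(temperature = 0.90, humidness = 0.55, duration = 10),
      list(temperature = 0.40, humidness = 0.35, duration = 10),
      list(temperature = 0.05, humidness = 0.45, duration = 10)
    ),
    population = 500
  ))
  structure(list(outline = outline, mask = mask, meshing = meshing,
                 deformation = deformation, seasons = seasons,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  do.call(pipeline_config, obj[intersect(names(obj),
                                         names(formals(pipeline_config)))])
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full leaf-lifecycle pipeline
#'
#' Chains the stages: build (or load) the outline, fit and sample the
#' boundary curve, triangulate and optimize the mesh, generate (or load) the
#' mask map, simulate the mask-controlled deformation, and evolve a leaf
#' population through the senescence schedule. Writes `mesh.obj`,
#' `mask.png`, numbered `snapshot_XXXX.obj` files, `population_history.csv`
#' and `manifest.json` (all parameters plus seed and package version; the
#' manifest alone reproduces the run). Identical configuration and seed give
#' identical outputs.
#'
#' @param config A [pipeline_config()] (or list accepted by it).
#' @param out_dir Optional override of the configured output directory.
#' @param quiet Suppress progress messages (default TRUE).
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage outline")
  kp <- pipeline_stage("outline", {
    ob <- config$outline
    if (!is.null(ob$file)) {
      read_key_points(ob$file)
    } else {
      make_outline(shape = ob$shape, a = ob$a, b = ob$b,
                   n_keypoints = ob$n_keypoints, lobes = ob$lobes,
                   lobe_depth = ob$lobe_depth, sharpness = ob$sharpness,
                   jitter = ob$jitter, seed = config$seed)
    }
  })

  say("stage meshing")
  mesh <- pipeline_stage("meshing", {
    curve <- fit_closed_bspline(kp)
    bpts <- sample_curve(curve, config$meshing$n_boundary)
    m <- triangulate(bpts)
    te <- config$meshing$target_edge
    if (!is.null(te) && (is.na(te) || te <= 0)) te <- NULL
    optimize_mesh(m, iterations = config$meshing$iterations,
                  target_edge = te)
  })
  write_mesh(mesh, file.path(out_dir, "mesh.obj"))

  say("stage mask")
  mask <- pipeline_stage("mask", {
    mb <- config$mask
    if (!is.null(mb$file)) {
      if (!file.exists(mb$file)) {
        stop(sprintf("mask input '%s' for the deformation stage is missing",
                     mb$file), call. = FALSE)
      }
      read_mask(mb$file)
    } else {
      make_mask(pattern = mb$pattern, boundary = kp, width = mb$width,
                height = mb$height, value = mb$value, dark = mb$dark,
                bright = mb$bright, edge_band = mb$edge_band,
                vein_halfwidth = mb$vein_halfwidth)
    }
  })
  write_mask(mask, file.path(out_dir, "mask.png"))

  say("stage deformation")
  deform <- pipeline_stage("deformation", {
    db <- config$deformation
    cfg <- sim_config(dt = db$dt, tau_c = db$tau_c, stiffness = db$stiffness,
                      damping = db$damping,
                      external_force = uniform_force(db$force),
                      n_constraint_passes = db$n_constraint_passes)
    simulate_deformation(mesh, mask, cfg, n_steps = db$n_steps,
                         snapshot_every = db$snapshot_every,
                         petiole = db$petiole,
                         anchor_radius = db$anchor_radius)
  })
  for (k in seq_along(deform$snapshots)) {
    snap <- deform$snapshots[[k]]
    write_mesh(mesh,
               file.path(out_dir,
                         sprintf("snapshot_%04d.obj", attr(snap, "step"))),
               positions = snap)
  }

  say("stage seasons")
  pop <- pipeline_stage("seasons", {
    sb <- config$seasons
    spec <- if (!is.null(sb$spec$file)) {
      read_senescence_spec(sb$spec$file)
    } else {
      make_default_spec(sb$spec$n_states, seed = config$seed)
    }
    schedule <- lapply(sb$schedule, function(ep) {
      list(env = leaf_env(ep$temperature, ep$humidness),
           duration = ep$duration)
    })
    evolve_population(leaf_population(sb$population), schedule, spec,
                      seed = config$seed)
  })
  write_history(pop, file.path(out_dir, "population_history.csv"))

  manifest <- list(
    package = "leafcycle",
    version = as.character(utils::packageVersion("leafcycle")),
    seed = config$seed,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("done: %s", out_dir)
  invisible(out_dir)
}
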