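# End-to-end orchestration: ingest -> inflate -> contours -> assemble ->
# mesh -> (optional) fem -> report. Every stage is a pure function of
# (inputs, config, seed); rerunning with an identical config reproduces
# identical contours, tracks and mesh manifests.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and houses the pipeline's fixed
#' constants (inflation weight 4/10, up to 40 CPD iterations, 85%
#' resolution reduction, 100 um slice distance, 1 mm^3 structure floor,
#' Poisson ratio 0.45 via the material table).
#'
#' @param stack a [stack_config()].
#' @param inflation an [inflation_config()].
#' @param match a [match_config()].
#' @param mesh a [mesh_config()].
#' @param materials a [derive_material_table()] result.
#' @param pressure intravascular pressure for the FEM stage, kPa.
#' @param min_track_length shortest track lifted to a point cloud
#'   (default 2: a tissue visible in a single slice cannot be traced).
#' @param seed global seed for stochastic components.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stack = stack_config(pixel_pitch = 12,
                                                 downsample_keep_fraction = 1),
                            inflation = inflation_config(),
                            match = match_config(),
                            mesh = mesh_config(),
                            materials = derive_material_table(36.44, 133.9),
                            pressure = 13.33,
                            min_track_length = 2L,
                            seed = 1L) {
  structure(list(
    stack = stack, inflation = inflation, match = match, mesh = mesh,
    materials = materials, pressure = pressure,
    min_track_length = as.integer(min_track_length),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline config\n")
  print(x$stack)
  cat(sprintf("  inflation t = %g; CPD <= %d iterations; mesh floor %g mm^3; p = %g kPa; seed %d\n",
              x$inflation$t, x$match$cpd_max_iterations,
              x$mesh$min_volume / 1e9, x$pressure, x$seed))
  invisible(x)
}

# internal: md5 of the serialized config, for the run manifest
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full reconstruction pipeline
#'
#' Executes ingest, virtual inflation, contour extraction, registration +
#' matching + point-cloud assembly, capping + meshing + cleanup, an
#' optional single-slice FEM comparison, and (for phantom inputs) the
#' ground-truth recovery report. Any stage error halts the run with the
#' stage name; completed artifacts are kept in the returned state.
#'
#' @param input a [phantom_spec()], a directory of PNG label images, or a
#'   list of [labeled_slice()] objects.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for stage artifacts (label images,
#'   contours JSONL, XYZ clouds, PLY meshes, VTK stress fields, manifest
#'   JSON). NULL keeps everything in memory.
#' @param run_fem logical: run the homogeneous-vs-heterogeneous FEM
#'   comparison on the middle slice (default FALSE).
#' @return list with the per-stage artifacts: `slices`, `inflated`,
#'   `contours_by_slice`, `tracks`, `transforms`, `clouds`, `meshes`
#'   (cleaned tissue meshes), `tissue_meshes_unfiltered`, `wall_meshes`,
#'   `fem`, `report`, `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         output_dir = NULL, run_fem = FALSE) {
  t0 <- Sys.time()
  manifest <- list(config_hash = .config_hash(config),
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("histowall3d")),
                   stages = list())
  stage_t <- function(name, prev) {
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), prev, units = "secs")))
    Sys.time()
  }
  out_path <- function(...) {
    p <- file.path(output_dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- ingest ---------------------------------------------------------------
  truth <- NULL
  slices <- run_stage("ingest", {
    if (inherits(input, "phantom_spec")) {
      gen <- generate_phantom_stack(input)
      truth <- gen$truth
      gen$slices
    } else if (is.character(input)) {
      read_label_stack(input, config$stack)
    } else {
      input
    }
  })
  if (config$stack$downsample_keep_fraction < 1) {
    slices <- lapply(slices, downsample_labels,
                     keep_fraction = config$stack$downsample_keep_fraction)
  }
  if (!is.null(output_dir)) {
    for (sl in slices) {
      write_label_slice(sl, out_path("ingest",
                                     sprintf("slice_%03d.png", sl$slice_index)))
    }
  }
  tprev <- stage_t("ingest", t0)

  # -- inflate --------------------------------------------------------------
  inflated <- run_stage("inflate", lapply(slices, function(sl) {
    wc <- wall_contours(sl)
    res <- inflate_slice(sl, wc$inner, wc$outer, config$inflation)
    res$slice
  }))
  if (!is.null(output_dir)) {
    for (sl in inflated) {
      write_label_slice(sl, out_path("inflate",
                                     sprintf("slice_%03d.png", sl$slice_index)))
    }
  }
  tprev <- stage_t("inflate", tprev)

  # -- contours -------------------------------------------------------------
  # The default-class (intact wall) component spanning the whole annulus is
  # the background fill between the wall meshes, not a tissue segment: wall
  # volume not covered by any tissue mesh receives default_class in the FE
  # model instead of being meshed (and its ring topology cannot be
  # represented by a single outer contour anyway).
  default_cl <- attr(config$materials, "default_class")
  contours_by_slice <- run_stage("contours", lapply(inflated, function(sl) {
    wc <- wall_contours(sl)
    cts <- extract_contours(sl)
    outer_area <- polygon_area(wc$outer$points)
    keep <- vapply(cts, function(ct) {
      !(ct$tissue_class == default_cl &&
          polygon_area(ct$points) > 0.8 * outer_area)
    }, logical(1))
    if (any(!keep)) {
      hw_log(sprintf(
        "slice %d: treating the whole-wall class-%d component as background fill",
        sl$slice_index, default_cl), "debug")
    }
    c(cts[keep], list(wc$inner, wc$outer))
  }))
  if (!is.null(output_dir)) {
    write_contours_jsonl(do.call(c, contours_by_slice),
                         out_path("contours", "contours.jsonl"))
  }
  tprev <- stage_t("contours", tprev)

  # -- assemble -------------------------------------------------------------
  asm <- run_stage("assemble",
                   build_tracks(contours_by_slice, config$match))
  tracks <- asm$tracks
  keep <- vapply(tracks, function(t) {
    length(t$contours) >= config$min_track_length
  }, logical(1))
  dropped <- sum(!keep)
  if (dropped > 0) {
    hw_log(sprintf(
      "assemble: dropping %d track(s) shorter than %d slices (not traceable)",
      dropped, config$min_track_length), "info")
  }
  tracks <- tracks[keep]
  clouds <- build_point_clouds(tracks, config$stack$slice_distance)
  if (!is.null(output_dir)) {
    for (i in seq_along(clouds)) {
      write_xyz(clouds[[i]], out_path("clouds",
                                      sprintf("segment_%03d_class%02d.xyz", i,
                                              clouds[[i]]$tissue_class)))
    }
  }
  tprev <- stage_t("assemble", tprev)

  # -- mesh -----------------------------------------------------------------
  meshed <- run_stage("mesh", {
    capped <- lapply(seq_along(clouds), function(i) {
      add_caps(clouds[[i]], tracks[[i]], config$stack$slice_distance)
    })
    lapply(seq_along(capped), function(i) {
      cfg <- config$mesh
      role <- "tissue"
      if (clouds[[i]]$tissue_class == 10L) role <- "wall-inner"
      if (clouds[[i]]$tissue_class == 11L) role <- "wall-outer"
      if (role != "tissue") {
        cfg$icosphere_subdiv <- cfg$icosphere_subdiv + 1L # global structures
      }
      m <- fit_mesh(capped[[i]], cfg)
      m$role <- role
      m
    })
  })
  is_wall <- vapply(meshed, function(m) m$role != "tissue", logical(1))
  pick_wall <- function(role) {
    hits <- Filter(function(m) m$role == role, meshed[is_wall])
    if (length(hits) > 0) hits[[1]] else NULL
  }
  wall_meshes <- list(inner = pick_wall("wall-inner"),
                      outer = pick_wall("wall-outer"))
  tissue_raw <- meshed[!is_wall]
  tissue_clean <- run_stage("mesh", clean_and_filter(tissue_raw, config$mesh))
  if (!is.null(output_dir)) {
    for (i in seq_along(tissue_clean)) {
      write_ply(tissue_clean[[i]],
                out_path("meshes", sprintf("tissue_%03d_class%02d.ply", i,
                                           tissue_clean[[i]]$tissue_class)))
    }
    for (nm in names(wall_meshes)) {
      if (!is.null(wall_meshes[[nm]])) {
        write_ply(wall_meshes[[nm]], out_path("meshes",
                                              sprintf("wall_%s.ply", nm)))
      }
    }
    mesh_manifest <- lapply(tissue_clean, function(m) {
      list(tissue_class = m$tissue_class, volume_um3 = m$volume,
           vertices = nrow(m$vertices), faces = nrow(m$faces))
    })
    jsonlite::write_json(mesh_manifest, out_path("meshes", "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tprev <- stage_t("mesh", tprev)

  # -- fem (optional) -------------------------------------------------------
  fem <- NULL
  if (run_fem) {
    fem <- run_stage("fem", {
      mid <- inflated[[ceiling(length(inflated) / 2)]]
      sec <- fe_section_from_slice(mid)
      model <- build_fe_model(sec, config$materials, config$pressure)
      list(model = model,
           comparison = compare_homo_hetero(model, config$materials))
    })
    if (!is.null(output_dir)) {
      write_vtk(fem$model, fem$comparison$heterogeneous,
                out_path("fem", "heterogeneous.vtk"))
      write_vtk(fem$model, fem$comparison$homogeneous,
                out_path("fem", "homogeneous.vtk"))
    }
    tprev <- stage_t("fem", tprev)
  }

  # -- report ---------------------------------------------------------------
  result <- list(
    slices = slices, inflated = inflated,
    contours_by_slice = contours_by_slice,
    tracks = tracks, transforms = asm$transforms, clouds = clouds,
    meshes = tissue_clean, tissue_meshes_unfiltered = tissue_raw,
    wall_meshes = wall_meshes, fem = fem, truth = truth
  )
  if (!is.null(truth)) {
    result$report <- run_stage("report",
                               ground_truth_report(result, truth,
                                                   config$mesh$grid_n))
    tprev <- stage_t("report", tprev)
  }
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  manifest$n_slices <- length(slices)
  manifest$n_tracks <- length(tracks)
  manifest$n_tissue_meshes <- length(tissue_clean)
  if (!is.null(output_dir)) {
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result$manifest <- manifest
  result
}
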