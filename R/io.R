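#' Write an image stack as a multi-page TIFF with a JSON spacing sidecar
#'
#' Intensities are scaled by `scale` (default: the stack's maximum, stored in
#' the sidecar) into `[0, 1]` and written as 16-bit gray pages (one page per
#' z-slice). Voxel spacing, origin and the scale go into `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param scale intensity divisor; values above it are clipped.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = NULL) {
  stopifnot(inherits(stack, "lcn_stack"))
  if (is.null(scale)) scale <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k)
    pmin(pmax(stack$data[, , k] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_spacing_um = stack$spacing_um,
                            origin_um = stack$origin_um,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack()]
#'
#' Requires the `<path>.json` sidecar for the voxel spacing (xy spacing can
#' fall back to the TIFF resolution tags, but there is no reliable z-spacing
#' tag in baseline TIFF, so a missing sidecar is an error). A single-page
#' TIFF is rejected: the pipeline operates on 3D stacks.
#'
#' @param path TIFF path.
#' @return An [image_stack()] (intensities rescaled by the stored scale).
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing spacing sidecar '", sidecar,
         "': write_stack() stores voxel_spacing_um there (convention: ",
         "<stack>.tif.json with fields voxel_spacing_um, origin_um, ",
         "intensity_scale)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("'", path, "' has a single page: a 3D multi-page TIFF is required")
  d1 <- dim(pages[[1]])
  arr <- array(0, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg
  }
  scale <- meta$intensity_scale %||% 1
  image_stack(arr * scale, as.numeric(meta$voxel_spacing_um),
              as.numeric(meta$origin_um %||% c(0, 0, 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an LCN graph as nodes/edges CSV (and optionally GraphML)
#'
#' `nodes.csv` columns: `id, x_um, y_um, z_um, kind, degree, lacuna_id`;
#' `edges.csv` columns: `source, target, length_um, path_wkt` (the full 3D
#' polyline as a WKT-style `LINESTRING Z`). With `graphml = TRUE` an
#' additional `graph.graphml` is written via igraph.
#'
#' @param graph an [lcn_graph()].
#' @param dir output directory (created if needed).
#' @param graphml also write GraphML.
#' @return `dir`, invisibly.
#' @export
write_graph_files <- function(graph, dir, graphml = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- graph$nodes
  write.csv(n, file.path(dir, "nodes.csv"), row.names = FALSE)
  e <- graph$edges
  e$path_wkt <- vapply(graph$paths, path_to_wkt, character(1))
  write.csv(e, file.path(dir, "edges.csv"), row.names = FALSE)
  if (graphml)
    igraph::write_graph(as_igraph(graph),
                        file.path(dir, "graph.graphml"), format = "graphml")
  invisible(dir)
}

#' Read an LCN graph written by [write_graph_files()]
#'
#' @param dir directory containing `nodes.csv` and `edges.csv`.
#' @return An [lcn_graph()]; topology is exact, geometry round-trips to
#'   better than 1e-6 um.
#' @export
read_graph_files <- function(dir) {
  n <- read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE)
  e <- read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE)
  paths <- lapply(e$path_wkt %||% character(nrow(e)), wkt_to_path)
  e$path_wkt <- NULL
  if (!nrow(e)) paths <- list()
  lcn_graph(n, e, paths)
}

#' Default pipeline configuration
#'
#' One nested list holding every stage's parameters (generator, extraction,
#' metrics, regions, qBEI) plus the master seed; this is what
#' [read_pipeline_config()] validates against, and unknown keys are rejected.
#'
#' @return Named nested list.
#' @export
default_pipeline_config <- function() {
  gp <- generator_params()
  list(
    seed = 1L,
    generator = gp[setdiff(names(gp), "seed")],
    extraction = list(sigma_small_um = 0.15, sigma_large_um = 0.8,
                      threshold_k = 0.1, thickness_radius_um = 1.0,
                      min_lacuna_volume_um3 = 50, merge_radius_um = 0.5,
                      prune_length_um = 0.5, attach_radius_um = 5.0),
    metrics = list(v_sub_um3 = 400),
    regions = list(projection_mode = "count"),
    qbei = list(gl_carbon = 25, gl_aluminum = 225,
                anchors = list(c(25, 0), c(225, 39.86)))
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Starts from [default_pipeline_config()] and overlays the file's values;
#' keys not present in the defaults raise an error (typo protection).
#'
#' @param path YAML file.
#' @return Validated nested list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd, where) {
    for (key in names(upd)) {
      if (!key %in% names(base))
        stop("unknown configuration key '",
             if (nzchar(where)) paste0(where, ".", key) else key, "'")
      if (is.list(base[[key]]) && is.list(upd[[key]]) &&
          !is.null(names(base[[key]])))
        base[[key]] <- merge_cfg(base[[key]], upd[[key]],
                                 if (nzchar(where)) paste0(where, ".", key)
                                 else key)
      else base[[key]] <- upd[[key]]
    }
    base
  }
  merge_cfg(default_pipeline_config(), user, "")
}

#' Write a pipeline configuration to YAML
#'
#' @param config nested list (e.g. [default_pipeline_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records what a pipeline stage did: its name, parameters, seed, input and
#' output files (with sizes) and a timestamp, as JSON.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param params parameter list.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, params, inputs = character(),
                           outputs = character()) {
  fsize <- function(f) ifelse(file.exists(f), file.size(f), NA)
  jsonlite::write_json(list(
    stage = stage, params = params,
    inputs = data.frame(path = inputs, bytes = fsize(inputs)),
    outputs = data.frame(path = outputs, bytes = fsize(outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
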