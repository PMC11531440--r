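#' 3D image stack with physical voxel spacing
#'
#' Container for a 3D scalar intensity grid with anisotropic voxel spacing,
#' the common currency of the phantom generator and the extraction pipeline.
#' The physical position of voxel `[i, j, k]` (1-based) is
#' `(i - 0.5, j - 0.5, k - 0.5) * spacing + origin`, i.e. voxel centres sit at
#' half-integer multiples of the spacing.
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param spacing_um numeric length-3, voxel spacing in micrometres (> 0).
#'   The default matches a confocal acquisition with 379 nm pixels and 340 nm
#'   z-steps.
#' @param origin_um numeric length-3, physical position of the corner of voxel
#'   `[1, 1, 1]` in micrometres.
#' @return An object of class `lcn_stack` with elements `data`, `spacing_um`,
#'   `origin_um`.
#' @export
image_stack <- function(data, spacing_um = c(0.379, 0.379, 0.340),
                        origin_um = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("`spacing_um` must be 3 positive finite numbers")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  structure(list(data = data, spacing_um = spacing_um,
                 origin_um = as.numeric(origin_um)),
            class = "lcn_stack")
}

#' @export
print.lcn_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lcn_stack> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2],
              x$spacing_um[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f um, intensity range [%.3g, %.3g]\n",
              d[1] * x$spacing_um[1], d[2] * x$spacing_um[2],
              d[3] * x$spacing_um[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Spatial network of lacunae and canaliculi
#'
#' The graph representation of a lacunocanalicular network: nodes are lacunae,
#' canalicular intersections (junctions) and free branch ends (endpoints);
#' edges are canaliculi with a full 3D polyline path and arc length.
#'
#' @param nodes data.frame with columns `id` (integer), `x_um`, `y_um`, `z_um`,
#'   `kind` (one of `"lacuna"`, `"junction"`, `"endpoint"`), and optionally
#'   `lacuna_id` linking lacuna nodes to a segmentation label. A `degree`
#'   column is (re)computed from the edges.
#' @param edges data.frame with columns `source`, `target` (node ids) and
#'   `length_um`.
#' @param paths list parallel to the edge rows; each element an (n x 3) matrix
#'   of ordered 3D points (um) tracing the canaliculus.
#' @return An object of class `lcn_graph`.
#' @export
lcn_graph <- function(nodes = NULL, edges = NULL, paths = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                        z_um = numeric(), kind = character(),
                        lacuna_id = integer())
  if (is.null(edges))
    edges <- data.frame(source = integer(), target = integer(),
                        length_um = numeric())
  if (is.null(paths)) paths <- list()
  if (!all(c("id", "x_um", "y_um", "z_um", "kind") %in% names(nodes)))
    stop("`nodes` must have columns id, x_um, y_um, z_um, kind")
  if (!all(c("source", "target", "length_um") %in% names(edges)))
    stop("`edges` must have columns source, target, length_um")
  if (!is.null(nodes$kind) && nrow(nodes) &&
      !all(nodes$kind %in% c("lacuna", "junction", "endpoint")))
    stop("node kind must be lacuna, junction or endpoint")
  if (nrow(edges)) {
    bad <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
    if (any(bad))
      stop("edge referencing missing node: rows ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (length(paths) != nrow(edges))
    stop("`paths` must have one entry per edge")
  if (!"lacuna_id" %in% names(nodes)) nodes$lacuna_id <- NA_integer_
  g <- structure(list(nodes = nodes, edges = edges, paths = paths),
                 class = "lcn_graph")
  recompute_degrees(g)
}

recompute_degrees <- function(graph) {
  n <- graph$nodes
  deg <- integer(nrow(n))
  if (nrow(graph$edges)) {
    tab <- table(factor(c(graph$edges$source, graph$edges$target),
                        levels = n$id))
    deg <- as.integer(tab)
  }
  graph$nodes$degree <- deg
  graph
}

#' @export
print.lcn_graph <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("lacuna", "junction", "endpoint")))
  cat(sprintf(paste0("<lcn_graph> %d nodes (%d lacunae, %d junctions, ",
                     "%d endpoints), %d edges, total length %.1f um\n"),
              nrow(x$nodes), k[["lacuna"]], k[["junction"]], k[["endpoint"]],
              nrow(x$edges), sum(x$edges$length_um)))
  invisible(x)
}

#' Total canalicular length of a network
#'
#' @param graph an [lcn_graph()].
#' @return Sum of edge arc lengths in micrometres.
#' @export
total_length <- function(graph) sum(graph$edges$length_um)

#' Node degrees of the "genuine" network nodes
#'
#' Genuine nodes are canalicular intersections with degree >= 3; lacunae and
#' endpoints are excluded.
#'
#' @param graph an [lcn_graph()].
#' @return Integer vector of degrees.
#' @export
genuine_degrees <- function(graph) {
  n <- graph$nodes
  n$degree[n$kind == "junction" & n$degree >= 3]
}

#' Lacunar degrees (number of canaliculi emanating from each lacuna)
#'
#' @param graph an [lcn_graph()].
#' @return data.frame with `id`, `lacuna_id` and `lc_dg`.
#' @export
lacuna_degrees <- function(graph) {
  n <- graph$nodes[graph$nodes$kind == "lacuna", , drop = FALSE]
  data.frame(id = n$id, lacuna_id = n$lacuna_id, lc_dg = n$degree)
}

polyline_length <- function(p) {
  if (is.null(dim(p)) || nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Convert an LCN graph to an igraph object
#'
#' Node attributes `x_um`, `y_um`, `z_um`, `kind`, `degree` and edge attribute
#' `length_um` (plus the path encoded as a WKT-style linestring) are carried
#' over.
#'
#' @param graph an [lcn_graph()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  n <- graph$nodes
  e <- graph$edges
  vert <- data.frame(name = as.character(n$id), x_um = n$x_um, y_um = n$y_um,
                     z_um = n$z_um, kind = n$kind, degree = n$degree,
                     stringsAsFactors = FALSE)
  ed <- data.frame(from = as.character(e$source), to = as.character(e$target),
                   length_um = e$length_um,
                   path_wkt = vapply(graph$paths, path_to_wkt, character(1)),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
}

path_to_wkt <- function(p) {
  if (is.null(dim(p)) || nrow(p) == 0) return("LINESTRING Z EMPTY")
  pts <- apply(p, 1, function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3]))
  paste0("LINESTRING Z (", paste(pts, collapse = ", "), ")")
}

wkt_to_path <- function(s) {
  if (identical(s, "LINESTRING Z EMPTY")) return(matrix(numeric(), 0, 3))
  body <- sub("^LINESTRING Z \\((.*)\\)$", "\\1", s)
  pts <- strsplit(strsplit(body, ",")[[1]], "[[:space:]]+")
  m <- t(vapply(pts, function(v) as.numeric(v[v != ""]), numeric(3)))
  unname(m)
}
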