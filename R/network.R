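#' Capillary network objects
#'
#' A `capnet` holds a capillary network as two tibbles plus per-vessel
#' centerline polylines. Coordinates are in um, right-handed, with the origin
#' at the bounding-box corner. Vessel orientation is `from -> to`; signed
#' quantities (flow, velocity) are relative to that orientation.
#'
#' @param nodes Tibble with columns `node` (integer id), `x`, `y`, `z` (um)
#'   and optionally `boundary` (`"inflow"`, `"outflow"` or `"interior"`).
#' @param vessels Tibble with columns `vessel` (integer id), `from`, `to`
#'   (node ids) and `diameter` (um). A list column `centerline` of n-by-3
#'   matrices may be supplied; otherwise straight segments are used.
#' @param validate Check structural invariants (default `TRUE`).
#'
#' @return An object of class `capnet`.
#' @export
capnet <- function(nodes, vessels, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  vessels <- tibble::as_tibble(vessels)
  stopifnot(all(c("node", "x", "y", "z") %in% names(nodes)),
            all(c("vessel", "from", "to", "diameter") %in% names(vessels)))
  nodes$node <- as.integer(nodes$node)
  vessels$vessel <- as.integer(vessels$vessel)
  vessels$from <- as.integer(vessels$from)
  vessels$to <- as.integer(vessels$to)
  if (!"centerline" %in% names(vessels)) {
    vessels$centerline <- purrr::map2(vessels$from, vessels$to, function(a, b) {
      ia <- match(a, nodes$node); ib <- match(b, nodes$node)
      rbind(c(nodes$x[ia], nodes$y[ia], nodes$z[ia]),
            c(nodes$x[ib], nodes$y[ib], nodes$z[ib]))
    })
  }
  vessels$length <- vapply(vessels$centerline, polyline_length, numeric(1))
  if (!"boundary" %in% names(nodes)) {
    deg <- node_degrees(nodes$node, vessels)
    nodes$boundary <- ifelse(deg <= 1, "outflow", "interior")
  }
  net <- structure(list(nodes = nodes, vessels = vessels), class = "capnet")
  if (validate) validate_capnet(net)
  net
}

#' Arc length of a polyline
#' @param pts n-by-3 matrix of points (um).
#' @return Total arc length, um.
#' @export
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

node_degrees <- function(node_ids, vessels) {
  tab <- table(factor(c(vessels$from, vessels$to), levels = node_ids))
  as.integer(tab)
}

#' Validate the structural invariants of a capillary network
#'
#' Checks unique ids, edge endpoints, connectivity, degree/boundary
#' consistency and agreement of stored lengths with centerline arc lengths.
#'
#' @param net A `capnet`.
#' @return `net`, invisibly; errors describe the violated invariant.
#' @export
validate_capnet <- function(net) {
  nodes <- net$nodes; vessels <- net$vessels
  if (anyDuplicated(nodes$node)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$node[duplicated(nodes$node)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(vessels$vessel)) {
    stop("duplicate vessel id(s): ",
         paste(unique(vessels$vessel[duplicated(vessels$vessel)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(c(vessels$from, vessels$to), nodes$node)
  if (length(unknown) > 0) {
    stop("vessel endpoint references unknown node id(s): ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(vessels$from == vessels$to)) {
    stop("vessel(s) with identical endpoints: ",
         paste(vessels$vessel[vessels$from == vessels$to], collapse = ", "),
         call. = FALSE)
  }
  g <- capnet_igraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("network graph is disconnected (", comp$no,
         " components of sizes ", sizes, ")", call. = FALSE)
  }
  arc <- vapply(vessels$centerline, polyline_length, numeric(1))
  bad <- abs(arc - vessels$length) > 1e-9 * pmax(arc, 1)
  if (any(bad)) {
    stop("stored length disagrees with centerline arc length for vessel(s): ",
         paste(vessels$vessel[bad], collapse = ", "), call. = FALSE)
  }
  deg <- node_degrees(nodes$node, vessels)
  b <- nodes$boundary
  if (any(b %in% c("inflow", "outflow") & deg != 1)) {
    stop("boundary node(s) with degree != 1: ",
         paste(nodes$node[b != "interior" & deg != 1], collapse = ", "),
         call. = FALSE)
  }
  if (any(b == "interior" & deg < 2)) {
    stop("interior node(s) with degree < 2: ",
         paste(nodes$node[b == "interior" & deg < 2], collapse = ", "),
         call. = FALSE)
  }
  invisible(net)
}

capnet_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$vessels$from),
               to = as.character(net$vessels$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$node))
  )
}

#' Bounding box of a network
#' @param net A `capnet`.
#' @return 2-by-3 matrix (rows: min, max; columns x, y, z), um.
#' @export
capnet_bbox <- function(net) {
  pts <- do.call(rbind, net$vessels$centerline)
  rbind(min = apply(pts, 2, min), max = apply(pts, 2, max))
}

#' @export
print.capnet <- function(x, ...) {
  bb <- capnet_bbox(x)
  ext <- bb[2, ] - bb[1, ]
  cat(sprintf("<capnet> %d vessels, %d nodes (%d inflow, %d outflow)\n",
              nrow(x$vessels), nrow(x$nodes),
              sum(x$nodes$boundary == "inflow"),
              sum(x$nodes$boundary == "outflow")))
  cat(sprintf("  bounding box %.0f x %.0f x %.0f um\n", ext[1], ext[2], ext[3]))
  cat(sprintf("  diameter %.2f +/- %.2f um, length %.1f +/- %.1f um\n",
              mean(x$vessels$diameter), stats::sd(x$vessels$diameter),
              mean(x$vessels$length), stats::sd(x$vessels$length)))
  if ("v_rbc" %in% names(x$vessels)) {
    cat(sprintf("  flow solved: |v_rbc| %.2f +/- %.2f mm/s\n",
                mean(abs(x$vessels$v_rbc)) / 1000,
                stats::sd(abs(x$vessels$v_rbc)) / 1000))
  }
  invisible(x)
}

#' @export
as_tibble.capnet <- function(x, what = c("vessels", "nodes"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' Save a capillary network to disk
#'
#' The CSV format writes `nodes.csv` (id, coordinates, boundary kind),
#' `edges.csv` (topology, diameter and any flow columns) and
#' `centerlines.json` (per-vessel polylines). The JSON format writes a single
#' self-contained file. Both round-trip losslessly through [load_network()].
#'
#' @param net A `capnet`.
#' @param path Directory (CSV format) or file path (JSON format).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      nodes = net$nodes,
      vessels = dplyr::select(net$vessels, -"centerline"),
      centerlines = purrr::map(net$vessels$centerline, ~ unname(as.matrix(.x)))
    )
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         always_decimal = TRUE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  readr::write_csv(net$nodes, file.path(path, "nodes.csv"))
  readr::write_csv(dplyr::select(net$vessels, -"centerline"),
                   file.path(path, "edges.csv"))
  cl <- purrr::map(net$vessels$centerline, ~ unname(as.matrix(.x)))
  names(cl) <- as.character(net$vessels$vessel)
  jsonlite::write_json(cl, file.path(path, "centerlines.json"), digits = NA,
                       always_decimal = TRUE)
  invisible(path)
}

#' Load a capillary network from disk
#'
#' Reads the formats written by [save_network()] and validates the result.
#' Parse errors name the offending ids; disconnected graphs are rejected with
#' the component sizes.
#'
#' @param path Directory with `nodes.csv`/`edges.csv`/`centerlines.json`, or
#'   a JSON file.
#' @param format `"csv"` or `"json"`; guessed from `path` by default.
#' @return A validated `capnet`.
#' @export
load_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "csv" else "json"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    vessels <- tibble::as_tibble(obj$vessels)
    vessels$centerline <- purrr::map(obj$centerlines, ~ matrix(unlist(.x),
                                                               ncol = 3))
    return(capnet(tibble::as_tibble(obj$nodes), vessels))
  }
  nfile <- file.path(path, "nodes.csv")
  efile <- file.path(path, "edges.csv")
  cfile <- file.path(path, "centerlines.json")
  for (f in c(nfile, efile)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  nodes <- readr::read_csv(nfile, show_col_types = FALSE)
  vessels <- readr::read_csv(efile, show_col_types = FALSE)
  if (file.exists(cfile)) {
    cl <- jsonlite::read_json(cfile, simplifyVector = TRUE)
    idx <- match(as.character(vessels$vessel), names(cl))
    if (anyNA(idx)) {
      stop("centerlines.json is missing vessel id(s): ",
           paste(vessels$vessel[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    vessels$centerline <- unname(purrr::map(cl[idx],
                                            ~ matrix(unlist(.x), ncol = 3)))
  }
  capnet(nodes, vessels)
}

#' Export a network to legacy VTK polydata (write-only)
#'
#' Writes an ASCII `.vtk` polydata file with one polyline per vessel and the
#' available per-vessel scalar arrays (diameter, velocity, hematocrit, mean
#' saturation), for visualization in ParaView.
#'
#' @param net A `capnet`.
#' @param path Output file path.
#' @param fields Vessel columns to export as cell data (defaults to all
#'   numeric scalar columns present).
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(net, path, fields = NULL) {
  cl <- net$vessels$centerline
  pts <- do.call(rbind, cl)
  npts <- vapply(cl, nrow, integer(1))
  offsets <- cumsum(c(0, npts[-length(npts)]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "capillary network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(pts))),
             con)
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 10),
                                             collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(cl), length(cl) + sum(npts)), con)
  for (i in seq_along(cl)) {
    writeLines(paste(c(npts[i], offsets[i] + seq_len(npts[i]) - 1),
                     collapse = " "), con)
  }
  if (is.null(fields)) {
    fields <- intersect(c("diameter", "length", "v_rbc", "h_t", "mu_ld",
                          "q", "q_rbc", "s_mean"), names(net$vessels))
  }
  writeLines(sprintf("CELL_DATA %d", length(cl)), con)
  for (f in fields) {
    writeLines(c(sprintf("SCALARS %s double 1", f), "LOOKUP_TABLE default"),
               con)
    writeLines(format(net$vessels[[f]], digits = 10), con)
  }
  invisible(path)
}
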