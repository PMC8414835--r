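# File interfaces: contour stacks as CSV, meshes and nodal fields as ASCII
# VTK unstructured grids (.vtu, with a .pvd manifest for time series),
# scalar traces as CSV, and a JSON run container carrying configuration and
# seed for provenance. Quadratic hexahedra are written as eight linear
# sub-hexahedra per element so any VTK reader displays them; nodal fields
# are written in full. A minimal reader for the package's own .vtu files
# supports round-trip checks.

#' Write a contour stack to CSV
#'
#' One row per contour: station, center xyz, radii, rotation, normal,
#' native flag.
#'
#' @param stack a `contour_stack`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(stack, path) {
  utils::write.csv(stack$contours, path, row.names = FALSE)
  invisible(path)
}

#' Read a contour stack from CSV
#' @param path CSV written by [write_contour_csv()].
#' @param spacing nominal contour spacing, mm (recomputed if `NULL`).
#' @return a `contour_stack`.
#' @export
read_contour_csv <- function(path, spacing = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(spacing)) spacing <- mean(diff(df$station))
  new_contour_stack(df, spacing = spacing)
}

# split one 27-node hex (lexicographic ordering) into 8 linear hexes
hex27_to_hex8 <- function(conn) {
  lex <- function(i, j, k) conn[1L + i + 3L * j + 9L * k]
  out <- matrix(NA_integer_, 8, 8)
  r <- 1L
  for (k in 0:1) for (j in 0:1) for (i in 0:1) {
    out[r, ] <- c(lex(i, j, k), lex(i + 1L, j, k), lex(i + 1L, j + 1L, k),
                  lex(i, j + 1L, k), lex(i, j, k + 1L), lex(i + 1L, j, k + 1L),
                  lex(i + 1L, j + 1L, k + 1L), lex(i, j + 1L, k + 1L))
    r <- r + 1L
  }
  out
}

#' Write a mesh with nodal fields as an ASCII .vtu file
#'
#' @param mesh a `wall_mesh` or `lumen_surface`.
#' @param path output path (`.vtu`).
#' @param point_data named list of per-node fields: vectors (scalars) or
#'   n x 3 matrices (vectors).
#' @param displacement optional n x 3 displacement (mm) added to the node
#'   positions before writing.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), displacement = NULL) {
  P <- mesh$nodes
  if (!is.null(displacement)) P <- P + displacement
  if (inherits(mesh, "wall_mesh")) {
    cells <- do.call(rbind, lapply(seq_len(nrow(mesh$hexes)),
                                   function(e) hex27_to_hex8(mesh$hexes[e, ])))
    ctype <- 12L  # VTK_HEXAHEDRON
  } else {
    cells <- mesh$quads
    ctype <- 9L   # VTK_QUAD
  }
  n <- nrow(P); nc <- nrow(cells); npc <- ncol(cells)
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, nc)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('%s', num(as.vector(t(P))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w('%s', paste(as.vector(t(cells)) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w('%s', paste(seq_len(nc) * npc, collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w('%s', paste(rep(ctype, nc), collapse = " "))
  w('</DataArray></Cells>')
  w('<PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    ncomp <- if (is.matrix(v)) ncol(v) else 1L
    w('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
      nm, ncomp)
    w('%s', num(if (is.matrix(v)) as.vector(t(v)) else v))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Read points and point data back from a package-written .vtu file
#'
#' Minimal reader for round-trip verification of [write_vtu()] output.
#'
#' @param path a `.vtu` file.
#' @return list with `points` (n x 3) and `point_data` (named list).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  parse_da <- function(node) {
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
    ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    if (!is.na(ncomp) && ncomp > 1) matrix(vals, ncol = ncomp, byrow = TRUE)
    else vals
  }
  pts <- parse_da(xml2::xml_find_first(piece, ".//Points/DataArray"))
  pd_nodes <- xml2::xml_find_all(piece, ".//PointData/DataArray")
  pd <- stats::setNames(lapply(pd_nodes, parse_da),
                        vapply(pd_nodes, function(nd) xml2::xml_attr(nd, "Name"),
                               character(1)))
  list(points = pts, point_data = pd)
}

#' Write a .pvd manifest for a .vtu time series
#'
#' @param vtu_paths character vector of `.vtu` files (relative paths are
#'   kept as given).
#' @param times time stamp per file, s.
#' @param path output `.pvd` path.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(vtu_paths, times, path) {
  stopifnot(length(vtu_paths) == length(times))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="Collection" version="0.1"><Collection>', con)
  for (i in seq_along(vtu_paths)) {
    writeLines(sprintf('<DataSet timestep="%.9g" part="0" file="%s"/>',
                       times[i], vtu_paths[i]), con)
  }
  writeLines('</Collection></VTKFile>', con)
  invisible(path)
}

#' Export a wall state to VTK
#'
#' Writes displacement, nodal von Mises stress and the six Cauchy stress
#' components (element means distributed to nodes) as point data.
#'
#' @param state an `aaa_wall_state`.
#' @param path output `.vtu` path.
#' @return `path`, invisibly.
#' @export
export_wall_state <- function(state, path) {
  mesh <- state$mesh
  comp_names <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")
  pd <- list(displacement = state$displacement,
             von_mises = nodal_von_mises(state))
  for (c6 in seq_len(6)) {
    pd[[comp_names[c6]]] <- qp_to_nodal(mesh, state$cauchy_stress[, c6])
  }
  write_vtu(mesh, path, point_data = pd)
}

#' Export FSI traces and fields
#'
#' Writes the last-cycle scalar traces (time, inlet/outlet pressure and
#' flow, mid-sac pressure) as CSV, the per-station TAWSS/OSI as CSV, a .pvd
#' + .vtu displacement time series (every `stride`-th step), and a JSON run
#' container with configuration and seed.
#'
#' @param result an `aaa_fsi_result`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param stride step stride of the VTK series (default: 10).
#' @param seed,config_extra provenance entries for the JSON container.
#' @return named list of written paths, invisibly.
#' @export
export_fsi_result <- function(result, dir, prefix = "fsi", stride = 10L,
                              seed = NULL, config_extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- nrow(result$p)
  traces <- data.frame(
    time = result$time,
    p_inlet = result$p[1, ], p_outlet = result$p[nz, ],
    p_sac = result$lumen_pressure,
    q_inlet = result$q[1, ], q_outlet = result$q[nz, ])
  trace_path <- file.path(dir, paste0(prefix, "_traces.csv"))
  utils::write.csv(traces, trace_path, row.names = FALSE)

  wssf <- data.frame(station = result$stations,
                     native = result$native_stations,
                     tawss = tawss(result$wss, result$time),
                     osi = osi(result$wss, result$time))
  wss_path <- file.path(dir, paste0(prefix, "_wss.csv"))
  utils::write.csv(wssf, wss_path, row.names = FALSE)

  steps <- seq(1L, length(result$time), by = stride)
  vtu_files <- character(0)
  for (s in steps) {
    f <- sprintf("%s_%04d.vtu", prefix, s)
    write_vtu(result$mesh, file.path(dir, f),
              point_data = list(displacement = result$displacement[[s]]))
    vtu_files <- c(vtu_files, f)
  }
  pvd_path <- file.path(dir, paste0(prefix, ".pvd"))
  write_pvd(vtu_files, result$time[steps], pvd_path)

  container <- c(list(
    arm = if (result$prestress) "pse" else "nopse",
    seed = seed, config = unclass(result$config),
    dia_pressure = result$dia_pressure, sys_pressure = result$sys_pressure,
    periodicity = result$periodicity), config_extra)
  json_path <- file.path(dir, paste0(prefix, "_run.json"))
  jsonlite::write_json(container, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(traces = trace_path, wss = wss_path, pvd = pvd_path,
                 json = json_path))
}

#' Serialize a metric report to JSON
#'
#' @param report a `metric_report`.
#' @param path output JSON path.
#' @param seed optional seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, seed = NULL) {
  out <- unclass(report)
  out$spatial_fields <- NULL  # per-node fields go to VTK, not JSON
  out$arms <- NULL
  out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
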