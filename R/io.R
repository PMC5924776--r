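#' Write a time series as annotated CSV
#'
#' CSV with `#`-prefixed header metadata lines (including the seed when
#' supplied), readable back bit-identically by [read_trace_csv()].
#'
#' @param trace a data frame.
#' @param path output file.
#' @param meta named list of metadata written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  # full-precision numeric formatting so the round trip is bit-identical
  out <- as.data.frame(lapply(trace, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  names(out) <- names(trace)
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_trace_csv()]
#'
#' @param path input file.
#' @return The data frame, with the metadata in attribute `"meta"`.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write a calcium transient as a sampled two-column CSV
#'
#' @param ca a [make_calcium()] object.
#' @param path output file.
#' @param dt sampling interval (s).
#' @return `path`, invisibly.
#' @export
write_calcium_csv <- function(ca, path, dt = 1e-3) {
  t <- seq(0, ca$period, by = dt)
  write_trace_csv(data.frame(time_s = t, ca_nM = ca_at(ca)(t)), path,
                  meta = list(period_s = ca$period))
  invisible(path)
}

#' Read a sampled calcium transient
#'
#' Returns a linear-interpolation evaluator wrapped with the recorded
#' period, usable anywhere a [make_calcium()] object's evaluator is.
#'
#' @param path CSV written by [write_calcium_csv()] (or any two-column
#'   time/concentration file with a `period_s` metadata line).
#' @return List with `period` and vectorised function `fun(t)` (nM).
#' @export
read_calcium_csv <- function(path) {
  df <- read_trace_csv(path)
  period <- as.numeric(attr(df, "meta")$period_s)
  if (!length(period) || is.na(period)) period <- max(df[[1]])
  fun <- function(t) {
    stats::approx(df[[1]], df[[2]], xout = t %% period, rule = 2)$y
  }
  list(period = period, fun = fun)
}

#' Load a model configuration from a YAML file
#'
#' Reads `active:`, `passive:`, `mesh:`, `drive:` and `calcium:` blocks
#' and instantiates the corresponding parameter objects, applying block
#' entries over the package defaults.  Units follow the package
#' conventions (stress kPa at the organ scale and Pa at the cellular
#' scale, lengths nm for sarcomeres and mm for the mesh, time s,
#' volume mL, calcium nM).
#'
#' @param path YAML file.
#' @return List with `active`, `passive`, `mesh`, `drive`, `calcium`
#'   objects and `seed` (if declared).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  act <- do.call(active_params, cfg$active %||% list())
  pas <- do.call(passive_params, cfg$passive %||% list())
  mesh <- do.call(build_lv_mesh, cfg$mesh %||% list())
  drive <- do.call(make_flowrate, cfg$drive %||% list())
  ca <- do.call(make_calcium, cfg$calcium %||% list())
  list(active = act, passive = pas, mesh = mesh, drive = drive,
       calcium = ca, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a mesh (with optional fields) as legacy-ASCII VTK
#'
#' Writes an unstructured-grid file viewable in ParaView: hexahedral
#' cells, optional nodal displacements as point vectors and per-element
#' scalars as cell data.
#'
#' @param mesh a [build_lv_mesh()] object.
#' @param path output `.vtk` file.
#' @param u optional nodal displacement matrix (n x 3).
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, u = NULL, cell_data = list()) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  n <- nrow(x); ne <- nrow(mesh$elem)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "left-ventricle hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(x, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  utils::write.table(cbind(8L, mesh$elem - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
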