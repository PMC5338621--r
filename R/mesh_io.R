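#' Read a labelled tetrahedral mesh
#'
#' Reads a tetrahedral volume mesh with integer per-cell compartment labels
#' from a legacy-VTK ASCII unstructured-grid file (the interchange format
#' written by [write_mesh()] and understood by common mesh viewers).
#'
#' @param path file path.
#' @param format mesh format; currently `"vtk"` (legacy ASCII).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format = c("vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  read_vtk_lines(lines)
}

read_vtk_lines <- function(lines) {
  up <- toupper(lines)
  if (!any(startsWith(up, "DATASET UNSTRUCTURED_GRID"))) {
    stop("not a legacy-VTK unstructured grid")
  }
  scan_block <- function(start, n, what = double()) {
    txt <- character(0)
    i <- start
    got <- 0L
    out <- vector(mode = typeof(what), length = 0L)
    while (got < n && i <= length(lines)) {
      vals <- scan(text = lines[i], what = what, quiet = TRUE)
      out <- c(out, vals)
      got <- length(out)
      i <- i + 1L
    }
    if (length(out) < n) stop("truncated VTK block")
    list(values = out[seq_len(n)], next_line = i)
  }

  ip <- grep("^POINTS", up)[1]
  if (is.na(ip)) stop("POINTS section missing")
  npts <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  pts <- scan_block(ip + 1L, 3L * npts)
  nodes <- matrix(pts$values, ncol = 3L, byrow = TRUE)

  ic <- grep("^CELLS", up)[1]
  if (is.na(ic)) stop("CELLS section missing")
  hdr <- strsplit(trimws(lines[ic]), "\\s+")[[1]]
  ncell <- as.integer(hdr[2]); ntot <- as.integer(hdr[3])
  cells <- scan_block(ic + 1L, ntot, what = integer())$values

  it <- grep("^CELL_TYPES", up)[1]
  if (is.na(it)) stop("CELL_TYPES section missing")
  ctypes <- scan_block(it + 1L, ncell, what = integer())$values
  if (any(ctypes != 10L)) stop("unsupported cell type; only tetrahedra (VTK type 10) are supported")

  # unpack connectivity: each record is "4 i j k l"
  conn <- matrix(cells, ncol = 5L, byrow = TRUE)
  if (any(conn[, 1] != 4L)) stop("unsupported cell type; non-tetrahedral cell record")
  tets <- conn[, 2:5, drop = FALSE] + 1L

  id <- grep("^CELL_DATA", up)[1]
  if (is.na(id)) stop("CELL_DATA with compartment labels missing")
  isc <- grep("^SCALARS", up)
  isc <- isc[isc > id][1]
  if (is.na(isc)) stop("CELL_DATA with compartment labels missing")
  # skip LOOKUP_TABLE line if present
  start <- isc + 1L
  if (grepl("^LOOKUP_TABLE", up[start])) start <- start + 1L
  labels <- scan_block(start, ncell, what = integer())$values

  comp <- NULL
  imeta <- grep("^# compartments:", lines)
  if (length(imeta)) {
    comp <- strsplit(sub("^# compartments:\\s*", "", lines[imeta[1]]), ",")[[1]]
    comp <- trimws(comp)
  }
  if (is.null(comp) || !length(comp)) {
    comp <- paste0("compartment", seq_len(max(labels)))
  }
  tet_mesh(nodes, tets, labels, compartments = comp)
}

#' Write a labelled tetrahedral mesh
#'
#' Writes a [tet_mesh()] as a legacy-VTK ASCII unstructured grid with the
#' compartment labels stored as an integer `CELL_DATA` scalar field.
#' Coordinates are written with 17 significant digits so that
#' [read_mesh()] round-trips them bit-exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param format mesh format; currently `"vtk"`.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = c("vtk")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  n <- nrow(mesh$nodes); t <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "cemfwd tetrahedral head mesh",
               paste0("# compartments: ", paste(mesh$compartments, collapse = ",")),
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", t, 5L * t), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", t), con)
  writeLines(format(rep.int(10L, t)), con)
  writeLines(sprintf("CELL_DATA %d", t), con)
  writeLines(c("SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh$labels), con)
  invisible(path)
}
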