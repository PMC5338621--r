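#' Quasi-uniform spiral electrode layout
#'
#' Deterministic Fibonacci-spiral layout of electrode center points over the
#' upper portion of a sphere, standing in for a 10-20 style cap. The electrode
#' nearest the vertex (+z) is nominated `"Fz-like"` (it sits over the anterior
#' fontanel of [default_fontanels()]), and electrode 5 is nominated
#' `"C6-like"`, mirroring the numbering used by the two-source experiment.
#'
#' @param n_electrodes number of electrodes (default 74).
#' @param radius sphere radius (m) on which centers are placed.
#' @param coverage fraction of the sphere's surface covered by the cap,
#'   measured from the vertex (default 0.65, i.e. down to z/r = -0.3).
#' @return tibble with columns `electrode`, `x`, `y`, `z`, `label`
#'   (`"Fz-like"`, `"C6-like"` or `""`).
#' @export
fibonacci_cap_centers <- function(n_electrodes = 74L, radius = 0.05,
                                  coverage = 0.65) {
  stopifnot(n_electrodes >= 1L, coverage > 0, coverage <= 1)
  k <- seq_len(n_electrodes)
  z_lo <- 1 - 2 * coverage
  # midpoint rule in z keeps points off the rim and the exact vertex
  z <- 1 - (k - 0.5) / n_electrodes * (1 - z_lo)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (k - 1L)
  rho <- sqrt(pmax(0, 1 - z^2))
  xyz <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  lab <- character(n_electrodes)
  lab[which.max(xyz[, 3])] <- "Fz-like"
  if (n_electrodes >= 5L && lab[5L] == "") lab[5L] <- "C6-like"
  tibble::tibble(electrode = k, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 label = lab)
}

#' Build an electrode cap on a mesh boundary
#'
#' Forms each electrode contact surface as the set of boundary triangles
#' whose centroid lies within `contact_radius` of the electrode center
#' (circular 10 mm contacts as triangle sets within 5 mm of the center, by
#' default). Centers are first projected radially onto the scalp radius of
#' the mesh boundary.
#'
#' @param mesh a [tet_mesh()].
#' @param centers electrode centers: a numeric L x 3 matrix or a tibble with
#'   columns `x`, `y`, `z` (and optionally `label`), e.g. from
#'   [fibonacci_cap_centers()].
#' @param contact_radius capture distance (m); default 5 mm, i.e. 10 mm
#'   diameter contacts.
#' @param impedance average contact impedance Z_l in Ohm: scalar (recycled) or
#'   length-L vector. Must be positive.
#' @return object of class `electrode_cap`: list with `centers` (L x 3,
#'   surface-projected), `triangles` (list of boundary-triangle index
#'   vectors), `areas` (m^2), `impedance` (Ohm), `labels`,
#'   `contact_radius`, plus the boundary-triangle count of the mesh it was
#'   built on.
#' @export
build_electrode_cap <- function(mesh, centers, contact_radius = 0.005,
                                impedance = 2000) {
  labels <- NULL
  if (is.data.frame(centers)) {
    labels <- if ("label" %in% names(centers)) centers$label else NULL
    centers <- as.matrix(centers[, c("x", "y", "z")])
  }
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  L <- nrow(centers)
  if (is.null(labels)) labels <- character(L)
  impedance <- rep_len(as.numeric(impedance), L)
  if (any(impedance <= 0)) stop("electrode impedances must be positive")

  geo <- boundary_geometry(mesh)
  areas <- triangle_areas(mesh)
  # project centers radially to the outer surface radius
  rad <- sqrt(rowSums(geo$centroids^2))
  r_out <- max(rad)
  cn <- sqrt(rowSums(centers^2))
  if (any(cn == 0)) stop("electrode center at the origin cannot be projected")
  centers <- centers / cn * r_out

  # restrict candidate triangles to the outer surface (a head mesh has a
  # single outer boundary, but be robust to internal cavities)
  tri_sets <- vector("list", L)
  assign_of <- integer(nrow(geo$centroids))  # 0 = unassigned
  for (l in seq_len(L)) {
    d2 <- rowSums(sweep(geo$centroids, 2L, centers[l, ])^2)
    hit <- which(d2 <= contact_radius^2)
    if (!length(hit)) {
      stop("empty electrode: no boundary triangle centroid within ",
           format(contact_radius), " m of electrode ", l)
    }
    clash <- hit[assign_of[hit] != 0L]
    if (length(clash)) {
      stop("overlapping electrode patches: electrodes ",
           assign_of[clash[1]], " and ", l,
           " both capture boundary triangle ", clash[1])
    }
    assign_of[hit] <- l
    tri_sets[[l]] <- hit
  }
  a_l <- vapply(tri_sets, function(ix) sum(areas[ix]), numeric(1))
  structure(
    list(centers = centers, triangles = tri_sets, areas = a_l,
         impedance = impedance, labels = labels,
         contact_radius = contact_radius,
         n_boundary_tris = nrow(mesh$boundary_tris)),
    class = "electrode_cap"
  )
}

#' @export
print.electrode_cap <- function(x, ...) {
  cat("<electrode_cap> ", length(x$triangles), " electrodes, contact radius ",
      format(x$contact_radius), " m\n", sep = "")
  cat("areas (m^2): ", format(min(x$areas), digits = 3), " - ",
      format(max(x$areas), digits = 3),
      "; impedance (Ohm): ", format(min(x$impedance)), " - ",
      format(max(x$impedance)), "\n", sep = "")
  invisible(x)
}

#' Tidy view of an electrode cap
#' @param x an `electrode_cap`.
#' @param ... unused.
#' @return tibble with one row per electrode: center coordinates, contact
#'   area, impedance, triangle count and label.
#' @export
tidy.electrode_cap <- function(x, ...) {
  ctr <- x$centers
  areas <- x$areas
  imp <- x$impedance
  ntri <- lengths(x$triangles)
  labs <- x$labels
  tibble::tibble(
    electrode = seq_along(ntri),
    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
    area = areas,
    impedance = imp,
    n_triangles = ntri,
    label = labs
  )
}

#' Replace the contact impedances of a cap
#' @param cap an `electrode_cap`.
#' @param impedance scalar or per-electrode vector (Ohm), positive.
#' @return the cap with updated impedances.
#' @export
set_impedance <- function(cap, impedance) {
  impedance <- rep_len(as.numeric(impedance), length(cap$triangles))
  if (any(impedance <= 0)) stop("electrode impedances must be positive")
  cap$impedance <- impedance
  cap
}

#' Write / read an electrode cap specification
#'
#' The cap is stored as JSON: per electrode center, contact radius, impedance
#' and label. Triangle assignments are mesh-dependent and are rebuilt with
#' [build_electrode_cap()] after reading.
#'
#' @param cap an `electrode_cap`.
#' @param path file path.
#' @return `write_electrode_cap` returns `path` invisibly;
#'   `read_electrode_cap` returns a tibble of centers suitable for
#'   [build_electrode_cap()] with attributes `contact_radius` and `impedance`.
#' @export
write_electrode_cap <- function(cap, path) {
  obj <- list(
    contact_radius = cap$contact_radius,
    electrodes = tidy.electrode_cap(cap)[, c("electrode", "x", "y", "z",
                                             "impedance", "label")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_electrode_cap
#' @export
read_electrode_cap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- tibble::as_tibble(obj$electrodes)
  attr(centers, "contact_radius") <- obj$contact_radius
  attr(centers, "impedance") <- centers$impedance
  centers
}

#' Single-triangle electrode patches (point-electrode limit)
#'
#' Builds a degenerate cap in which each electrode's contact surface is the
#' single boundary triangle nearest its center, holding the effective
#' impedance `Z_tilde = Z_l A_l` fixed (so `Z_l = z_tilde / A_l`). In the
#' limit of vanishing patch size the CEM voltages tend to the point electrode
#' model evaluated at the patch location; pairing this cap with a barycentric
#' PEM at the triangle centroids exhibits that limit under mesh refinement.
#'
#' @param mesh a [tet_mesh()].
#' @param centers electrode centers (matrix or tibble as in
#'   [build_electrode_cap()]).
#' @param z_tilde effective contact impedance (Ohm m^2), scalar or per
#'   electrode.
#' @return an `electrode_cap` whose `centers` are the chosen triangle
#'   centroids.
#' @export
single_triangle_cap <- function(mesh, centers, z_tilde = 0.15) {
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y", "z")])
  centers <- as.matrix(centers)
  geo <- boundary_geometry(mesh)
  areas <- triangle_areas(mesh)
  L <- nrow(centers)
  z_tilde <- rep_len(as.numeric(z_tilde), L)
  tri <- integer(L)
  for (l in seq_len(L)) {
    d2 <- rowSums(sweep(geo$centroids, 2L, centers[l, ])^2)
    d2[tri[seq_len(l - 1L)]] <- Inf  # keep patches disjoint
    tri[l] <- which.min(d2)
  }
  a_l <- areas[tri]
  structure(
    list(centers = geo$centroids[tri, , drop = FALSE],
         triangles = as.list(tri), areas = a_l,
         impedance = z_tilde / a_l, labels = character(L),
         contact_radius = sqrt(max(a_l)),
         n_boundary_tris = nrow(mesh$boundary_tris)),
    class = "electrode_cap"
  )
}
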