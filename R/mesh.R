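#' Tetrahedral head mesh
#'
#' Container for a labelled tetrahedral volume mesh: the computational domain
#' of the forward problem. Node coordinates are in meters with the head center
#' at the origin. On construction every tetrahedron is reordered to positive
#' signed volume, the boundary triangulation is extracted (faces belonging to
#' exactly one tetrahedron) and oriented so that recorded vertex order gives an
#' outward normal.
#'
#' @param nodes numeric matrix, N x 3, node coordinates (m).
#' @param tets integer matrix, T x 4, 1-based node indices.
#' @param labels integer vector of length T, per-tetrahedron compartment code.
#' @param compartments character vector naming the compartment codes, i.e.
#'   `compartments[labels]` is the compartment name of each tetrahedron.
#'
#' @return An object of class `tet_mesh` with elements `nodes`, `tets`,
#'   `labels`, `compartments`, `boundary_tris` (B x 3, outward-oriented) and
#'   `boundary_tet` (owning tetrahedron of each boundary triangle).
#' @export
tet_mesh <- function(nodes, tets, labels,
                     compartments = c("brain", "csf", "skull", "fontanel", "scalp")) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  labels <- as.integer(labels)
  if (ncol(nodes) != 3L) stop("`nodes` must be an N x 3 matrix")
  if (ncol(tets) != 4L) stop("`tets` must be a T x 4 matrix")
  if (length(labels) != nrow(tets)) stop("`labels` must have one entry per tetrahedron")
  if (min(tets) < 1L || max(tets) > nrow(nodes)) stop("tetrahedron node index out of range")
  if (anyNA(nodes) || anyNA(tets)) stop("mesh contains missing values")

  vols <- signed_tet_volumes(nodes, tets)
  if (any(abs(vols) < .Machine$double.eps)) {
    stop("degenerate (zero-volume) tetrahedron at index ",
         which(abs(vols) < .Machine$double.eps)[1])
  }
  neg <- vols < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]

  bnd <- extract_boundary(nodes, tets)
  structure(
    list(nodes = nodes, tets = tets, labels = labels,
         compartments = compartments,
         boundary_tris = bnd$tris, boundary_tet = bnd$tet),
    class = "tet_mesh"
  )
}

#' Signed tetrahedron volumes
#'
#' @param nodes N x 3 coordinate matrix.
#' @param tets T x 4 index matrix.
#' @return numeric vector of signed volumes (m^3); positive under the
#'   package's node-ordering convention.
#' @keywords internal
signed_tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Tetrahedron volumes of a mesh
#' @param mesh a [tet_mesh()].
#' @return numeric vector of positive volumes (m^3).
#' @export
tet_volumes <- function(mesh) {
  abs(signed_tet_volumes(mesh$nodes, mesh$tets))
}

# All 4 faces of every tet, with the opposite (local 4th) node recorded.
# Faces are returned unsorted (as-listed) together with a canonical sorted key.
all_tet_faces <- function(tets) {
  nt <- nrow(tets)
  # face k is opposite local vertex k
  f1 <- tets[, c(2L, 3L, 4L)]
  f2 <- tets[, c(1L, 3L, 4L)]
  f3 <- tets[, c(1L, 2L, 4L)]
  f4 <- tets[, c(1L, 2L, 3L)]
  faces <- rbind(f1, f2, f3, f4)
  opp <- c(tets[, 1L], tets[, 2L], tets[, 3L], tets[, 4L])
  tet_of <- rep.int(seq_len(nt), 4L)
  sorted <- t(apply(faces, 1L, sort.int, method = "radix"))
  list(faces = faces, opp = opp, tet = tet_of, sorted = sorted)
}

face_keys <- function(sorted, n_nodes) {
  # collision-free integer-ish key via character paste (robust for any N)
  paste(sorted[, 1], sorted[, 2], sorted[, 3], sep = "_")
}

extract_boundary <- function(nodes, tets) {
  ft <- all_tet_faces(tets)
  key <- face_keys(ft$sorted, nrow(nodes))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  idx <- which(key %in% bkey)
  tris <- ft$faces[idx, , drop = FALSE]
  opp <- ft$opp[idx]
  own <- ft$tet[idx]
  # orient outward: normal of (v1,v2,v3) must point away from the opposite node
  p1 <- nodes[tris[, 1], , drop = FALSE]
  p2 <- nodes[tris[, 2], , drop = FALSE]
  p3 <- nodes[tris[, 3], , drop = FALSE]
  n <- vec_cross(p2 - p1, p3 - p1)
  inward <- rowSums(n * (nodes[opp, , drop = FALSE] - p1)) > 0
  tris[inward, c(2L, 3L)] <- tris[inward, c(3L, 2L)]
  list(tris = tris, tet = own)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Areas of triangles given by node indices
#' @param mesh a [tet_mesh()].
#' @param tris M x 3 index matrix (defaults to the mesh boundary).
#' @return numeric vector of areas (m^2).
#' @export
triangle_areas <- function(mesh, tris = mesh$boundary_tris) {
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  n <- vec_cross(p2 - p1, p3 - p1)
  sqrt(rowSums(n^2)) / 2
}

#' Outward unit normals and centroids of boundary triangles
#' @param mesh a [tet_mesh()].
#' @return list with `normals` (B x 3) and `centroids` (B x 3).
#' @export
boundary_geometry <- function(mesh) {
  tris <- mesh$boundary_tris
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  n <- vec_cross(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(n^2))
  list(normals = n / len, centroids = (p1 + p2 + p3) / 3)
}

#' Interior faces of a mesh
#'
#' Enumerates faces shared by exactly two tetrahedra, with the two adjacent
#' tetrahedra and the pair of opposite nodes (the nodes of the two adjacent
#' tetrahedra that do not lie on the face).
#'
#' @param mesh a [tet_mesh()].
#' @return list of matrices `faces` (F x 3), `tets` (F x 2) and `opp` (F x 2):
#'   `opp[f, k]` is the node of `tets[f, k]` opposite `faces[f, ]`.
#' @export
interior_faces <- function(mesh) {
  ft <- all_tet_faces(mesh$tets)
  key <- face_keys(ft$sorted, nrow(mesh$nodes))
  ord <- order(key, method = "radix")
  key_s <- key[ord]
  runs <- rle(key_s)
  two <- runs$lengths == 2L
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  i1 <- ord[starts[two]]
  i2 <- ord[ends[two]]
  list(faces = ft$sorted[i1, , drop = FALSE],
       tets = cbind(ft$tet[i1], ft$tet[i2]),
       opp = cbind(ft$opp[i1], ft$opp[i2]))
}

#' Validate mesh invariants
#'
#' Checks positive volumes, boundary-face consistency (faces belonging to one
#' tetrahedron only), outward orientation of recorded boundary triangles, the
#' face-count conservation identity `4 T = 2 F_int + F_bnd`, index ranges and
#' absence of orphan label codes.
#'
#' @param mesh a [tet_mesh()].
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vols <- signed_tet_volumes(mesh$nodes, mesh$tets)
  if (any(vols <= 0)) stop("non-positive tetrahedron volume at index ", which(vols <= 0)[1])
  fi <- interior_faces(mesh)
  if (4L * nrow(mesh$tets) != 2L * nrow(fi$faces) + nrow(mesh$boundary_tris)) {
    stop("face-count conservation violated")
  }
  geo <- boundary_geometry(mesh)
  own <- mesh$boundary_tet
  tc <- tet_centroids(mesh)[own, , drop = FALSE]
  outward <- rowSums(geo$normals * (geo$centroids - tc)) > 0
  if (!all(outward)) stop("boundary triangle with inward orientation")
  if (max(mesh$labels) > length(mesh$compartments) || min(mesh$labels) < 1L) {
    stop("compartment label outside `compartments` range")
  }
  invisible(TRUE)
}

#' Tetrahedron centroids
#' @param mesh a [tet_mesh()].
#' @return T x 3 matrix of centroids (m).
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets, ",
      nrow(x$boundary_tris), " boundary triangles\n", sep = "")
  tab <- table(factor(x$compartments[x$labels], levels = x$compartments))
  tab <- tab[tab > 0]
  cat("compartments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
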