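#' Quadrature verification of a Whitney source column
#'
#' Independently recomputes one column of the source matrix `G` and the dipole
#' moment integral by numerical quadrature over the two tetrahedra adjacent to
#' the dipole's face, without using the two-entry closed form. The face-based
#' vector field is reconstructed from first principles: `w = alpha_T (x -
#' P_T)` on each adjacent tetrahedron (`P_T` the vertex opposite the face),
#' with the two coefficients fixed by continuity of the normal flux across the
#' face and by normalizing the quadrature moment `int w dV` to the unit vector
#' from `P_i` to `P_j`. A 4-point degree-2 barycentric rule (exact for the
#' linear integrands involved) evaluates `int psi (div w) dV` for every node
#' of the two tetrahedra and the moment itself.
#'
#' @param mesh a [tet_mesh()].
#' @param space a `whitney_source_space` built on `mesh`.
#' @param k dipole index.
#' @return list with `g` (sparse-style list: `nodes`, `values`), `moment`
#'   (the quadrature moment, should equal `space$moments[k, ]`), and
#'   `g_dense` (length-N numeric column).
#' @export
whitney_quadrature_column <- function(mesh, space, k) {
  pi_ <- space$node_pairs[k, 1]; pj <- space$node_pairs[k, 2]
  t1 <- space$adjacent_tets[k, 1]; t2 <- space$adjacent_tets[k, 2]
  # identify which adjacent tet holds which opposite node
  has_j <- pj %in% mesh$tets[t2, ]
  if (!has_j) { tmp <- t1; t1 <- t2; t2 <- tmp }
  stopifnot(pi_ %in% mesh$tets[t1, ], pj %in% mesh$tets[t2, ])

  # degree-2 barycentric quadrature on a tetrahedron (4 points, weights 1/4)
  a <- (5 - sqrt(5)) / 20; b <- (5 + 3 * sqrt(5)) / 20
  bary <- rbind(c(b, a, a, a), c(a, b, a, a), c(a, a, b, a), c(a, a, a, b))

  tet_quad <- function(tet_idx, alpha, P) {
    vids <- mesh$tets[tet_idx, ]
    V <- abs(signed_tet_volumes(mesh$nodes, mesh$tets[tet_idx, , drop = FALSE]))
    pts <- bary %*% mesh$nodes[vids, , drop = FALSE]
    divw <- 3 * alpha
    # int psi_v (div w) dV for each vertex v: psi_v at quad point = bary coord
    g_local <- colSums(bary * (V / 4)) * divw
    mom <- colSums((pts - matrix(mesh$nodes[P, ], 4, 3, byrow = TRUE)) *
                     (V / 4)) * alpha
    list(vids = vids, g = g_local, moment = mom, V = V)
  }

  V1 <- abs(signed_tet_volumes(mesh$nodes, mesh$tets[t1, , drop = FALSE]))
  V2 <- abs(signed_tet_volumes(mesh$nodes, mesh$tets[t2, , drop = FALSE]))
  # normal-flux continuity across the shared face: alpha1 V1 = -alpha2 V2
  # (equal and opposite volumetric outflow); solve the remaining scale from
  # the quadrature moment = unit vector P_i -> P_j
  alpha2 <- 1
  alpha1 <- -alpha2 * V2 / V1
  q1 <- tet_quad(t1, alpha1, pi_)
  q2 <- tet_quad(t2, alpha2, pj)
  mom_raw <- q1$moment + q2$moment
  qhat <- space$moments[k, ]
  scale <- sum(qhat * qhat) / sum(mom_raw * qhat)
  g_dense <- numeric(nrow(mesh$nodes))
  g_dense[q1$vids] <- g_dense[q1$vids] + scale * q1$g
  g_dense[q2$vids] <- g_dense[q2$vids] + scale * q2$g
  nz <- which(abs(g_dense) > 0)
  list(g = list(nodes = nz, values = g_dense[nz]),
       moment = scale * mom_raw,
       g_dense = g_dense)
}
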