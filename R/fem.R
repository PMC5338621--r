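#' Assemble the P1 stiffness matrix
#'
#' Linear (nodal) finite-element stiffness matrix of the conductivity-weighted
#' Laplacian: entries `int sigma grad(psi_i) . grad(psi_j) dV` with
#' piecewise-constant conductivity per tetrahedron. Symmetric positive
#' semidefinite with the constant vector in its null space.
#'
#' @param mesh a [tet_mesh()].
#' @param sigma named per-compartment conductivity vector (S/m), e.g.
#'   [conductivity_model()], or a numeric vector of length `nrow(mesh$tets)`.
#' @return sparse symmetric N x N matrix (`Matrix::dgCMatrix`).
#' @export
assemble_stiffness <- function(mesh, sigma) {
  st <- if (!is.null(names(sigma)) || length(sigma) == 1L) {
    if (length(sigma) == 1L && is.null(names(sigma))) {
      rep_len(as.numeric(sigma), nrow(mesh$tets))
    } else sigma_per_tet(mesh, sigma)
  } else {
    if (length(sigma) != nrow(mesh$tets)) stop("per-tet sigma has wrong length")
    as.numeric(sigma)
  }
  nodes <- mesh$nodes; tets <- mesh$tets
  vols <- signed_tet_volumes(nodes, tets)
  if (any(vols <= 0)) stop("degenerate tetrahedron at index ", which(vols <= 0)[1])
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  d <- nodes[tets[, 4], , drop = FALSE] - p1
  det6 <- 6 * vols
  # rows of the inverse Jacobian = gradients of barycentric coords 2..4
  g2 <- vec_cross(b, d) / det6
  g3 <- vec_cross(d, a) / det6
  g4 <- vec_cross(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)
  w <- st * vols
  nt <- nrow(tets)
  ii <- jj <- integer(16L * nt); xx <- numeric(16L * nt)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * nt + seq_len(nt)
    ii[idx] <- tets[, i]
    jj[idx] <- tets[, j]
    xx[idx] <- w * rowSums(grads[[i]] * grads[[j]])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(nodes), nrow(nodes)))
}

# surface mass and load contributions of an electrode patch:
# returns triplets of int psi_i psi_j dS over the patch and the per-node
# loads int psi_i dS (exact closed forms for P1 on triangles).
patch_surface_terms <- function(mesh, tri_idx) {
  tris <- mesh$boundary_tris[tri_idx, , drop = FALSE]
  ar <- triangle_areas(mesh, tris)
  nt <- nrow(tris)
  ii <- jj <- integer(9L * nt); xx <- numeric(9L * nt)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    idx <- k * nt + seq_len(nt)
    ii[idx] <- tris[, i]
    jj[idx] <- tris[, j]
    xx[idx] <- ar * (1 + (i == j)) / 12
    k <- k + 1L
  }
  load_i <- as.vector(tris)
  load_x <- rep(ar / 3, 3L)
  list(mass = list(i = ii, j = jj, x = xx),
       load = list(i = load_i, x = load_x))
}

# deterministic ground node: boundary node outside all electrode patches,
# maximizing the minimal distance to the electrode centers (smallest index on
# ties)
choose_ground_node <- function(mesh, centers, patch_nodes) {
  bnodes <- sort(unique(as.vector(mesh$boundary_tris)))
  cand <- setdiff(bnodes, patch_nodes)
  if (!length(cand)) stop("no boundary node outside all electrodes; cannot ground")
  p <- mesh$nodes[cand, , drop = FALSE]
  dmin <- rep(Inf, length(cand))
  for (l in seq_len(nrow(centers))) {
    dl <- sqrt(rowSums(sweep(p, 2L, centers[l, ])^2))
    dmin <- pmin(dmin, dl)
  }
  cand[which.max(dmin)]
}

# symmetric grounding: zero row and column, unit diagonal. Valid whenever the
# right-hand side and the electrode coupling vanish at the ground node, which
# the construction guarantees (sources are interior, ground is outside all
# patches).
ground_matrix <- function(A, node) {
  A[node, ] <- 0
  A[, node] <- 0
  A[node, node] <- 1
  A
}

#' Assemble the complete electrode model system
#'
#' Builds the CEM block system matrices: `A` = stiffness plus the
#' impedance-weighted electrode surface mass `sum_l 1/(Z_l A_l) int_{e_l}
#' psi_i psi_j dS`, grounded symmetrically at a deterministic boundary node
#' outside all patches; `B` with `b_{i,l} = 1/(Z_l A_l) int_{e_l} psi_i dS`;
#' and diagonal `C` with `c_{ll} = 1/Z_l`. The electrode boundary term carries
#' the `1/(Z_l A_l)` factor of the weak form, consistent with `c_{ll} = 1/Z_l`.
#'
#' @param mesh a [tet_mesh()].
#' @param sigma per-compartment conductivities (see [assemble_stiffness()]).
#' @param cap an [build_electrode_cap()] result built on `mesh`.
#' @param ground_node optional boundary node index; default chosen by maximal
#'   distance from all electrode centers.
#' @return object of class `cem_system`: `A` (N x N sparse symmetric), `B`
#'   (N x L sparse), `C` (length-L diagonal of 1/Z), `ground_node`, `cap`,
#'   `model = "cem"`.
#' @export
assemble_cem_system <- function(mesh, sigma, cap, ground_node = NULL) {
  if (cap$n_boundary_tris != nrow(mesh$boundary_tris)) {
    stop("electrode cap was built on a different mesh boundary")
  }
  K <- assemble_stiffness(mesh, sigma)
  L <- length(cap$triangles)
  N <- nrow(mesh$nodes)
  zt <- cap$impedance * cap$areas  # effective impedance Z_l * A_l (Ohm m^2)
  mi <- mj <- integer(0); mx <- numeric(0)
  bi <- bl <- integer(0); bx <- numeric(0)
  for (l in seq_len(L)) {
    pt <- patch_surface_terms(mesh, cap$triangles[[l]])
    mi <- c(mi, pt$mass$i); mj <- c(mj, pt$mass$j)
    mx <- c(mx, pt$mass$x / zt[l])
    bi <- c(bi, pt$load$i); bl <- c(bl, rep.int(l, length(pt$load$i)))
    bx <- c(bx, pt$load$x / zt[l])
  }
  A <- K + Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(N, N))
  B <- Matrix::sparseMatrix(i = bi, j = bl, x = bx, dims = c(N, L))
  patch_nodes <- unique(as.vector(mesh$boundary_tris[unlist(cap$triangles), ]))
  if (is.null(ground_node)) {
    ground_node <- choose_ground_node(mesh, cap$centers, patch_nodes)
  }
  if (ground_node %in% patch_nodes) stop("ground node lies under an electrode")
  A <- ground_matrix(A, ground_node)
  structure(
    list(A = Matrix::forceSymmetric(A), B = B, C = 1 / cap$impedance,
         ground_node = ground_node, cap = cap, model = "cem",
         n_nodes = N),
    class = "cem_system"
  )
}

#' Assemble the point electrode model system
#'
#' The PEM uses the plain grounded stiffness matrix and evaluates the
#' potential at one scalp point per electrode. By default each electrode point
#' is snapped to the nearest boundary node, making `B'` a 0/1 selection
#' matrix; `mode = "barycentric"` instead interpolates linearly within the
#' nearest boundary triangle.
#'
#' @param mesh a [tet_mesh()].
#' @param sigma per-compartment conductivities.
#' @param points electrode points: an `electrode_cap` (its centers are used),
#'   a tibble with `x`,`y`,`z`, or an L x 3 matrix.
#' @param ground_node optional boundary node index (use the CEM system's node
#'   to compare models under an identical reference).
#' @param mode `"node"` (snap to nearest boundary node) or `"barycentric"`.
#' @param snap_tol maximal allowed distance (m) from a point to the surface;
#'   default 2 local edge lengths.
#' @return object of class `pem_system`: `A` (grounded stiffness), `B`
#'   (N x L interpolation matrix, unit column sums), `points` (snapped),
#'   `ground_node`, `model = "pem"`.
#' @export
assemble_pem_system <- function(mesh, sigma, points, ground_node = NULL,
                                mode = c("node", "barycentric"),
                                snap_tol = NULL) {
  mode <- match.arg(mode)
  centers <- if (inherits(points, "electrode_cap")) {
    points$centers
  } else if (is.data.frame(points)) {
    as.matrix(points[, c("x", "y", "z")])
  } else as.matrix(points)
  L <- nrow(centers)
  N <- nrow(mesh$nodes)
  K <- assemble_stiffness(mesh, sigma)
  geo <- boundary_geometry(mesh)
  if (is.null(snap_tol)) {
    snap_tol <- 2 * sqrt(max(triangle_areas(mesh)))
  }
  bnodes <- sort(unique(as.vector(mesh$boundary_tris)))
  bp <- mesh$nodes[bnodes, , drop = FALSE]
  bi <- integer(0); bl <- integer(0); bx <- numeric(0)
  snapped <- centers
  for (l in seq_len(L)) {
    if (mode == "node") {
      dl <- sqrt(rowSums(sweep(bp, 2L, centers[l, ])^2))
      k <- which.min(dl)
      if (dl[k] > snap_tol) {
        stop("electrode point ", l, " is ", format(dl[k]),
             " m from the surface (tolerance ", format(snap_tol), ")")
      }
      bi <- c(bi, bnodes[k]); bl <- c(bl, l); bx <- c(bx, 1)
      snapped[l, ] <- bp[k, ]
    } else {
      d2 <- rowSums(sweep(geo$centroids, 2L, centers[l, ])^2)
      t0 <- which.min(d2)
      tri <- mesh$boundary_tris[t0, ]
      p <- mesh$nodes[tri, , drop = FALSE]
      # project onto the triangle plane, then barycentric coordinates
      nrm <- geo$normals[t0, ]
      q <- centers[l, ] - sum((centers[l, ] - p[1, ]) * nrm) * nrm
      if (sqrt(sum((q - centers[l, ])^2)) > snap_tol) {
        stop("electrode point ", l, " too far from the surface")
      }
      v0 <- p[2, ] - p[1, ]; v1 <- p[3, ] - p[1, ]; v2 <- q - p[1, ]
      d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
      d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
      den <- d00 * d11 - d01 * d01
      w2 <- (d11 * d20 - d01 * d21) / den
      w3 <- (d00 * d21 - d01 * d20) / den
      w <- pmax(c(1 - w2 - w3, w2, w3), 0)
      w <- w / sum(w)
      bi <- c(bi, tri); bl <- c(bl, rep.int(l, 3L)); bx <- c(bx, w)
      snapped[l, ] <- q
    }
  }
  B <- Matrix::sparseMatrix(i = bi, j = bl, x = bx, dims = c(N, L))
  if (is.null(ground_node)) {
    ground_node <- choose_ground_node(mesh, centers,
                                      patch_nodes = bi[bx > 0])
  }
  A <- ground_matrix(K, ground_node)
  structure(
    list(A = Matrix::forceSymmetric(A), B = B, points = snapped,
         ground_node = ground_node, model = "pem", n_nodes = N),
    class = "pem_system"
  )
}

#' Solve the forward problem for a given source amplitude vector
#'
#' For a CEM system solves the full block system
#' `[[A, -B], [-B^T, C]] [z; v] = [-G x; 0]` by sparse factorization; for a
#' PEM system solves `A' z = -G x` and evaluates `v = B'^T z`. Electrode
#' voltages are returned unreferenced (apply [average_reference()] for
#' referenced data).
#'
#' @param system a `cem_system` or `pem_system`.
#' @param x source amplitude vector (A m), length M.
#' @param G N x M sparse source matrix (see [build_source_space()]).
#' @param rtol relative residual tolerance for the solve check (default 1e-10).
#' @return object of class `potential_solution` with `z` (nodal potentials,
#'   V), `v` (electrode voltages, V), `model`, `residual`.
#' @export
solve_forward <- function(system, x, G, rtol = 1e-10) {
  if (any(!is.finite(x))) stop("non-finite source amplitudes")
  rhs_z <- as.numeric(-(G %*% x))
  N <- system$n_nodes
  L <- ncol(system$B)
  if (system$model == "cem") {
    M <- rbind(cbind(system$A, -system$B),
               cbind(-Matrix::t(system$B), Matrix::Diagonal(L, system$C)))
    rhs <- c(rhs_z, numeric(L))
    s <- as.numeric(Matrix::solve(M, rhs))
    res <- sqrt(sum((as.numeric(M %*% s) - rhs)^2))
    nr <- sqrt(sum(rhs^2))
    if (nr > 0 && res > max(rtol, 1e-8) * nr) {
      stop("forward solve did not reach tolerance; residual ", format(res / nr))
    }
    out <- list(z = s[seq_len(N)], v = s[N + seq_len(L)], model = "cem",
                residual = if (nr > 0) res / nr else 0)
  } else {
    z <- as.numeric(Matrix::solve(system$A, rhs_z))
    out <- list(z = z, v = as.numeric(Matrix::crossprod(system$B, z)),
                model = "pem", residual = 0)
  }
  class(out) <- "potential_solution"
  out
}

#' Subelectrode potential variation
#'
#' The variation `u - U_l` of the potential beneath electrode `l`, sampled at
#' the contact-triangle centroids of a CEM solution. Because `U_l` is the area
#' mean of `u` over the patch, the area-weighted mean of the returned values
#' is zero.
#'
#' @param solution a CEM [solve_forward()] result.
#' @param mesh the mesh the system was assembled on.
#' @param cap the electrode cap.
#' @param electrode electrode index `l`.
#' @return tibble with one row per contact triangle: `triangle` (boundary
#'   triangle index), `area`, `u` (centroid potential), `variation`
#'   (`u - U_l`).
#' @export
subelectrode_variation <- function(solution, mesh, cap, electrode) {
  if (solution$model != "cem") {
    stop("subelectrode variation is defined for CEM solutions only")
  }
  ix <- cap$triangles[[electrode]]
  tris <- mesh$boundary_tris[ix, , drop = FALSE]
  uc <- (solution$z[tris[, 1]] + solution$z[tris[, 2]] + solution$z[tris[, 3]]) / 3
  tibble::tibble(
    triangle = ix,
    area = triangle_areas(mesh, tris),
    u = uc,
    variation = uc - solution$v[electrode]
  )
}

#' Net current through each electrode
#'
#' Computes the discrete net contact current
#' `1/(Z_l A_l) int_{e_l} (u - U_l) dS` for every electrode directly from the
#' nodal potentials and the patch geometry (independent of the assembled `B`
#' and `C` matrices). For an exact CEM solution this vanishes: the zero net
#' current boundary condition.
#'
#' @inheritParams subelectrode_variation
#' @return numeric vector of length L (A).
#' @export
electrode_net_current <- function(solution, mesh, cap) {
  vapply(seq_along(cap$triangles), function(l) {
    ix <- cap$triangles[[l]]
    tris <- mesh$boundary_tris[ix, , drop = FALSE]
    ar <- triangle_areas(mesh, tris)
    int_u <- sum(ar * (solution$z[tris[, 1]] + solution$z[tris[, 2]] +
                       solution$z[tris[, 3]]) / 3)
    (int_u - cap$areas[l] * solution$v[l]) / (cap$impedance[l] * cap$areas[l])
  }, numeric(1))
}
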