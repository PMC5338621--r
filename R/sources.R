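#' Whitney (Raviart-Thomas) synthetic dipole source space
#'
#' Each interior face `F` shared by two tetrahedra of the source compartment
#' carries one synthetic dipole: with `P_i`, `P_j` the two nodes opposite `F`,
#' the dipole sits at the midpoint `r_w = (r_Pi + r_Pj)/2` with unit moment
#' `q_w = (r_Pj - r_Pi) / |r_Pj - r_Pi|`. The divergence pairing of the
#' face-based vector basis function with the nodal basis yields a two-entry
#' source column: normalizing the basis function so that its volume integral
#' equals the unit moment `q_w` gives `g_{P_i,k} = +1/|r_Pj - r_Pi|` and
#' `g_{P_j,k} = -1/|r_Pj - r_Pi|` (so that the system right-hand side `-G x`
#' is the standard weak dipole load `q . grad(psi)`).
#'
#' Dipoles whose opposite nodes lie within `exclude_surface_layers` node
#' layers of the compartment boundary are excluded (material-discontinuity
#' outlier guard).
#'
#' @param mesh a [tet_mesh()].
#' @param compartment compartment name (default `"brain"`).
#' @param exclude_surface_layers integer >= 0; 1 removes dipoles with an
#'   opposite node on the compartment interface itself.
#' @return object of class `whitney_source_space`: `positions` (M x 3),
#'   `moments` (M x 3, unit), `node_pairs` (M x 2: P_i, P_j), `lengths`
#'   (|r_Pj - r_Pi|, m), `G` (N x M sparse), `compartment`,
#'   `exclude_surface_layers`, `fontanels` (copied from the mesh, if any).
#' @export
build_source_space <- function(mesh, compartment = "brain",
                               exclude_surface_layers = 1L) {
  code <- match(compartment, mesh$compartments)
  if (is.na(code)) stop("unknown compartment: ", compartment)
  in_comp <- mesh$labels == code
  if (!any(in_comp)) stop("compartment `", compartment, "` has no tetrahedra")
  fi <- interior_faces(mesh)
  both <- in_comp[fi$tets[, 1]] & in_comp[fi$tets[, 2]]
  faces <- fi$faces[both, , drop = FALSE]
  opp <- fi$opp[both, , drop = FALSE]
  adj <- fi$tets[both, , drop = FALSE]

  # boundary nodes of the compartment: nodes of compartment tets that also
  # belong to a non-compartment tet or to the domain boundary
  comp_tets <- mesh$tets[in_comp, , drop = FALSE]
  comp_nodes <- unique(as.vector(comp_tets))
  other_nodes <- unique(as.vector(mesh$tets[!in_comp, , drop = FALSE]))
  excl <- intersect(comp_nodes, union(other_nodes,
                                      unique(as.vector(mesh$boundary_tris))))
  if (exclude_surface_layers > 1L) {
    for (k in seq_len(exclude_surface_layers - 1L)) {
      touch <- rowSums(matrix(comp_tets %in% excl, ncol = 4L)) > 0
      excl <- union(excl, unique(as.vector(comp_tets[touch, , drop = FALSE])))
    }
  }
  keep <- if (exclude_surface_layers >= 1L) {
    !(opp[, 1] %in% excl) & !(opp[, 2] %in% excl)
  } else rep(TRUE, nrow(opp))
  opp <- opp[keep, , drop = FALSE]
  adj <- adj[keep, , drop = FALSE]
  faces <- faces[keep, , drop = FALSE]
  if (!nrow(opp)) stop("source space is empty after surface exclusion")

  # deterministic orientation: P_i = smaller node index
  swap <- opp[, 1] > opp[, 2]
  opp[swap, ] <- opp[swap, c(2L, 1L)]
  # distinct faces can share the same opposite node pair (structured meshes);
  # such dipoles are exact duplicates (same position, moment and source
  # column), so keep one per unique pair
  uniq <- !duplicated(paste(opp[, 1], opp[, 2]))
  opp <- opp[uniq, , drop = FALSE]
  adj <- adj[uniq, , drop = FALSE]
  faces <- faces[uniq, , drop = FALSE]
  pi_ <- opp[, 1]; pj <- opp[, 2]
  ri <- mesh$nodes[pi_, , drop = FALSE]
  rj <- mesh$nodes[pj, , drop = FALSE]
  dv <- rj - ri
  d <- sqrt(rowSums(dv^2))
  M <- length(d)
  G <- Matrix::sparseMatrix(i = c(pi_, pj), j = c(seq_len(M), seq_len(M)),
                            x = c(1 / d, -1 / d),
                            dims = c(nrow(mesh$nodes), M))
  structure(
    list(positions = (ri + rj) / 2, moments = dv / d,
         node_pairs = cbind(pi_, pj), lengths = d, G = G,
         faces = faces, adjacent_tets = adj,
         compartment = compartment,
         exclude_surface_layers = as.integer(exclude_surface_layers),
         fontanels = attr(mesh, "fontanels")),
    class = "whitney_source_space"
  )
}

#' @export
print.whitney_source_space <- function(x, ...) {
  cat("<whitney_source_space> ", nrow(x$positions), " dipoles in `",
      x$compartment, "` (", x$exclude_surface_layers,
      " surface layer(s) excluded)\n", sep = "")
  invisible(x)
}

#' Tidy view of a source space
#' @param x a `whitney_source_space`.
#' @param ... unused.
#' @return tibble: one row per dipole with position, unit moment, opposite
#'   node pair and eccentricity (relative norm).
#' @export
tidy.whitney_source_space <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  pos <- x$positions; mom <- x$moments; np <- x$node_pairs
  tibble::tibble(
    source = seq_len(nrow(pos)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    qx = mom[, 1], qy = mom[, 2], qz = mom[, 3],
    node_i = np[, 1], node_j = np[, 2],
    eccentricity = r / max(r)
  )
}

#' Source eccentricities (relative norms)
#'
#' Distance of each dipole from the head barycenter divided by the maximal
#' admissible dipole radius, so that 0.98 is "as superficial as the source
#' space allows".
#'
#' @param space a `whitney_source_space`.
#' @return numeric vector in (0, 1].
#' @export
source_eccentricities <- function(space) {
  r <- sqrt(rowSums(space$positions^2))
  r / max(r)
}

#' Sample dipoles by eccentricity band
#'
#' Uniform random sample without replacement from the dipoles whose relative
#' norm lies within `tolerance` of each requested eccentricity.
#'
#' @param space a `whitney_source_space`.
#' @param eccentricities numeric vector in (0, 1); defaults to the five
#'   levels 0.2, 0.4, 0.6, 0.8, 0.98.
#' @param n_per_level sources per level (default 100).
#' @param tolerance band half-width on the relative norm (default 0.02).
#' @param seed integer seed (the sampling is the only randomness).
#' @return named list mapping each eccentricity (as a name) to an integer
#'   vector of dipole indices.
#' @export
sample_sources_by_eccentricity <- function(space,
                                           eccentricities = c(0.2, 0.4, 0.6, 0.8, 0.98),
                                           n_per_level = 100L,
                                           tolerance = 0.02,
                                           seed = 1L) {
  if (any(eccentricities <= 0 | eccentricities >= 1)) {
    stop("eccentricities must lie in (0, 1)")
  }
  rel <- source_eccentricities(space)
  out <- vector("list", length(eccentricities))
  names(out) <- as.character(eccentricities)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (k in seq_along(eccentricities)) {
    band <- which(abs(rel - eccentricities[k]) <= tolerance)
    if (length(band) < n_per_level) {
      stop("eccentricity band ", eccentricities[k], " holds only ",
           length(band), " dipoles (< ", n_per_level,
           "); enlarge the tolerance or refine the mesh")
    }
    out[[k]] <- sort(sample(band, n_per_level))
  }
  out
}

# set the RNG deterministically and return a restorer
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Locate the two fixed test sources (A and B)
#'
#' Source A is the admissible dipole nearest the C6-like electrode (index 5
#' of the synthetic cap); source B is the admissible dipole beneath the
#' frontal fontanel cone that lies nearest to the ray from the head center
#' through the Fz-like electrode. Both carry the 10 nAm amplitude used by the
#' voltage-pattern experiment.
#'
#' Both sources are chosen with a predominantly radial moment
#' (`|q . r_hat| >= min_radiality`) so that they produce a local voltage
#' extremum at the overlying electrode, matching the role the two sources
#' play in the voltage-pattern comparison; a tangential dipole would peak
#' away from its nearest electrode.
#'
#' @param space a `whitney_source_space` (with fontanel metadata for mode B).
#' @param cap an `electrode_cap` whose labels designate the C6-like and
#'   Fz-like electrodes (see [fibonacci_cap_centers()]).
#' @param mode `"A"` or `"B"`.
#' @param amplitude dipole amplitude in A m (default 1e-8 = 10 nAm).
#' @param min_radiality minimal |cosine| between the dipole moment and the
#'   radial direction (set 0 to disable the orientation preference).
#' @return list with `index` (dipole), `amplitude`, `electrode` (index of the
#'   reference electrode), `mode`.
#' @export
locate_test_sources <- function(space, cap, mode = c("A", "B"),
                                amplitude = 1e-8, min_radiality = 0.5) {
  mode <- match.arg(mode)
  rn <- sqrt(rowSums(space$positions^2))
  radial <- abs(rowSums(space$moments * space$positions / rn))
  admiss <- radial >= min_radiality
  if (!any(admiss)) admiss <- rep(TRUE, length(radial))
  if (mode == "A") {
    el <- which(cap$labels == "C6-like")
    if (!length(el)) el <- 5L
    el <- el[1]
    d2 <- rowSums(sweep(space$positions, 2L, cap$centers[el, ])^2)
    d2[!admiss] <- Inf
    k <- which.min(d2)
  } else {
    if (is.null(space$fontanels) || !length(space$fontanels)) {
      stop("no fontanel cone configured; source B requires the frontal fontanel")
    }
    fo <- space$fontanels[[1]]
    el <- which(cap$labels == "Fz-like")
    if (!length(el)) el <- which.max(cap$centers[, 3])
    el <- el[1]
    dirs <- space$positions / rn
    inside <- (dirs %*% fo$direction)[, 1] >= cos(fo$angular_radius)
    if (!any(inside)) stop("no admissible dipole inside the frontal fontanel cone")
    u <- cap$centers[el, ] / sqrt(sum(cap$centers[el, ]^2))
    proj <- space$positions %*% u
    perp2 <- rn^2 - proj[, 1]^2
    perp2[!inside | !admiss] <- Inf
    if (all(!is.finite(perp2))) { perp2 <- rn^2 - proj[, 1]^2; perp2[!inside] <- Inf }
    k <- which.min(perp2)
  }
  list(index = k, amplitude = amplitude, electrode = el, mode = mode)
}

#' Restrict a source space to a subset of dipoles
#'
#' Used e.g. to remove the data-generating dipole from the reconstruction
#' source space (inverse-crime avoidance).
#'
#' @param space a `whitney_source_space`.
#' @param keep integer or logical index of dipoles to keep.
#' @return a `whitney_source_space` with the selected dipoles (and the
#'   matching columns of `G`).
#' @export
subset_sources <- function(space, keep) {
  out <- space
  out$positions <- space$positions[keep, , drop = FALSE]
  out$moments <- space$moments[keep, , drop = FALSE]
  out$node_pairs <- space$node_pairs[keep, , drop = FALSE]
  out$lengths <- space$lengths[keep]
  out$faces <- space$faces[keep, , drop = FALSE]
  out$adjacent_tets <- space$adjacent_tets[keep, , drop = FALSE]
  out$G <- space$G[, keep, drop = FALSE]
  out
}

#' Mean inter-dipole spacing
#'
#' Mean over all dipoles of the distance to the nearest other dipole; the
#' source-space resolution scale used by the self-consistency bound on
#' localization error.
#'
#' @param space a `whitney_source_space`.
#' @param chunk block size for the pairwise-distance computation.
#' @return scalar (m).
#' @export
mean_dipole_spacing <- function(space, chunk = 512L) {
  P <- space$positions
  M <- nrow(P)
  if (M < 2L) stop("need at least two dipoles")
  nn <- numeric(M)
  sq <- rowSums(P^2)
  for (start in seq(1L, M, by = chunk)) {
    ix <- start:min(start + chunk - 1L, M)
    D2 <- outer(sq[ix], sq, "+") - 2 * P[ix, , drop = FALSE] %*% t(P)
    D2[cbind(seq_along(ix), ix)] <- Inf
    nn[ix] <- sqrt(pmax(0, apply(D2, 1L, min)))
  }
  mean(nn)
}
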