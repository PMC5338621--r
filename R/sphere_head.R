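#' Compartment conductivity models
#'
#' Isotropic per-compartment conductivities (S/m) for the three neonatal head
#' variants used throughout the experiments. Model I is the open-skull
#' reference (fontanel/suture openings at 0.3 S/m), model II closes the skull
#' (fontanel tissue set to bone, 0.04 S/m) and model III raises the bone
#' conductivity to 0.1 S/m.
#'
#' @param model `"I"`, `"II"` or `"III"`.
#' @return named numeric vector with entries `brain`, `csf`, `skull`,
#'   `fontanel`, `scalp`; the model tag is kept in attribute `"model"`.
#' @export
#' @examples
#' conductivity_model("I")
conductivity_model <- function(model = c("I", "II", "III")) {
  model <- match.arg(model)
  sig <- switch(model,
    I   = c(brain = 0.33, csf = 1.79, skull = 0.04, fontanel = 0.30, scalp = 0.33),
    II  = c(brain = 0.33, csf = 1.79, skull = 0.04, fontanel = 0.04, scalp = 0.33),
    III = c(brain = 0.33, csf = 1.79, skull = 0.10, fontanel = 0.30, scalp = 0.33)
  )
  structure(sig, model = model)
}

#' Per-tetrahedron conductivity vector
#' @param mesh a [tet_mesh()].
#' @param sigma named conductivity vector (per compartment name), e.g. from
#'   [conductivity_model()].
#' @return numeric vector of length `nrow(mesh$tets)` (S/m).
#' @export
sigma_per_tet <- function(mesh, sigma) {
  nm <- mesh$compartments[mesh$labels]
  miss <- setdiff(unique(nm), names(sigma))
  if (length(miss)) stop("no conductivity given for compartment(s): ",
                         paste(miss, collapse = ", "))
  s <- unname(sigma[nm])
  if (any(!is.finite(s)) || any(s <= 0)) stop("conductivities must be finite and positive")
  s
}

#' Fontanel / suture opening specification
#'
#' A skull opening is modelled as a cone from the head center: skull-labelled
#' tetrahedra whose centroid direction lies within `angular_radius` of
#' `direction` are relabelled to the fontanel compartment.
#'
#' @param direction length-3 numeric, cone axis (need not be unit length).
#' @param angular_radius cone half-angle in radians, in (0, pi/2).
#' @return list with normalized `direction` and `angular_radius`.
#' @export
fontanel <- function(direction, angular_radius) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L || sum(direction^2) == 0)
    stop("`direction` must be a nonzero length-3 vector")
  if (!(angular_radius > 0 && angular_radius < pi / 2))
    stop("`angular_radius` must lie in (0, pi/2)")
  list(direction = direction / sqrt(sum(direction^2)),
       angular_radius = angular_radius)
}

#' Default neonatal fontanel layout
#'
#' One large anterior opening at the vertex (where the frontal fontanel meets
#' the Fz-like electrode in the synthetic cap) and two smaller lateral ones.
#'
#' @return list of [fontanel()] specifications; the first entry is the
#'   anterior (frontal) fontanel.
#' @export
default_fontanels <- function() {
  list(
    anterior = fontanel(c(0, 0.2, 1), 0.45),
    lateral_left = fontanel(c(-1, 0, 0.25), 0.2),
    lateral_right = fontanel(c(1, 0, 0.25), 0.2)
  )
}

# Smooth cube-surface-to-sphere map for points with sup-norm 1.
cube_to_sphere <- function(p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
        y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
        z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)))
}

#' Synthetic layered-sphere neonatal head
#'
#' Builds a quasi-uniform tetrahedral mesh of a ball with four concentric
#' compartments (brain, CSF, skull, scalp) and optional fontanel/suture
#' openings in the skull. The mesh is a structured spherified-cube
#' tetrahedralization: a `2n x 2n x 2n` cube grid is split into six
#' tetrahedra per cell and mapped radially so that the lattice shells land
#' exactly on the requested compartment interface radii. Strictly interior
#' brain nodes receive a small seeded jitter so that source positions fill
#' the brain volume quasi-continuously; the construction is fully
#' deterministic for a fixed seed and parameters.
#'
#' @param radii increasing numeric vector of 4 shell radii (m):
#'   brain, CSF (outer), skull (outer), scalp (outer). Defaults are sized for
#'   a neonate (50 mm scalp radius, 4 mm CSF/skull/scalp shells).
#' @param fontanels list of [fontanel()] specifications (possibly empty).
#' @param target_edge_length requested edge length (m); sets the grid
#'   subdivision `n = max(4, round(radii[4] / target_edge_length))`.
#' @param n optional explicit subdivision count, overriding
#'   `target_edge_length`; the outermost three lattice shells are pinned to
#'   the CSF/skull/scalp interfaces, so `n >= 4` is required.
#' @param jitter relative amplitude (fraction of the local radial spacing)
#'   of the seeded perturbation applied to strictly interior brain nodes;
#'   0 disables it.
#' @param seed integer seed for the interior-node jitter; the mesh is fully
#'   deterministic for a fixed seed and parameters.
#' @return a [tet_mesh()] with compartments
#'   `c("brain","csf","skull","fontanel","scalp")` and attributes
#'   `radii`, `fontanels`, `n`, `seed`.
#' @export
build_sphere_head <- function(radii = c(0.038, 0.042, 0.046, 0.050),
                              fontanels = default_fontanels(),
                              target_edge_length = 0.005,
                              n = NULL,
                              jitter = 0.25,
                              seed = 1L) {
  radii <- as.numeric(radii)
  if (length(radii) != 4L || any(diff(radii) <= 0) || radii[1] <= 0)
    stop("`radii` must be 4 strictly increasing positive values")
  if (is.null(n)) n <- max(4L, as.integer(round(radii[4] / target_edge_length)))
  n <- as.integer(n)
  if (n < 4L) stop("`n` must be at least 4 (three outer shells + brain)")
  # thinnest shell must be resolvable by one lattice layer without the
  # radial map collapsing: brain interior layers must stay positive
  inner_step <- radii[1] / (n - 3L)
  if (inner_step <= 0) stop("target edge length too coarse to resolve the shells")

  # lattice shell radii: levels 0..n-3 uniform in [0, r_brain], then the
  # three interfaces
  levels_r <- c(seq(0, radii[1], length.out = n - 2L), radii[2], radii[3], radii[4])

  g <- -n:n
  m <- 2L * n + 1L
  nodes_cube <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  storage.mode(nodes_cube) <- "double"
  sup <- pmax(abs(nodes_cube[, 1]), abs(nodes_cube[, 2]), abs(nodes_cube[, 3]))
  dirs <- nodes_cube
  pos <- sup > 0
  dirs[pos, ] <- cube_to_sphere(nodes_cube[pos, , drop = FALSE] / sup[pos])
  r <- levels_r[sup + 1L]
  nodes <- dirs
  nodes[pos, ] <- dirs[pos, , drop = FALSE] * r[pos]
  nodes[!pos, ] <- 0

  # Seeded jitter of strictly interior brain nodes (lattice levels
  # 1 .. n-4): breaks the radial quantization of the structured lattice so
  # that dipole radii fill the brain volume quasi-continuously, without
  # touching the compartment interfaces. Displacement is bounded by
  # `jitter` times the local radial spacing, far below the inversion limit.
  if (jitter > 0 && n >= 5L) {
    interior <- which(sup >= 1L & sup <= n - 4L)
    if (length(interior)) {
      restore <- local_rng(seed)
      on.exit(restore(), add = TRUE)
      u <- matrix(stats::runif(3L * length(interior), -1, 1),
                  ncol = 3L)
      nodes[interior, ] <- nodes[interior, , drop = FALSE] +
        u * (jitter * inner_step)
    }
  }

  node_id <- function(i, j, k) ((k + n) * m + (j + n)) * m + (i + n) + 1L
  # hex cells with lower corner (i,j,k), i,j,k in -n..(n-1)
  cc <- as.matrix(expand.grid(i = -n:(n - 1L), j = -n:(n - 1L), k = -n:(n - 1L)))
  v0 <- node_id(cc[, 1],      cc[, 2],      cc[, 3])
  v1 <- node_id(cc[, 1] + 1L, cc[, 2],      cc[, 3])
  v2 <- node_id(cc[, 1] + 1L, cc[, 2] + 1L, cc[, 3])
  v3 <- node_id(cc[, 1],      cc[, 2] + 1L, cc[, 3])
  v4 <- node_id(cc[, 1],      cc[, 2],      cc[, 3] + 1L)
  v5 <- node_id(cc[, 1] + 1L, cc[, 2],      cc[, 3] + 1L)
  v6 <- node_id(cc[, 1] + 1L, cc[, 2] + 1L, cc[, 3] + 1L)
  v7 <- node_id(cc[, 1],      cc[, 2] + 1L, cc[, 3] + 1L)
  # conforming 6-tet split around the main diagonal v0-v6
  tets <- rbind(cbind(v0, v1, v2, v6),
                cbind(v0, v2, v3, v6),
                cbind(v0, v3, v7, v6),
                cbind(v0, v7, v4, v6),
                cbind(v0, v4, v5, v6),
                cbind(v0, v5, v1, v6))

  # drop unused nodes later; first compute labels from mapped centroids
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
          nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  rc <- sqrt(rowSums(cen^2))
  lab <- findInterval(rc, radii) + 1L          # 1 brain, 2 csf, 3 skull, 4 scalp-ish
  lab[lab == 4L] <- 5L                          # scalp code is 5 (4 = fontanel)
  keep <- lab <= 5L & rc < radii[4]             # outside-ball cells dropped
  # cells whose centroid is outside the scalp radius belong to the cube
  # corners; drop them
  tets <- tets[keep, , drop = FALSE]
  lab <- lab[keep]
  cen <- cen[keep, , drop = FALSE]
  rc <- rc[keep]

  # fontanel relabelling: skull tets inside any cone
  if (length(fontanels)) {
    dirn <- cen / rc
    for (f in fontanels) {
      ca <- cos(f$angular_radius)
      inside <- lab == 3L & (dirn %*% f$direction)[, 1] >= ca
      lab[inside] <- 4L
    }
  }

  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  mesh <- tet_mesh(nodes[used, , drop = FALSE],
                   matrix(remap[tets], ncol = 4L),
                   lab)
  attr(mesh, "radii") <- radii
  attr(mesh, "fontanels") <- fontanels
  attr(mesh, "n") <- n
  attr(mesh, "seed") <- as.integer(seed)
  mesh
}
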