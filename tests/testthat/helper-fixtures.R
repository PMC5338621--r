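# Shared fixtures, memoised so expensive meshes are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

fix_head <- function(n, fontanels = default_fontanels(), seed = 1L) {
  fixture(sprintf("head_%d_%d_%d", n, length(fontanels), seed), function() {
    build_sphere_head(n = n, fontanels = fontanels, seed = seed)
  })
}

fix_space <- function(n, ...) {
  fixture(sprintf("space_%d", n), function() build_source_space(fix_head(n, ...)))
}

fix_cap <- function(n, n_electrodes = 74L, impedance = 2000) {
  fixture(sprintf("cap_%d_%d", n, n_electrodes), function() {
    build_electrode_cap(fix_head(n),
                        fibonacci_cap_centers(n_electrodes, radius = 0.05),
                        impedance = impedance)
  })
}

# single regular-ish reference tetrahedron
unit_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tet_mesh(nodes, matrix(1:4, nrow = 1), labels = 1L,
           compartments = "brain")
}

# two tetrahedra sharing the face x = 0.5-plane-ish; opposite nodes at
# (0,0,0) and (1,0,0) as in the Whitney-dipole reference example
two_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0),        # P_i
                 c(1, 0, 0),        # P_j
                 c(0.5, -0.5, -0.5),
                 c(0.5, 0.5, -0.3),
                 c(0.5, 0, 0.6))
  tets <- rbind(c(1L, 3L, 4L, 5L),
                c(2L, 3L, 4L, 5L))
  tet_mesh(nodes, tets, labels = c(1L, 1L), compartments = "brain")
}
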