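test_that("the reference two-tet dipole matches the closed forms", {
  m <- two_tet_mesh()
  sp <- build_source_space(m, compartment = "brain",
                           exclude_surface_layers = 0L)
  expect_equal(nrow(sp$positions), 1L)
  expect_equal(sp$positions[1, ], c(0.5, 0, 0))
  expect_equal(sp$moments[1, ], c(1, 0, 0))     # unit vector P_i -> P_j
  expect_equal(sp$lengths[1], 1)
  g <- sp$G[, 1]
  # moment-normalized source column: +1/d at P_i, -1/d at P_j, so that the
  # right-hand side -G x is the weak dipole load q . grad(psi)
  expect_equal(g[1], 1)
  expect_equal(g[2], -1)
  expect_equal(sum(abs(g) > 0), 2L)
  expect_equal(sum(g), 0)
})

test_that("every source column agrees with independent volume quadrature", {
  mesh <- fix_head(6)
  space <- fix_space(6)
  ks <- seq(1L, ncol(space$G), length.out = 20L)
  for (k in ks) {
    qq <- whitney_quadrature_column(mesh, space, k)
    gk <- as.numeric(space$G[, k])
    expect_lt(max(abs(qq$g_dense - gk)), 1e-10 * max(abs(gk)))
    expect_lt(max(abs(qq$moment - space$moments[k, ])), 1e-8)
  }
  # unit moments, zero column sums across the whole space
  expect_equal(sqrt(rowSums(space$moments^2)),
               rep(1, nrow(space$moments)), tolerance = 1e-12)
  expect_lt(max(abs(Matrix::colSums(space$G))), 1e-12)
  nnz <- diff(space$G@p)
  expect_true(all(nnz == 2L))
})

test_that("surface exclusion removes exactly the interface-touching dipoles", {
  mesh <- fix_head(6)
  sp0 <- build_source_space(mesh, exclude_surface_layers = 0L)
  sp1 <- build_source_space(mesh, exclude_surface_layers = 1L)
  # explicit interface-node list: brain nodes shared with non-brain tets
  code <- match("brain", mesh$compartments)
  bn <- unique(as.vector(mesh$tets[mesh$labels == code, ]))
  on <- unique(as.vector(mesh$tets[mesh$labels != code, ]))
  interface <- intersect(bn, on)
  touches <- sp0$node_pairs[, 1] %in% interface |
    sp0$node_pairs[, 2] %in% interface
  key0 <- paste(sp0$node_pairs[, 1], sp0$node_pairs[, 2])
  key1 <- paste(sp1$node_pairs[, 1], sp1$node_pairs[, 2])
  expect_setequal(key1, key0[!touches])
})

test_that("eccentricity sampling is banded, sized and reproducible", {
  space <- fix_space(8)
  s1 <- sample_sources_by_eccentricity(space, c(0.6, 0.98), 30L,
                                       tolerance = 0.02, seed = 11L)
  s2 <- sample_sources_by_eccentricity(space, c(0.6, 0.98), 30L,
                                       tolerance = 0.02, seed = 11L)
  expect_identical(s1, s2)
  expect_equal(lengths(s1), c("0.6" = 30L, "0.98" = 30L))
  rel <- source_eccentricities(space)
  expect_true(all(abs(rel[s1[["0.6"]]] - 0.6) <= 0.02))
  expect_true(all(abs(rel[s1[["0.98"]]] - 0.98) <= 0.02))
  expect_error(sample_sources_by_eccentricity(space, 0.05, 100L),
               "holds only")
  expect_error(sample_sources_by_eccentricity(space, 1.2, 1L), "in \\(0, 1\\)")
})

test_that("test sources A and B sit where the experiment needs them", {
  mesh <- fix_head(8)
  space <- fix_space(8)
  cap <- fix_cap(8)
  A <- locate_test_sources(space, cap, "A")
  expect_equal(A$amplitude, 1e-8)
  expect_equal(A$electrode, 5L)
  # A is the argmin over radially-aligned admissible dipoles
  rn <- sqrt(rowSums(space$positions^2))
  radial <- abs(rowSums(space$moments * space$positions / rn)) >= 0.5
  d2 <- rowSums(sweep(space$positions, 2L, cap$centers[5L, ])^2)
  expect_equal(A$index, which(radial)[which.min(d2[radial])])
  B <- locate_test_sources(space, cap, "B")
  fo <- space$fontanels[[1]]
  dirB <- space$positions[B$index, ] / sqrt(sum(space$positions[B$index, ]^2))
  expect_gte(sum(dirB * fo$direction), cos(fo$angular_radius))
  # without fontanel metadata mode B is a configuration error
  sp2 <- space; sp2$fontanels <- NULL
  expect_error(locate_test_sources(sp2, cap, "B"), "fontanel")
})

test_that("subsetting keeps positions, moments and columns aligned", {
  space <- fix_space(6)
  keep <- c(3L, 10L, 50L)
  sub <- subset_sources(space, keep)
  expect_equal(sub$positions, space$positions[keep, ])
  expect_equal(sub$moments, space$moments[keep, ])
  expect_equal(as.matrix(sub$G), as.matrix(space$G[, keep]))
  expect_gt(mean_dipole_spacing(space), 0)
})
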