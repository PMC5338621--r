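test_that("stiffness matrix matches the hand-computed reference tetrahedron", {
  m <- unit_tet_mesh()
  K <- as.matrix(assemble_stiffness(m, c(brain = 1)))
  # gradients of the P1 basis on the unit tet: (-1,-1,-1) and the unit axes;
  # K_ij = sigma V grad_i . grad_j with V = 1/6
  K_ref <- rbind(c(3, -1, -1, -1),
                 c(-1, 1,  0,  0),
                 c(-1, 0,  1,  0),
                 c(-1, 0,  0,  1)) / 6
  expect_equal(K, K_ref, ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("stiffness has constants in its null space and is linear in sigma", {
  m <- fix_head(5)
  K <- assemble_stiffness(m, conductivity_model("I"))
  ones <- rep(1, nrow(m$nodes))
  expect_lt(max(abs(K %*% ones)), 1e-12 * max(abs(K)))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(K)))
  K2 <- assemble_stiffness(m, 2 * conductivity_model("I"))
  expect_equal(as.matrix(2 * K), as.matrix(K2), tolerance = 1e-14)
})

test_that("CEM assembly satisfies the partition-of-unity and symmetry identities", {
  mesh <- fix_head(6)
  cap <- build_electrode_cap(mesh, fibonacci_cap_centers(16, radius = 0.05),
                             impedance = c(rep(500, 8), rep(3000, 8)))
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  # column sum of B equals 1/Z_l = c_ll (sum_i psi_i = 1 on the patch)
  expect_equal(Matrix::colSums(sys$B), 1 / cap$impedance, tolerance = 1e-12)
  expect_equal(sys$C, 1 / cap$impedance)
  # A symmetric; full block matrix symmetric
  expect_lt(max(abs(sys$A - Matrix::t(sys$A))), 1e-12 * max(abs(sys$A)))
  BM <- rbind(cbind(sys$A, -sys$B),
              cbind(-Matrix::t(sys$B), Matrix::Diagonal(16, sys$C)))
  expect_lt(max(abs(BM - Matrix::t(BM))), 1e-12 * max(abs(BM)))
  # B rows live only on nodes touching electrode triangles
  patch_nodes <- unique(as.vector(mesh$boundary_tris[unlist(cap$triangles), ]))
  expect_true(all(which(Matrix::rowSums(abs(sys$B)) > 0) %in% patch_nodes))
  # ground node outside all patches
  expect_false(sys$ground_node %in% patch_nodes)
})

test_that("infinite impedance reduces the CEM matrix to the grounded stiffness", {
  mesh <- fix_head(5)
  cap <- build_electrode_cap(mesh, fibonacci_cap_centers(8, radius = 0.05),
                             impedance = 1e15)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  K <- assemble_stiffness(mesh, conductivity_model("I"))
  Kg <- cemfwd:::ground_matrix(K, sys$ground_node)
  expect_lt(max(abs(sys$A - Kg)), 1e-12 * max(abs(K)))
  expect_lt(max(abs(sys$B)), 1e-12)
  expect_true(all(sys$C <= 1e-15))
})

test_that("PEM interpolation columns sum to one in both modes", {
  mesh <- fix_head(5)
  cen <- fibonacci_cap_centers(8, radius = 0.05)
  p1 <- assemble_pem_system(mesh, conductivity_model("I"), cen)
  expect_equal(unname(Matrix::colSums(p1$B)), rep(1, 8))
  expect_true(all(p1$B@x %in% c(0, 1)))  # snap mode: selection matrix
  p2 <- assemble_pem_system(mesh, conductivity_model("I"), cen,
                            mode = "barycentric")
  expect_equal(unname(Matrix::colSums(p2$B)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(p2$B@x >= 0))
  # snap error for a point far from the surface
  expect_error(assemble_pem_system(mesh, conductivity_model("I"),
                                   rbind(c(0.2, 0, 0)), snap_tol = 1e-3),
               "from the surface")
})

test_that("forward solves are linear and satisfy the electrode identities", {
  mesh <- fix_head(6)
  cap <- fix_cap(6, n_electrodes = 16L)
  space <- fix_space(6)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  M <- ncol(space$G)
  x1 <- numeric(M); x1[10L] <- 1e-8
  x2 <- numeric(M); x2[200L] <- -2e-8
  s0 <- solve_forward(sys, numeric(M), space$G)
  expect_equal(s0$z, numeric(nrow(mesh$nodes)))
  expect_equal(s0$v, numeric(16L))
  s1 <- solve_forward(sys, x1, space$G)
  s2 <- solve_forward(sys, x2, space$G)
  s12 <- solve_forward(sys, x1 + x2, space$G)
  expect_equal(s12$z, s1$z + s2$z, tolerance = 1e-9)
  expect_equal(s12$v, s1$v + s2$v, tolerance = 1e-9)
  # U_l is the area mean of u over the patch <=> zero net contact current,
  # computed from the patch geometry, independent of B and C
  inet <- electrode_net_current(s1, mesh, cap)
  iscale <- max(abs(Matrix::crossprod(sys$B, s1$z)))
  expect_lt(max(abs(inet)), 1e-10 * iscale)
  # PEM voltages are the nodal potentials at the electrode nodes
  pem <- assemble_pem_system(mesh, conductivity_model("I"), cap,
                             ground_node = sys$ground_node)
  sp <- solve_forward(pem, x1, space$G)
  nodes_of <- apply(as.matrix(pem$B), 2L, which.max)
  expect_equal(sp$v, sp$z[nodes_of], tolerance = 1e-12)
})

test_that("subelectrode variation has zero area-weighted mean and needs a CEM solution", {
  mesh <- fix_head(6)
  cap <- fix_cap(6, n_electrodes = 16L)
  space <- fix_space(6)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  x <- numeric(ncol(space$G)); x[5L] <- 1e-8
  sol <- solve_forward(sys, x, space$G)
  for (l in c(1L, 9L)) {
    sv <- subelectrode_variation(sol, mesh, cap, l)
    expect_lt(abs(sum(sv$area * sv$variation)) / sum(sv$area),
              1e-10 * max(abs(sol$v)))
  }
  pem <- assemble_pem_system(mesh, conductivity_model("I"), cap)
  solp <- solve_forward(pem, x, space$G)
  expect_error(subelectrode_variation(solp, mesh, cap, 1L), "CEM")
})

test_that("a cap from a different mesh is rejected at assembly", {
  mesh <- fix_head(6)
  other <- fix_head(5)
  cap_other <- build_electrode_cap(other, fibonacci_cap_centers(8, radius = 0.05))
  expect_error(assemble_cem_system(mesh, conductivity_model("I"), cap_other),
               "different mesh")
})
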