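test_that("the three lead-field routes agree and are average-referenced", {
  mesh <- fix_head(6)
  cap <- fix_cap(6, n_electrodes = 16L)
  space <- fix_space(6)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  cols <- seq(1L, ncol(space$G), length.out = 12L)
  Gs <- space$G[, cols]
  lf1 <- compute_lead_field(sys, Gs, method = "schur")
  lf2 <- compute_lead_field(sys, Gs, method = "block")
  lf3 <- compute_lead_field(sys, Gs, method = "transfer")
  sc <- max(abs(lf1$matrix))
  expect_lt(max(abs(lf1$matrix - lf2$matrix)), 1e-8 * sc)
  expect_lt(max(abs(lf1$matrix - lf3$matrix)), 1e-8 * sc)
  expect_lt(max(abs(colSums(lf1$matrix))), 1e-10 * sc)
  # lead-field columns match direct forward solves
  x <- numeric(ncol(Gs)); x[3L] <- 1
  sol <- solve_forward(sys, x, Gs)
  expect_equal(average_reference(sol$v), lf1$matrix[, 3L], tolerance = 1e-8)
})

test_that("the average reference operator is the centering matrix", {
  R <- reference_matrix(7L)
  expect_equal(R %*% R, R, tolerance = 1e-12)
  y <- rnorm(7)
  expect_equal(as.numeric(R %*% y), average_reference(y), tolerance = 1e-12)
  Y <- matrix(rnorm(21), 7)
  expect_equal(unname(R %*% Y), average_reference(Y), tolerance = 1e-12)
})

test_that("lead fields round-trip through the text container", {
  mesh <- fix_head(5)
  cap <- build_electrode_cap(mesh, fibonacci_cap_centers(8, radius = 0.05))
  space <- fix_space(5)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  lf <- compute_lead_field(sys, space$G[, 1:5])
  path <- withr::local_tempfile(fileext = ".txt")
  write_lead_field(lf, path)
  back <- read_lead_field(path)
  expect_identical(back$matrix, lf$matrix)
  expect_identical(back$model, "cem")
  expect_equal(back$impedance, lf$impedance)
})

test_that("tidy() exposes the gain table", {
  mesh <- fix_head(5)
  cap <- build_electrode_cap(mesh, fibonacci_cap_centers(8, radius = 0.05))
  space <- fix_space(5)
  lf <- compute_lead_field(assemble_pem_system(mesh, conductivity_model("I"), cap),
                           space$G[, 1:3])
  td <- tidy(lf)
  expect_equal(nrow(td), 24L)
  expect_equal(td$gain[td$electrode == 2 & td$source == 3], lf$matrix[2, 3])
})

test_that("CEM voltages approach the point electrode model as patches shrink", {
  # single-triangle patches at fixed effective impedance vs barycentric PEM
  # at the same points: topography difference falls under refinement
  rds <- vapply(c(5L, 7L), function(nn) {
    mesh <- fix_head(nn)
    cen <- fibonacci_cap_centers(16, radius = 0.05)
    cap1 <- single_triangle_cap(mesh, cen, z_tilde = 0.15)
    cem <- assemble_cem_system(mesh, conductivity_model("I"), cap1)
    pem <- assemble_pem_system(mesh, conductivity_model("I"), cap1$centers,
                               ground_node = cem$ground_node,
                               mode = "barycentric")
    space <- build_source_space(mesh)
    k <- which.min(abs(source_eccentricities(space) - 0.4))
    Gk <- space$G[, k, drop = FALSE]
    rdm(compute_lead_field(pem, Gk)$matrix[, 1],
        compute_lead_field(cem, Gk, method = "schur")$matrix[, 1])
  }, numeric(1))
  expect_lt(rds[2], rds[1])
  expect_lt(rds[2], 1)
})
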