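test_that("the 74-electrode cap forms disjoint patches with consistent areas", {
  mesh <- fix_head(8)
  cap <- fix_cap(8)
  expect_length(cap$triangles, 74L)
  expect_true(all(lengths(cap$triangles) >= 1L))
  all_tris <- unlist(cap$triangles)
  expect_equal(anyDuplicated(all_tris), 0L)
  # A_l equals the sum of its triangles' areas
  areas <- triangle_areas(mesh)
  a_sum <- vapply(cap$triangles, function(ix) sum(areas[ix]), numeric(1))
  expect_equal(cap$areas, a_sum, tolerance = 1e-12)
  # mean contact area approaches the 10 mm disc area
  expect_lt(abs(mean(cap$areas) / (pi * 0.005^2) - 1), 0.05)
  # every captured triangle centroid lies within the capture distance
  geo <- boundary_geometry(mesh)
  for (l in c(1L, 5L, 37L, 74L)) {
    d <- sqrt(rowSums(sweep(geo$centroids[cap$triangles[[l]], , drop = FALSE],
                            2L, cap$centers[l, ])^2))
    expect_true(all(d <= cap$contact_radius + 1e-12))
  }
})

test_that("degenerate cap requests fail loudly", {
  mesh <- fix_head(5)
  cen <- fibonacci_cap_centers(4, radius = 0.05)
  expect_error(build_electrode_cap(mesh, cen, contact_radius = 1e-5),
               "empty electrode")
  dup <- cen[c(1, 1), ]
  expect_error(build_electrode_cap(mesh, dup), "overlapping")
  expect_error(build_electrode_cap(mesh, cen, impedance = -1), "positive")
})

test_that("cap JSON round trip preserves centers and impedances", {
  cap <- fix_cap(8)
  path <- withr::local_tempfile(fileext = ".json")
  write_electrode_cap(cap, path)
  back <- read_electrode_cap(path)
  expect_equal(nrow(back), 74L)
  expect_equal(as.matrix(back[, c("x", "y", "z")]), cap$centers,
               ignore_attr = TRUE)
  expect_equal(attr(back, "contact_radius"), cap$contact_radius)
  expect_equal(attr(back, "impedance"), cap$impedance)
})

test_that("spiral layout nominates the Fz-like and C6-like electrodes", {
  cen <- fibonacci_cap_centers(74)
  expect_equal(sum(cen$label == "Fz-like"), 1L)
  expect_equal(which(cen$label == "Fz-like"), which.max(cen$z))
  expect_equal(cen$label[5], "C6-like")
  expect_equal(sqrt(rowSums(as.matrix(cen[, c("x", "y", "z")])^2)),
               rep(0.05, 74))
})

test_that("tidy view and impedance replacement behave", {
  cap <- fix_cap(8)
  td <- tidy(cap)
  expect_equal(nrow(td), 74L)
  expect_true(all(td$n_triangles == lengths(cap$triangles)))
  cap2 <- set_impedance(cap, 0.1)
  expect_equal(cap2$impedance, rep(0.1, 74))
  expect_error(set_impedance(cap, 0), "positive")
})
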