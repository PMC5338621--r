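# reduced desk configuration shared by the experiment tests (memoised)
exp_cfg <- function() experiment_config(n = 7L, n_per_level = 8L,
                                        tolerance = 0.06,
                                        impedances = impedance_sweep(n = 5L))

exp_setup <- function() fixture("exp_setup7", function() {
  cemfwd:::experiment_setup(exp_cfg())
})

test_that("identical configurations reproduce bitwise-identical tables", {
  cfg <- exp_cfg()
  a <- run_comparison_sweep(cfg, 1L, setup = exp_setup())
  b <- run_comparison_sweep(cfg, 1L, setup = exp_setup())
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(!is.null(attr(a, "manifest")$config_hash))
  expect_identical(attr(a, "manifest")$config_hash,
                   attr(b, "manifest")$config_hash)
})

test_that("identical head models on both sides yield zero RDM and MAG", {
  # with no fontanel openings, conductivity models I and II coincide, so
  # comparison 2 (open vs closed skull) degenerates to identical systems
  cfg <- experiment_config(n = 6L, n_per_level = 5L, tolerance = 0.06,
                           fontanels = list(),
                           impedances = c(10, 2000))
  sw <- run_comparison_sweep(cfg, 2L)
  expect_lt(max(abs(sw$rdm)), 1e-8)
  expect_lt(max(abs(sw$mag)), 1e-8)
})

test_that("the sweep records carry both measures over all impedances and sources", {
  sw <- run_comparison_sweep(exp_cfg(), 1L, setup = exp_setup())
  expect_equal(nrow(sw), 5L * 5L * 8L)  # impedances x levels x per-level
  expect_true(all(is.finite(sw$rdm)) && all(is.finite(sw$mag)))
  expect_true(all(sw$rdm >= 0 & sw$rdm <= 200))
  sm <- summarize_comparisons(sw)
  expect_setequal(unique(sm$measure), c("rdm", "mag"))
  expect_equal(nrow(sm), 10L)
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("eccentricity analysis returns finite localization measures", {
  cfg <- exp_cfg()
  cfg$eccentricities <- c(0.6, 0.9)
  cfg$n_per_level <- 4L
  ecc <- run_eccentricity_analysis(cfg, setup = local({
    s <- exp_setup()
    s$samples <- sample_sources_by_eccentricity(s$space, cfg$eccentricities,
                                                cfg$n_per_level, cfg$tolerance,
                                                seed = cfg$seed)
    s
  }))
  expect_equal(nrow(ecc), 8L)
  expect_true(all(is.finite(ecc$pd)) && all(ecc$pd >= 0))
  expect_true(all(ecc$ad >= 0 & ecc$ad <= 180))
  expect_equal(ecc$depth_bias, -ecc$nd)
  expect_s3_class(autoplot(ecc), "ggplot")
})

test_that("the A/B source experiment reproduces the shunting signatures", {
  ab <- run_source_ab(exp_cfg(), setup = exp_setup())
  v <- ab$voltages
  # referenced voltage patterns sum to zero
  sums <- tapply(v$voltage, paste(v$source, v$combo), sum)
  expect_lt(max(abs(sums)), 1e-10 * max(abs(v$voltage)))
  # source A peaks at its nearest (C6-like) electrode in all combinations
  peaks <- vapply(split(v[v$source == "A", ], v$combo[v$source == "A"]),
                  function(d) d$electrode[which.max(abs(d$voltage))],
                  integer(1))
  expect_true(all(peaks == ab$sources$A$electrode))
  # variation at 0.1 Ohm is far below its 2 kOhm counterpart
  va <- ab$variation
  for (s in c("A", "B")) {
    lo <- max(va$max_abs_variation[va$source == s & grepl("0.1 Ohm", va$combo)])
    hi <- max(va$max_abs_variation[va$source == s & grepl("2.0 kOhm", va$combo) &
                                     grepl("\\(I\\)", va$combo)])
    expect_lt(lo, 0.1 * hi)
  }
  expect_s3_class(autoplot(ab), "ggplot")
})

test_that("records round-trip through the manifest text format", {
  sw <- run_comparison_sweep(exp_cfg(), 1L, setup = exp_setup())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(sw, path)
  back <- read_records(path)
  for (cl in names(sw)) expect_equal(back[[cl]], sw[[cl]], tolerance = 1e-12)
  expect_equal(attr(back, "manifest")$config_hash,
               attr(sw, "manifest")$config_hash)
})

test_that("a corrupted coupling matrix breaks the zero-net-current identity", {
  mesh <- fix_head(6)
  cap <- fix_cap(6, n_electrodes = 16L)
  space <- fix_space(6)
  sys <- assemble_cem_system(mesh, conductivity_model("I"), cap)
  x <- numeric(ncol(space$G)); x[10L] <- 1e-8
  good <- solve_forward(sys, x, space$G)
  iscale <- max(abs(Matrix::crossprod(sys$B, good$z)))
  expect_lt(max(abs(electrode_net_current(good, mesh, cap))), 1e-10 * iscale)
  bad_sys <- sys
  nz <- which(bad_sys$B@x != 0)[1]
  bad_sys$B@x[nz] <- -bad_sys$B@x[nz]
  bad <- solve_forward(bad_sys, x, space$G)
  expect_gt(max(abs(electrode_net_current(bad, mesh, cap))), 1e-6 * iscale)
})

test_that("model mismatch penalizes localization and grows toward the surface", {
  cfg <- exp_cfg()
  cfg$eccentricities <- c(0.2, 0.98)
  cfg$n_per_level <- 5L
  setup <- exp_setup()
  setup$samples <- sample_sources_by_eccentricity(
    setup$space, cfg$eccentricities, cfg$n_per_level, cfg$tolerance,
    seed = cfg$seed)
  mis <- run_eccentricity_analysis(cfg, reconstruction = "pem", setup = setup)
  mat <- run_eccentricity_analysis(cfg, reconstruction = "cem", setup = setup)
  expect_true(all(is.finite(c(mis$pd, mis$ad, mis$nd))))
  # matched lead field reproduces its own data: zero forward difference
  expect_lt(max(abs(mat$rdm)), 1e-10)
  # mismatch penalty: PEM-based reconstruction localizes worse in the median
  sup <- mis$eccentricity == 0.98
  expect_gte(median(mis$pd[sup]), median(mat$pd[sup]))
  # forward differences grow toward the surface
  expect_gt(median(mis$rdm[sup]), median(mis$rdm[!sup]))
  expect_gt(median(abs(mis$mag[sup])), median(abs(mis$mag[!sup])))
})
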