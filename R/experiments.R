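#' Logarithmic contact-impedance sweep
#'
#' Fourteen values equally spaced on a log scale covering 0.1 Ohm to 12 kOhm
#' average contact impedance.
#'
#' @param from,to sweep limits (Ohm).
#' @param n number of values.
#' @return numeric vector (Ohm).
#' @export
impedance_sweep <- function(from = 0.1, to = 12000, n = 14L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Experiment configuration
#'
#' Bundles every setting of the scripted experiments: synthetic head
#' geometry and resolution, electrode cap, impedance sweep, eccentricity
#' design, IAS settings and the global seed. Defaults reproduce the study
#' design at desk scale: a 50 mm four-shell neonatal sphere head with
#' fontanel openings, 74 electrodes of 10 mm diameter, a 14-value impedance
#' sweep over 0.1 Ohm - 12 kOhm, and 100 sources at each of the five
#' eccentricities 0.2, 0.4, 0.6, 0.8, 0.98.
#'
#' @param radii shell radii (m), see [build_sphere_head()].
#' @param fontanels fontanel list, see [default_fontanels()].
#' @param n mesh subdivision (default 11, about 64k tetrahedra).
#' @param n_electrodes electrodes in the cap (default 74).
#' @param coverage cap coverage fraction.
#' @param contact_radius electrode contact radius (m).
#' @param impedances impedance sweep (Ohm).
#' @param eccentricities eccentricity levels.
#' @param n_per_level sources per level.
#' @param tolerance eccentricity band half-width.
#' @param inverse_impedance ACI (Ohm) used when generating CEM data for the
#'   localization analysis (default 2 kOhm).
#' @param ias an [ias_config()].
#' @param normalize_data scale each data vector to unit l2 norm before
#'   inversion (keeps the fixed `gamma` on a consistent scale).
#' @param seed global integer seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(radii = c(0.038, 0.042, 0.046, 0.050),
                              fontanels = default_fontanels(),
                              n = 11L,
                              n_electrodes = 74L,
                              coverage = 0.65,
                              contact_radius = 0.005,
                              impedances = impedance_sweep(),
                              eccentricities = c(0.2, 0.4, 0.6, 0.8, 0.98),
                              n_per_level = 100L,
                              tolerance = 0.02,
                              inverse_impedance = 2000,
                              ias = ias_config(),
                              normalize_data = TRUE,
                              seed = 1L) {
  structure(list(radii = radii, fontanels = fontanels, n = as.integer(n),
                 n_electrodes = as.integer(n_electrodes), coverage = coverage,
                 contact_radius = contact_radius, impedances = impedances,
                 eccentricities = eccentricities,
                 n_per_level = as.integer(n_per_level), tolerance = tolerance,
                 inverse_impedance = inverse_impedance, ias = ias,
                 normalize_data = normalize_data, seed = as.integer(seed)),
            class = "experiment_config")
}

# shared per-config setup: mesh, cap centers, cap (at a placeholder
# impedance), source space and the eccentricity samples
experiment_setup <- function(config) {
  mesh <- build_sphere_head(radii = config$radii, fontanels = config$fontanels,
                            n = config$n, seed = config$seed)
  centers <- fibonacci_cap_centers(config$n_electrodes, radius = config$radii[4],
                                   coverage = config$coverage)
  cap <- build_electrode_cap(mesh, centers,
                             contact_radius = config$contact_radius,
                             impedance = 2000)
  space <- build_source_space(mesh)
  samples <- sample_sources_by_eccentricity(
    space, config$eccentricities, config$n_per_level,
    config$tolerance, seed = config$seed)
  list(mesh = mesh, cap = cap, space = space, samples = samples)
}

manifest_of <- function(config, extra = list()) {
  c(list(config_hash = rlang::hash(config), seed = config$seed,
         mesh_n = config$n, n_electrodes = config$n_electrodes), extra)
}

#' Impedance sweep of forward-model comparisons
#'
#' Recomputes the three electrode/head model comparisons over the impedance
#' sweep: (1) CEM model I vs PEM model I, (2) CEM model I vs CEM model II
#' (open vs closed skull), (3) CEM model III vs PEM model III. For every
#' impedance and every sampled source the RDM and MAG between the two
#' forward solutions are recorded.
#'
#' @param config an [experiment_config()].
#' @param comparison 1, 2 or 3.
#' @param setup optional precomputed [experiment_setup()] (shared across
#'   comparisons to avoid re-meshing).
#' @return tibble of class `cem_sweep`: `comparison`, `impedance` (Ohm),
#'   `source` (dipole index), `eccentricity` (design level), `rdm`, `mag`
#'   (percent); manifest in `attr(, "manifest")`.
#' @export
run_comparison_sweep <- function(config = experiment_config(),
                                 comparison = 1L, setup = NULL) {
  stopifnot(comparison %in% 1:3)
  if (is.null(setup)) setup <- experiment_setup(config)
  mesh <- setup$mesh; cap <- setup$cap; space <- setup$space
  idx <- unlist(setup$samples, use.names = FALSE)
  levels <- rep(as.numeric(names(setup$samples)),
                times = lengths(setup$samples))
  Gs <- space$G[, idx, drop = FALSE]

  models <- switch(as.character(comparison),
    "1" = list(first = list("cem", "I"), second = list("pem", "I")),
    "2" = list(first = list("cem", "I"), second = list("cem", "II")),
    "3" = list(first = list("cem", "III"), second = list("pem", "III")))

  # the PEM side is impedance-independent: compute once
  ground <- NULL
  side_matrix <- function(kind, model, impedance, ground_node) {
    sig <- conductivity_model(model)
    if (kind == "pem") {
      sys <- assemble_pem_system(mesh, sig, cap, ground_node = ground_node)
      list(m = compute_lead_field(sys, Gs)$matrix, ground = sys$ground_node)
    } else {
      sys <- assemble_cem_system(mesh, sig, set_impedance(cap, impedance),
                                 ground_node = ground_node)
      list(m = compute_lead_field(sys, Gs, method = "schur")$matrix,
           ground = sys$ground_node)
    }
  }
  # fix a common ground node from the CEM(first) assembly at the first
  # impedance so that both sides share the same reference
  first0 <- side_matrix(models$first[[1]], models$first[[2]],
                        config$impedances[1], NULL)
  ground <- first0$ground
  second_static <- if (models$second[[1]] == "pem") {
    side_matrix("pem", models$second[[2]], NA, ground)$m
  } else NULL

  rows <- purrr::map_dfr(seq_along(config$impedances), function(iz) {
    z <- config$impedances[iz]
    m1 <- if (iz == 1L) first0$m else {
      side_matrix(models$first[[1]], models$first[[2]], z, ground)$m
    }
    m2 <- if (!is.null(second_static)) second_static else {
      side_matrix(models$second[[1]], models$second[[2]], z, ground)$m
    }
    tibble::tibble(
      comparison = comparison,
      impedance = z,
      source = idx,
      eccentricity = levels,
      rdm = vapply(seq_along(idx), function(j) rdm(m1[, j], m2[, j]), numeric(1)),
      mag = vapply(seq_along(idx), function(j) mag(m1[, j], m2[, j]), numeric(1))
    )
  })
  attr(rows, "manifest") <- manifest_of(config, list(comparison = comparison))
  class(rows) <- c("cem_sweep", class(rows))
  rows
}

#' Box-plot summaries of comparison records
#'
#' Per impedance (and eccentricity level, when present) box-plot statistics
#' of RDM and MAG.
#'
#' @param records a [run_comparison_sweep()] or [run_eccentricity_analysis()]
#'   tibble.
#' @param by grouping columns (default `"impedance"`).
#' @return tibble: grouping columns, `measure`, `median`, `iqr_low`,
#'   `iqr_high`, `min`, `max`, `n`.
#' @export
summarize_comparisons <- function(records, by = "impedance") {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(records)[, c(by, intersect(c("rdm", "mag", "pd", "ad", "nd"),
                                                names(records)))],
    cols = -dplyr::all_of(by), names_to = "measure", values_to = "value")
  dplyr::reframe(dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "measure")))),
                 boxplot_summary(.data$value))
}

#' Eccentricity analysis with IAS source localization
#'
#' For every sampled source: generate noiseless electrode data with the CEM
#' (model I, `inverse_impedance` ACI), reconstruct with the IAS minimum
#' current estimate using the PEM lead field (or the matched CEM lead field
#' when `reconstruction = "cem"`), with the generating dipole removed from
#' the reconstruction source space, and record RDM/MAG between the two
#' forward solutions together with the localization differences PD (mm),
#' AD (degrees), ND (mm, truth norm minus estimate norm) and the explicit
#' depth bias `-ND`.
#'
#' @param config an [experiment_config()].
#' @param reconstruction `"pem"` (study design) or `"cem"` (matched lead
#'   field, self-consistency mode).
#' @param setup optional precomputed [experiment_setup()].
#' @return tibble of class `cem_eccentricity` with one row per source;
#'   manifest in `attr(, "manifest")`.
#' @export
run_eccentricity_analysis <- function(config = experiment_config(),
                                      reconstruction = c("pem", "cem"),
                                      setup = NULL) {
  reconstruction <- match.arg(reconstruction)
  if (is.null(setup)) setup <- experiment_setup(config)
  mesh <- setup$mesh; cap <- setup$cap; space <- setup$space
  sig <- conductivity_model("I")
  cem <- assemble_cem_system(mesh, sig,
                             set_impedance(cap, config$inverse_impedance))
  pem <- assemble_pem_system(mesh, sig, cap, ground_node = cem$ground_node)

  idx <- unlist(setup$samples, use.names = FALSE)
  levels <- rep(as.numeric(names(setup$samples)),
                times = lengths(setup$samples))
  lf_cem <- compute_lead_field(cem, space$G, method = "schur")
  lf_rec_full <- if (reconstruction == "pem") {
    compute_lead_field(pem, space$G)
  } else lf_cem

  rows <- purrr::map_dfr(seq_along(idx), function(j) {
    k <- idx[j]
    y <- lf_cem$matrix[, k]
    sc <- if (config$normalize_data) sqrt(sum(y^2)) else 1
    keep <- setdiff(seq_len(ncol(space$G)), k)
    est <- ias_solve(lf_rec_full$matrix[, keep, drop = FALSE], y / sc,
                     config$ias, space = subset_sources(space, keep))
    r_true <- space$positions[k, ]; q_true <- space$moments[k, ]
    tibble::tibble(
      source = k,
      eccentricity = levels[j],
      rdm = rdm(lf_cem$matrix[, k], lf_rec_full$matrix[, k]),
      mag = mag(lf_cem$matrix[, k], lf_rec_full$matrix[, k]),
      pd = 1e3 * pd(r_true, est$position),
      ad = ad(q_true, est$moment),
      nd = 1e3 * nd(r_true, est$position),
      depth_bias = -1e3 * nd(r_true, est$position),
      objective = tail(est$objective, 1L)
    )
  })
  attr(rows, "manifest") <- manifest_of(
    config, list(reconstruction = reconstruction,
                 impedance = config$inverse_impedance))
  class(rows) <- c("cem_eccentricity", class(rows))
  rows
}

#' Voltage patterns and subelectrode variation for the two test sources
#'
#' Computes, for sources A (next to the C6-like electrode) and B (under the
#' Fz-like electrode and the frontal fontanel), the referenced 74-electrode
#' voltage pattern and — for the CEM combinations — the per-electrode
#' subelectrode potential variation, under the four model/impedance
#' combinations PEM (I), CEM (I) 2 kOhm, CEM (I) 0.1 Ohm and CEM (II) 2 kOhm.
#'
#' @param config an [experiment_config()].
#' @param setup optional precomputed [experiment_setup()].
#' @return list of class `cem_source_ab` with tibbles `voltages` (`source`,
#'   `combo`, `electrode`, `voltage` in volts, average-referenced) and
#'   `variation` (`source`, `combo`, `electrode`, `max_abs_variation`,
#'   `area`), plus `sources` (the located dipoles).
#' @export
run_source_ab <- function(config = experiment_config(), setup = NULL) {
  if (is.null(setup)) setup <- experiment_setup(config)
  mesh <- setup$mesh; cap <- setup$cap; space <- setup$space
  srcs <- list(A = locate_test_sources(space, cap, "A"),
               B = locate_test_sources(space, cap, "B"))
  combos <- tibble::tribble(
    ~combo, ~kind, ~model, ~impedance,
    "PEM (I)", "pem", "I", NA,
    "CEM (I) 2.0 kOhm", "cem", "I", 2000,
    "CEM (I) 0.1 Ohm", "cem", "I", 0.1,
    "CEM (II) 2.0 kOhm", "cem", "II", 2000
  )
  ground <- assemble_cem_system(mesh, conductivity_model("I"),
                                set_impedance(cap, 2000))$ground_node
  volt <- list(); vari <- list()
  for (i in seq_len(nrow(combos))) {
    kind <- combos$kind[i]
    sig <- conductivity_model(combos$model[i])
    sys <- if (kind == "cem") {
      assemble_cem_system(mesh, sig, set_impedance(cap, combos$impedance[i]),
                          ground_node = ground)
    } else {
      assemble_pem_system(mesh, sig, cap, ground_node = ground)
    }
    for (sname in names(srcs)) {
      s <- srcs[[sname]]
      x <- numeric(ncol(space$G)); x[s$index] <- s$amplitude
      sol <- solve_forward(sys, x, space$G)
      volt[[paste(sname, i)]] <- tibble::tibble(
        source = sname, combo = combos$combo[i],
        electrode = seq_along(sol$v),
        voltage = average_reference(sol$v))
      if (kind == "cem") {
        vv <- purrr::map_dfr(seq_along(cap$triangles), function(l) {
          sv <- subelectrode_variation(sol, mesh, cap, l)
          tibble::tibble(electrode = l,
                         max_abs_variation = max(abs(sv$variation)),
                         area = cap$areas[l])
        })
        vari[[paste(sname, i)]] <- dplyr::mutate(
          vv, source = sname, combo = combos$combo[i], .before = 1L)
      }
    }
  }
  out <- list(voltages = dplyr::bind_rows(volt),
              variation = dplyr::bind_rows(vari),
              sources = srcs)
  attr(out, "manifest") <- manifest_of(config)
  class(out) <- "cem_source_ab"
  out
}

#' Validation suite: oracle and invariant harness
#'
#' Runs the package's built-in correctness checks on a given configuration:
#' the Bayes mapping value, lead-field average-reference and zero-net-current
#' identities, Schur/block/transfer route equivalence, the reference-matrix
#' idempotency, Whitney-column quadrature agreement, the homogeneous-sphere
#' analytic-dipole oracle, and a matched-lead-field IAS recovery.
#'
#' @param config an [experiment_config()]; the default desk-scale suite uses
#'   a reduced mesh (`n = 6`) for speed.
#' @param n_oracle_dipoles dipoles entering the sphere-oracle median RDM.
#' @return tibble of class `cem_validation`: `check`, `value`, `tolerance`,
#'   `pass`. Attribute `"pass"` is `TRUE` when every check passed.
#' @export
run_validation_suite <- function(config = experiment_config(n = 8L,
                                                            n_per_level = 10L,
                                                            tolerance = 0.06),
                                 n_oracle_dipoles = 6L) {
  setup <- experiment_setup(config)
  mesh <- setup$mesh; cap <- setup$cap; space <- setup$space
  sig <- conductivity_model("I")
  cem <- assemble_cem_system(mesh, sig, set_impedance(cap, 2000))
  pem <- assemble_pem_system(mesh, sig, cap, ground_node = cem$ground_node)
  idx <- unlist(setup$samples, use.names = FALSE)
  sub <- idx[seq(1L, length(idx), length.out = min(25L, length(idx)))]
  Gs <- space$G[, sub, drop = FALSE]

  checks <- list()
  add <- function(check, value, tolerance) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, value = value, tolerance = tolerance,
      pass = value <= tolerance)
  }

  add("bayes gamma mapping |gamma - 1.4142e-6|",
      abs(gamma_from_bayes(0.001, 1) - sqrt(2) * 1e-6), 1e-18)

  lf1 <- compute_lead_field(cem, Gs, method = "schur")
  add("average reference: max |column sum| / max |entry|",
      max(abs(colSums(lf1$matrix))) / max(abs(lf1$matrix)), 1e-10)

  x <- numeric(ncol(Gs)); x[1] <- 1e-8
  sol <- solve_forward(cem, x, Gs)
  inet <- electrode_net_current(sol, mesh, cap)
  iscale <- max(abs(Matrix::crossprod(cem$B, sol$z)))
  add("zero net electrode current (relative)", max(abs(inet)) / iscale, 1e-10)

  lf2 <- compute_lead_field(cem, Gs, method = "block")
  lf3 <- compute_lead_field(cem, Gs, method = "transfer")
  sc <- max(abs(lf1$matrix))
  add("lead-field route: |schur - block| (relative)",
      max(abs(lf1$matrix - lf2$matrix)) / sc, 1e-8)
  add("lead-field route: |schur - transfer| (relative)",
      max(abs(lf1$matrix - lf3$matrix)) / sc, 1e-8)

  R <- reference_matrix(ncol(cem$B))
  add("reference matrix idempotency |RR - R|", max(abs(R %*% R - R)), 1e-12)

  qerr <- max(vapply(sub[seq_len(min(10L, length(sub)))], function(k) {
    qq <- whitney_quadrature_column(mesh, space, k)
    gk <- as.numeric(space$G[, k])
    max(abs(qq$g_dense - gk)) / max(abs(gk)) +
      max(abs(qq$moment - space$moments[k, ]))
  }, numeric(1)))
  add("Whitney column vs quadrature + moment", qerr, 1e-8)

  sig_h <- c(brain = 0.33, csf = 0.33, skull = 0.33, fontanel = 0.33,
             scalp = 0.33)
  pem_h <- assemble_pem_system(mesh, sig_h, cap)
  ecc <- source_eccentricities(space)
  cand <- which(abs(ecc - 0.4) < 0.1)
  ks <- cand[seq(1L, length(cand), length.out = min(n_oracle_dipoles,
                                                    length(cand)))]
  lfh <- compute_lead_field(pem_h, space$G[, ks, drop = FALSE])
  rds <- vapply(seq_along(ks), function(i) {
    ya <- average_reference(analytic_dipole_potential(
      pem_h$points, space$positions[ks[i], ], space$moments[ks[i], ],
      config$radii[4], 0.33))
    rdm(ya, lfh$matrix[, i])
  }, numeric(1))
  add("sphere oracle: median RDM (%)", median(rds), 5)

  # matched-lead-field IAS recovery: median PD over seeded superficial
  # sources, bounded by twice the mean inter-dipole spacing (a regression
  # guard; the weighted-average position of a minimum current estimate
  # carries intrinsic spread of the order of the source spacing)
  lf_all <- compute_lead_field(cem, space$G, method = "schur")
  restore <- local_rng(config$seed)
  ksup <- sample(which(ecc >= 0.8 & ecc < 0.95), 6L)
  restore()
  pds <- vapply(ksup, function(k) {
    keep <- setdiff(seq_len(ncol(space$G)), k)
    yk <- lf_all$matrix[, k]
    est <- ias_solve(lf_all$matrix[, keep, drop = FALSE],
                     yk / sqrt(sum(yk^2)),
                     config$ias, space = subset_sources(space, keep))
    pd(space$positions[k, ], est$position)
  }, numeric(1))
  add("IAS matched recovery median PD (m)", median(pds),
      2 * mean_dipole_spacing(space))

  out <- dplyr::bind_rows(checks)
  attr(out, "pass") <- all(out$pass)
  attr(out, "manifest") <- manifest_of(config)
  class(out) <- c("cem_validation", class(out))
  out
}

#' Write comparison/eccentricity records with a manifest header
#'
#' Delimited text (TSV) preceded by `# key: value` manifest lines (config
#' hash, seed, mesh resolution).
#'
#' @param records tibble with a `manifest` attribute.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_records <- function(records, path) {
  man <- attr(records, "manifest")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(man)) {
    writeLines(sprintf("# %s: %s", nm, format(man[[nm]])), con)
  }
  utils::write.table(as.data.frame(records), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  man_lines <- grep("^#", lines)
  tbl <- utils::read.table(text = lines[-man_lines], header = TRUE, sep = "\t")
  out <- tibble::as_tibble(tbl)
  man <- lapply(lines[man_lines], function(l) sub("^# [^:]+: ", "", l))
  names(man) <- vapply(lines[man_lines],
                       function(l) sub("^# ([^:]+):.*", "\\1", l), character(1))
  attr(out, "manifest") <- man
  out
}
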