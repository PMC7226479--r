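# The synthetic generator: standards registry layout, replicate and cohort
# simulation, dropout behaviour and the forward model.

test_that("standard registry reproduces the ladder layout and total mass", {
  reg <- build_ups2_registry(6, 8, 0.5, 50000, 10.6)
  expect_equal(nrow(reg), 48L)
  expect_equal(range(reg$amount_fmol), c(0.5, 50000))
  # per-tier amounts equal, tiers a x10 ladder
  tiers <- matrix(reg$amount_fmol, nrow = 8)
  expect_true(all(apply(tiers, 2, function(a) all(a == a[1]))))
  expect_equal(tiers[1, -1] / tiers[1, -6], rep(0.1, 5), tolerance = 1e-9)
  # mass conservation: sum(amount x mw) x 1e-9 ug equals the configured total
  expect_equal(sum(reg$amount_fmol * reg$mw_da) * 1e-9, 10.6,
               tolerance = 1e-6)
  expect_true(all(reg$mw_da > 0) && all(reg$length_aa > 0))
  expect_false(anyDuplicated(reg$protein_id) > 0)
})

test_that("two-point geometric ladder and argument guards", {
  reg <- build_ups2_registry(2, 1, 1, 10, 5)
  expect_equal(sort(reg$amount_fmol), c(1, 10))
  expect_error(build_ups2_registry(1, 8), class = "fq_invalid")
  expect_error(build_ups2_registry(6, 8, 10, 0.5), class = "fq_invalid")
  expect_error(build_ups2_registry(6, 8, -1, 10), class = "fq_invalid")
})

test_that("spiking maps the working dilution to the printed final range", {
  reg <- build_ups2_registry()
  conc <- standard_concentrations(reg, spike_ratio = 0.1,
                                  reconstitution_ul = 10)
  expect_equal(range(conc), c(0.005, 500))
})

test_that("replicate simulation is seed-deterministic and noise-calibrated", {
  reg <- build_ups2_registry()
  r1 <- simulate_calibration_replicates(reg, noise = noise_model(seed = 11))
  r2 <- simulate_calibration_replicates(reg, noise = noise_model(seed = 11))
  r3 <- simulate_calibration_replicates(reg, noise = noise_model(seed = 12))
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))

  # noiseless limit: all replicates of a protein identical
  r0 <- simulate_calibration_replicates(reg, noise = quiet_noise(seed = 1))
  cv <- tapply(r0$intensity, r0$protein_id, function(v) sd(v) / mean(v))
  expect_equal(unname(max(cv)), 0)

  # lognormal technical noise reproduces the configured CV (200 proteins)
  big <- build_ups2_registry(25, 8, 0.5, 50000, 10.6)
  rn <- simulate_calibration_replicates(
    big, noise = quiet_noise(seed = 2, replicate_cv = 0.15))
  cvs <- tapply(rn$intensity, rn$protein_id, function(v) sd(v) / mean(v))
  expect_equal(mean(cvs), 0.15, tolerance = 0.2)
  expect_error(simulate_calibration_replicates(reg[0, ]),
               class = "fq_invalid")
})

test_that("detection dropout is monotone in spiked amount", {
  reg <- build_ups2_registry()
  noise <- noise_model(dropout_midpoint_fmol = 5, dropout_steepness = 2,
                       seed = 3)
  reps <- simulate_calibration_replicates(reg, n_replicates = 200,
                                          noise = noise)
  rate <- tapply(reps$protein_id,
                 factor(reps$on_column_fmol,
                        sort(unique(reg$amount_fmol / 10 * 0.1 * 2))),
                 length) / (200 * 8)
  rate[is.na(rate)] <- 0
  expect_true(all(diff(rate) >= -0.05))
  # and the underlying probability curve is exactly monotone
  amounts <- 10^seq(-3, 3, 0.5)
  expect_true(all(diff(fetoquant:::detection_prob(amounts, noise)) >= 0))
})

test_that("cohort simulation reproduces the study group structure", {
  coh <- simulate_cohort(noise = noise_model(seed = 5))
  expect_equal(nrow(coh), 179L)
  expect_equal(as.vector(table(coh$group)[paste0("G0", 1:5)]),
               c(43L, 37L, 34L, 29L, 36L))
  expect_true(all(coh$df_status == (coh$group %in% c("G02", "G04"))))
  expect_true(all(coh$dm_type[coh$group %in% c("G03", "G04")] == "T2DM"))
  markers <- attr(coh, "markers")
  expect_true(all(c("CRP", "CEACAM1", "CNDP1", "IGHG4", "IGHA2") %in% markers))
  expect_true(all(as.matrix(coh[markers]) >= 0))
  # determinism
  expect_identical(coh, simulate_cohort(noise = noise_model(seed = 5)))
})

test_that("degenerate and large-sample cohort draws behave as configured", {
  spec0 <- group_spec("G05", 4, FALSE, list(M = c(10, 0)), dm_type = "none")
  coh0 <- simulate_cohort(list(spec0), quiet_noise(seed = 1))
  expect_equal(coh0$M, rep(10, 4))

  # CLT check at the published control-group CEACAM1 parameters
  spec <- group_spec("G05", 10000, FALSE, list(CEACAM1 = c(515.6, 72.14)),
                     dm_type = "none")
  coh <- simulate_cohort(list(spec), quiet_noise(seed = 2))
  se <- 72.14 / sqrt(10000)
  expect_lt(abs(mean(coh$CEACAM1) - 515.6), 3 * se)

  expect_error(group_spec("G01", 3, FALSE, list(M = c(1, -1))),
               class = "fq_invalid")
})

test_that("forward model errors are informative", {
  spec <- group_spec("G05", 2, FALSE, list(CNDP1 = c(17.1, 0)),
                     dm_type = "none")
  coh <- simulate_cohort(list(spec), quiet_noise())
  truth <- list(slope = 1, intercept = -3.6)
  map <- default_peptide_map(c("CNDP1", "BKG001"))
  expect_error(
    forward_model_intensities(coh, truth, default_peptide_map("BKG001"),
                              quiet_noise()),
    "peptide_map", class = "fq_invalid")
  # concentrations far above the compositional ceiling cannot be represented
  spec_hi <- group_spec("G05", 1, FALSE, list(CNDP1 = c(1e9, 0)),
                        dm_type = "none")
  coh_hi <- simulate_cohort(list(spec_hi), quiet_noise())
  expect_error(forward_model_intensities(coh_hi, truth, map, quiet_noise()),
               "ceiling", class = "fq_compute")
})

test_that("zero concentration emits no peptide rows for that marker", {
  spec <- group_spec("G05", 3, FALSE,
                     list(CNDP1 = c(17.1, 0), CEACAM1 = c(0, 0)),
                     dm_type = "none")
  coh <- simulate_cohort(list(spec), quiet_noise())
  map <- default_peptide_map(c("CNDP1", "CEACAM1", "BKG001"))
  tbl <- forward_model_intensities(coh, list(slope = 1, intercept = -3.6),
                                   map, quiet_noise())
  expect_false("CEACAM1" %in% tbl$protein_id)
  expect_true(all(c("CNDP1", "BKG001") %in% tbl$protein_id))
  expect_true(all(tbl$spectral_count >= 1))
})

test_that("with biological noise the mean recovered concentration is unbiased", {
  # 100 subjects at a fixed concentration, unit-mean lognormal biological
  # noise: mean recovered concentration within 5% of truth (slope 1).
  spec <- group_spec("G05", 100, FALSE, list(CNDP1 = c(17.1, 0)),
                     dm_type = "none")
  coh <- simulate_cohort(list(spec), quiet_noise())
  truth <- list(slope = 1, intercept = -3.65)
  map <- default_peptide_map(c("CNDP1", "BKG001"))
  tbl <- forward_model_intensities(
    coh, truth, map, quiet_noise(seed = 9, biological_cv = 0.15))
  curve <- identity_curve()
  # invert manually through the generating line (slope 1):
  pint <- tapply(tbl$intensity[tbl$protein_id == "CNDP1"],
                 tbl$sample_id[tbl$protein_id == "CNDP1"], sum)
  tot <- tapply(tbl$intensity, tbl$sample_id, sum)
  inorm <- pint / tot[names(pint)]
  conc <- 10^((log10(inorm) - truth$intercept) / truth$slope)
  mw <- df_markers()$mw_da[df_markers()$gene == "CNDP1"]
  expect_equal(mean(conc * mw * 1e-3), 17.1, tolerance = 0.05)
})

test_that("presence simulation feeds the set bookkeeping exactly", {
  sets <- simulate_protein_presence(321, c(G01 = 56, G02 = 37, G03 = 10,
                                           G04 = 34, G05 = 0))
  expect_equal(length(Reduce(intersect, sets)), 321L)
  expect_equal(lengths(sets),
               c(G01 = 377L, G02 = 358L, G03 = 331L, G04 = 355L, G05 = 321L))
})
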