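# Quantification: proteotypic filtering, TIC normalization, NSAF, unit
# conversion, frequency filter and set bookkeeping.

test_that("proteotypic filtering keeps exactly the uniquely mapped peptides", {
  obs <- data.frame(sample_id = "s", protein_id = "x",
                    peptide_seq = c("AAK", "CCK", "DDK"),
                    intensity = 1:3, spectral_count = 1L)
  map <- list(AAK = "P1", CCK = c("P1", "P2"), DDK = "P2")
  got <- unique_peptides(obs, map)
  expect_equal(got$peptide_seq, c("AAK", "DDK"))
  expect_error(unique_peptides(obs, map[1:2]), "DDK", class = "fq_invalid")

  # brute-force equivalence on a constructed 10-peptide map
  set.seed(3)
  peps <- sprintf("PEP%02dK", 1:10)
  map2 <- setNames(lapply(1:10, function(i)
    sprintf("Q%d", seq_len(sample(1:3, 1)))), peps)
  obs2 <- data.frame(sample_id = "s", protein_id = "q", peptide_seq = peps,
                     intensity = 1, spectral_count = 1L)
  expected <- peps[vapply(map2, length, integer(1)) == 1L]
  expect_equal(unique_peptides(obs2, map2)$peptide_seq, expected)
})

test_that("normalized total intensity is a per-sample TIC fraction", {
  obs <- data.frame(sample_id = "s1",
                    protein_id = c("A", "A", "B"),
                    peptide_seq = c("AAK", "CCK", "DDK"),
                    intensity = c(100, 200, 700), spectral_count = 1L)
  got <- normalized_total_intensity(obs)
  expect_equal(got$norm_intensity[got$protein_id == "A"], 0.3)
  expect_equal(got$norm_intensity[got$protein_id == "B"], 0.7)
  expect_equal(got$n_unique_peptides, c(2L, 1L))
  expect_equal(sum(got$norm_intensity), 1, tolerance = 1e-12)

  # single protein normalizes to 1; scale invariance
  one <- normalized_total_intensity(obs[3, ])
  expect_equal(one$norm_intensity, 1)
  obs2 <- obs; obs2$intensity <- obs2$intensity * 37.5
  expect_equal(normalized_total_intensity(obs2)$norm_intensity,
               got$norm_intensity, tolerance = 1e-14)
})

test_that("normalization invariants hold on simulated samples", {
  coh <- simulate_cohort(noise = noise_model(seed = 4))
  reg <- build_ups2_registry()
  truth <- calibration_truth(reg)
  map <- default_peptide_map(c("CRP", "CEACAM1", "CNDP1", "BKG001"))
  tbl <- forward_model_intensities(
    coh, truth, map, noise_model(replicate_cv = 0.1, seed = 4),
    markers = c("CRP", "CEACAM1", "CNDP1"))
  prot <- normalized_total_intensity(tbl)
  sums <- tapply(prot$norm_intensity, prot$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("NSAF follows its defining formula and sums to one", {
  expect_equal(nsaf(c(5, 5), c(100, 100)), c(0.5, 0.5))
  expect_equal(nsaf(c(10, 20), c(100, 400)), c(2 / 3, 1 / 3))
  set.seed(9)
  spc <- rpois(20, 30); len <- sample(100:900, 20)
  expect_equal(sum(nsaf(spc, len)), 1, tolerance = 1e-12)
  expect_error(nsaf(c(0, 0), c(10, 10)), class = "fq_compute")
  expect_error(nsaf(1:2, c(-1, 10)), class = "fq_invalid")
})

test_that("mass conversion and flags in single-protein quantification", {
  curve <- identity_curve()
  # 1 fmol/uL of a 50 kDa protein is 50 ng/mL
  q <- quantify_protein(curve, norm_intensity = 1, mw_da = 50000)
  expect_equal(q$conc_fmol_ul, 1)
  expect_equal(q$conc_ng_ml, 50)
  expect_equal(quantify_protein(curve, 0)$flags, "undetected")
  expect_true(is.na(quantify_protein(curve, 0)$conc_fmol_ul))

  # dimensional-analysis oracle at the published control CEACAM1 level
  mw <- df_markers()$mw_da[df_markers()$gene == "CEACAM1"]
  conc_fmol_ul <- 515.6 / (mw * 1e-3)
  q2 <- quantify_protein(curve, 10^(0 + 1 * log10(conc_fmol_ul)), mw)
  expect_equal(q2$conc_ng_ml / mw * 1e3, conc_fmol_ul, tolerance = 1e-9)
  expect_equal(q2$conc_ng_ml, 515.6, tolerance = 1e-9)
})

test_that("frequency filter applies the detected-fraction threshold", {
  man <- data.frame(sample_id = sprintf("s%02d", 1:37), group = "G02",
                    stringsAsFactors = FALSE)
  quant_all <- data.frame(sample_id = man$sample_id, protein_id = "P1")
  f1 <- frequency_filter(quant_all, man, 1.0)
  expect_equal(f1$records$frequency, 1.0)
  expect_true("P1" %in% f1$retained$G02)

  quant_36 <- quant_all[-1, ]
  f2 <- frequency_filter(quant_36, man, 1.0)
  expect_equal(f2$records$frequency, 36 / 37, tolerance = 1e-12)
  expect_false("P1" %in% f2$retained$G02)

  man2 <- data.frame(sample_id = c("a", "b"), group = "G01")
  f3 <- frequency_filter(data.frame(sample_id = "a", protein_id = "P1"),
                         man2, 0.5)
  expect_true("P1" %in% f3$retained$G01)  # >= threshold is retained
  expect_error(frequency_filter(quant_all, man, 0), class = "fq_invalid")
})

test_that("shared and group-specific sets match brute-force set algebra", {
  sets <- list(G01 = c("a", "b", "c"), G02 = c("b", "c", "d"),
               G03 = c("b", "e"))
  got <- group_specific_sets(sets)
  expect_equal(got$shared_all, "b")
  expect_equal(got$specific, list(G01 = "a", G02 = "d", G03 = "e"))
  expect_equal(got$pairwise["G01", "G02"], 2L, ignore_attr = TRUE)

  # identical detection everywhere
  same <- list(A = letters[1:5], B = letters[1:5])
  got2 <- group_specific_sets(same)
  expect_equal(lengths(got2$specific), c(A = 0L, B = 0L))
  expect_equal(length(got2$shared_all), 5L)

  # random 5-group instances vs exhaustive membership counting
  set.seed(11)
  for (i in 1:5) {
    mat <- matrix(runif(5 * 40) < 0.5, nrow = 5,
                  dimnames = list(paste0("G", 1:5), paste0("p", 1:40)))
    sets_i <- apply(mat, 1, function(r) colnames(mat)[r], simplify = FALSE)
    got_i <- group_specific_sets(sets_i)
    member_count <- colSums(mat)
    expect_setequal(got_i$shared_all, colnames(mat)[member_count == 5])
    for (g in rownames(mat))
      expect_setequal(got_i$specific[[g]],
                      colnames(mat)[mat[g, ] & member_count == 1])
    # disjointness properties
    spec_all <- unlist(got_i$specific)
    expect_false(anyDuplicated(spec_all) > 0)
    expect_length(intersect(spec_all, got_i$shared_all), 0L)
  }
})

test_that("the published shared/specific bookkeeping round-trips", {
  sets <- simulate_protein_presence(321, c(G01 = 56, G02 = 37, G03 = 10,
                                           G04 = 34, G05 = 0))
  counts <- group_specific_sets(sets)$counts
  expect_equal(unname(counts["shared_all"]), 321L)
  expect_equal(unname(counts[paste0("specific_G0", 1:4)]),
               c(56L, 37L, 10L, 34L))
})

test_that("quantify_samples flags out-of-range and margin predictions", {
  coh <- simulate_cohort(noise = noise_model(seed = 21))
  reg <- build_ups2_registry()
  reps <- simulate_calibration_replicates(reg, noise = quiet_noise(seed = 21))
  cal <- df_calibration(reps)
  map <- default_peptide_map(c("CRP", "CEACAM1", "CNDP1", "BKG001"))
  tbl <- forward_model_intensities(
    coh, calibration_truth(reg), map, quiet_noise(seed = 21),
    markers = c("CRP", "CEACAM1", "CNDP1"))
  quant <- quantify_samples(tbl, cal, map)
  # background is far above the top calibration point
  expect_true(all(grepl("extrapolated",
                        quant$flags[quant$protein_id == "BKG001"])))
  # typical CNDP1 concentrations put ~0.6-1.8 fmol on column: inside the
  # prohibited band for most subjects (the lowest control values fall below)
  expect_gt(mean(grepl("unreliable_margin",
                       quant$flags[quant$protein_id == "CNDP1"])), 0.5)
  # noiseless: recovered CRP equals the cohort truth
  crp <- quant[quant$protein_id == "CRP", ]
  expect_equal(crp$conc_ng_ml[match(coh$sample_id, crp$sample_id)],
               coh$CRP, tolerance = 1e-9)
})
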