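# Synthetic-data generator: spiked-standard replicates, patient cohorts and
# forward-modelled peptide intensity tables with the statistical structure the
# downstream analysis assumes. Defaults reproduce the study conditions: a
# 48-protein dilution standard (0.5-50,000 fmol, 10.6 ug total) spiked 1:10
# into a non-human background and run in six technical replicates, and a
# five-group cohort (n = 43/37/34/29/36) whose marker concentrations follow
# the published group means +/- SD.

#' Technical/biological noise model for the synthetic generator
#'
#' @param replicate_cv Relative SD (CV, as a fraction) of multiplicative
#'   lognormal technical noise between replicates or injections. Noise factors
#'   have unit mean so they do not bias the intensity scale.
#' @param biological_cv Extra per-subject multiplicative CV applied to true
#'   concentrations before forward-modelling; the published group SDs are
#'   treated as total between-subject spread, so the default adds none.
#' @param dropout_midpoint_fmol On-column amount (fmol) at which detection
#'   probability is 50%.
#' @param dropout_steepness Slope of the logistic dropout curve in log10
#'   on-column amount; larger is sharper.
#' @param seed Integer seed; identical seeds give identical outputs.
#'
#' @return An object of class `"fq_noise"` (a validated list).
#' @export
#' @examples
#' noise_model(replicate_cv = 0.15, seed = 1)
noise_model <- function(replicate_cv = 0.10, biological_cv = 0,
                        dropout_midpoint_fmol = 0.005, dropout_steepness = 4,
                        seed = NULL) {
  check_scalar_num(replicate_cv, "replicate_cv", min = 0)
  check_scalar_num(biological_cv, "biological_cv", min = 0)
  check_scalar_num(dropout_midpoint_fmol, "dropout_midpoint_fmol", positive = TRUE)
  check_scalar_num(dropout_steepness, "dropout_steepness", min = 0)
  if (!is.null(seed)) check_count(seed, "seed", min = 0L)
  structure(list(replicate_cv = replicate_cv, biological_cv = biological_cv,
                 dropout_midpoint_fmol = dropout_midpoint_fmol,
                 dropout_steepness = dropout_steepness,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "fq_noise")
}

detection_prob <- function(on_column_fmol, noise) {
  p <- plogis(noise$dropout_steepness *
                (log10(on_column_fmol) - log10(noise$dropout_midpoint_fmol)))
  p[on_column_fmol <= 0] <- 0
  p
}

#' Reference registry of the study's plasma markers
#'
#' Accession, gene symbol, representative average mass and sequence length for
#' the ten quantified markers (CRP, CEACAM1, CNDP1 and the immunoglobulin
#' subclasses), together with the display unit each is reported in and the
#' published per-group concentration means and SDs. Concentrations are stored
#' internally in ng/mL regardless of display unit.
#'
#' @return A data.frame with one row per marker: `protein_id`, `gene`,
#'   `mw_da`, `length_aa`, `unit`, and `mean_G01` ... `sd_G05` in ng/mL.
#' @export
#' @examples
#' df_markers()[, c("gene", "mw_da", "unit")]
df_markers <- function() {
  m <- data.frame(
    protein_id = c("P02741", "P13688", "Q96KN2", "P01857", "P01859", "P01860",
                   "P01861", "P01871", "P01876", "P01877"),
    gene = c("CRP", "CEACAM1", "CNDP1", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
             "IGHM", "IGHA1", "IGHA2"),
    mw_da = c(25039, 57560, 56692, 36106, 35901, 41287, 35941, 49440, 37655,
              36591),
    length_aa = c(224L, 526L, 507L, 330L, 326L, 377L, 327L, 452L, 353L, 340L),
    unit = c("ug_ml", "ng_ml", "ng_ml", rep("mg_ml", 7)),
    stringsAsFactors = FALSE
  )
  # Published group means +/- SD, converted to ng/mL (ug/mL x 1e3, mg/mL x 1e6).
  tab <- list(
    CRP     = c(2.04, 1.32, 5.29, 1.82, 2.84, 0.67, 4.21, 1.37, 1.97, 0.71) * 1e3,
    CEACAM1 = c(291.62, 34.55, 113.18, 16.23, 311.17, 42.16, 81.09, 10.54,
                515.6, 72.14),
    CNDP1   = c(32.4, 5.23, 49.3, 5.18, 27.4, 2.63, 37.7, 3.34, 17.1, 4.31),
    IGHG1   = c(8.84, 1.22, 7.81, 1.69, 8.26, 2.09, 7.65, 2.13, 7.07, 1.99) * 1e6,
    IGHG2   = c(2.27, 0.41, 2.43, 0.37, 2.54, 0.31, 2.37, 0.22, 2.11, 0.14) * 1e6,
    IGHG3   = c(2.06, 0.49, 2.12, 0.38, 1.87, 0.24, 2.05, 0.38, 1.93, 0.65) * 1e6,
    IGHG4   = c(2.12, 0.42, 1.85, 0.36, 2.08, 0.49, 1.81, 0.41, 2.64, 0.98) * 1e6,
    IGHM    = c(1.87, 0.31, 1.67, 0.20, 1.93, 0.26, 1.71, 0.17, 1.34, 0.12) * 1e6,
    IGHA1   = c(1.42, 0.26, 1.98, 0.14, 1.39, 0.19, 1.55, 0.28, 1.31, 0.23) * 1e6,
    IGHA2   = c(0.41, 0.08, 0.52, 0.04, 0.38, 0.07, 0.46, 0.07, 0.23, 0.09) * 1e6
  )
  vals <- t(vapply(m$gene, function(g) tab[[g]], numeric(10)))
  colnames(vals) <- as.vector(rbind(paste0("mean_G0", 1:5), paste0("sd_G0", 1:5)))
  cbind(m, as.data.frame(vals))
}

#' Specification of one cohort group
#'
#' @param group_id Group label, one of `"G01"`..`"G05"`.
#' @param n Number of subjects (> 0).
#' @param df_positive Logical; whether newborns in this group showed signs of
#'   diabetic fetopathy.
#' @param marker_params Named list mapping marker (gene symbol) to
#'   `c(mean, sd)` in ng/mL; all sd must be >= 0.
#' @param dm_type `"GDM"`, `"T2DM"` or `"none"`.
#' @param insulin_fraction Fraction of subjects treated with insulin (the
#'   remainder get dietary intervention; control groups get `"none"`).
#'
#' @return A `"fq_group_spec"` list.
#' @export
group_spec <- function(group_id, n, df_positive, marker_params,
                       dm_type = c("GDM", "T2DM", "none"),
                       insulin_fraction = 0) {
  dm_type <- match.arg(dm_type)
  n <- check_count(n, "n")
  if (!is.list(marker_params) || is.null(names(marker_params)))
    stop_invalid("marker_params must be a named list of c(mean, sd)")
  for (g in names(marker_params)) {
    p <- marker_params[[g]]
    if (length(p) != 2L || !all(is.finite(p)))
      stop_invalid("marker_params[['", g, "']] must be c(mean, sd)")
    if (p[2] < 0) stop_invalid("negative sd for marker ", g)
  }
  check_scalar_num(insulin_fraction, "insulin_fraction", min = 0)
  structure(list(group_id = group_id, n = n,
                 df_positive = isTRUE(df_positive),
                 marker_params = marker_params, dm_type = dm_type,
                 insulin_fraction = insulin_fraction),
            class = "fq_group_spec")
}

#' Default five-group cohort specification
#'
#' Builds the study's cohort layout: G01 (GDM, healthy newborns, n = 43),
#' G02 (GDM + DF, n = 37), G03 (T2DM, n = 34), G04 (T2DM + DF, n = 29) and
#' G05 (uncomplicated pregnancy, n = 36), with every marker's group mean and
#' SD taken from the published concentration tables.
#'
#' @param markers Marker registry as returned by [df_markers()]; rows may be
#'   dropped to simulate a subset of markers.
#' @return List of five [group_spec()] objects.
#' @export
#' @examples
#' sum(vapply(df_group_specs(), function(s) s$n, numeric(1)))  # 179 subjects
df_group_specs <- function(markers = df_markers()) {
  sizes <- c(G01 = 43L, G02 = 37L, G03 = 34L, G04 = 29L, G05 = 36L)
  dm <- c(G01 = "GDM", G02 = "GDM", G03 = "T2DM", G04 = "T2DM", G05 = "none")
  dfp <- c(G01 = FALSE, G02 = TRUE, G03 = FALSE, G04 = TRUE, G05 = FALSE)
  # 27% of GDM patients were insulin-treated; T2DM groups were insulin-treated.
  insulin <- c(G01 = 0.27, G02 = 0.27, G03 = 1, G04 = 1, G05 = 0)
  lapply(names(sizes), function(g) {
    mp <- setNames(lapply(seq_len(nrow(markers)), function(i)
      c(markers[[paste0("mean_", g)]][i], markers[[paste0("sd_", g)]][i])),
      markers$gene)
    group_spec(g, sizes[[g]], dfp[[g]], mp, dm_type = dm[[g]],
               insulin_fraction = insulin[[g]])
  })
}

#' Build a synthetic dilution-standard registry
#'
#' Lays out a UPS-2-style dynamic-range standard: `n_tiers` amount tiers on a
#' geometric ladder from `max_fmol` down to `min_fmol`, `proteins_per_tier`
#' proteins per tier. Synthetic protein masses are rescaled so the summed
#' protein mass equals `total_mass_ug`.
#'
#' @param n_tiers Number of amount tiers (>= 2).
#' @param proteins_per_tier Proteins per tier (>= 1).
#' @param min_fmol,max_fmol Lowest and highest spiked on-column amounts (fmol).
#' @param total_mass_ug Total protein mass of the standard (micrograms).
#'
#' @return A data.frame (`protein_id`, `amount_fmol`, `mw_da`, `length_aa`)
#'   with `n_tiers * proteins_per_tier` rows.
#' @export
#' @examples
#' reg <- build_ups2_registry()
#' range(reg$amount_fmol)                      # 0.5 ... 50,000 fmol
#' sum(reg$amount_fmol * reg$mw_da) * 1e-9     # 10.6 ug
build_ups2_registry <- function(n_tiers = 6, proteins_per_tier = 8,
                                min_fmol = 0.5, max_fmol = 50000,
                                total_mass_ug = 10.6) {
  n_tiers <- check_count(n_tiers, "n_tiers", min = 2L)
  proteins_per_tier <- check_count(proteins_per_tier, "proteins_per_tier")
  check_scalar_num(min_fmol, "min_fmol", positive = TRUE)
  check_scalar_num(max_fmol, "max_fmol", positive = TRUE)
  check_scalar_num(total_mass_ug, "total_mass_ug", positive = TRUE)
  if (min_fmol >= max_fmol) stop_invalid("min_fmol must be < max_fmol")

  amounts <- max_fmol * (min_fmol / max_fmol)^((seq_len(n_tiers) - 1) / (n_tiers - 1))
  n <- n_tiers * proteins_per_tier
  # Deterministic synthetic masses spread over a plasma-like size range; each
  # tier samples the whole range so mass and amount are not confounded.
  mw_raw <- seq(12000, 90000, length.out = proteins_per_tier)
  reg <- data.frame(
    protein_id = sprintf("UPS%03d", seq_len(n)),
    amount_fmol = rep(amounts, each = proteins_per_tier),
    mw_da = rep(mw_raw, times = n_tiers),
    stringsAsFactors = FALSE
  )
  # fmol x Da = 1e-9 ug; rescale masses so the registry mass is exact.
  scale <- total_mass_ug / (sum(reg$amount_fmol * reg$mw_da) * 1e-9)
  reg$mw_da <- reg$mw_da * scale
  reg$length_aa <- pmax(50L, as.integer(round(reg$mw_da / 110)))
  reg
}

#' Nominal final concentration of each standard protein
#'
#' Maps on-column registry amounts to the final injected concentration:
#' amounts are reconstituted in `reconstitution_ul` microliters (giving the
#' working dilution) and spiked into the background matrix at `spike_ratio`.
#' The defaults map 0.5-50,000 fmol to 0.005-500 fmol/uL.
#'
#' @param registry Standards registry from [build_ups2_registry()].
#' @param spike_ratio Spike ratio into the matrix (1:10 = 0.1).
#' @param reconstitution_ul Reconstitution volume (uL).
#' @return Numeric vector of final concentrations (fmol/uL), one per protein.
#' @export
standard_concentrations <- function(registry, spike_ratio = 0.1,
                                    reconstitution_ul = 10) {
  if (spike_ratio <= 0 || spike_ratio > 1)
    stop_invalid("spike_ratio must be in (0, 1]")
  check_scalar_num(reconstitution_ul, "reconstitution_ul", positive = TRUE)
  registry$amount_fmol / reconstitution_ul * spike_ratio
}

#' Simulate technical replicates of the spiked standard
#'
#' Per protein and replicate, raw intensity follows a power law in
#' concentration (`gain * conc^slope`) with multiplicative lognormal technical
#' noise; detection is subject to the logistic dropout model evaluated at the
#' on-column amount. Undetected observations are omitted.
#'
#' @inheritParams standard_concentrations
#' @param n_replicates Number of technical replicates (>= 2).
#' @param noise A [noise_model()].
#' @param gain Raw-intensity gain (arbitrary units at 1 fmol/uL).
#' @param slope True log-log response slope.
#' @param injection_ul Injected volume (uL), used for the dropout model.
#' @return A data.frame: `replicate`, `protein_id`, `nominal_conc_fmol_ul`,
#'   `on_column_fmol`, `intensity`.
#' @export
#' @examples
#' reg <- build_ups2_registry()
#' reps <- simulate_calibration_replicates(reg, noise = noise_model(seed = 1))
#' range(reps$nominal_conc_fmol_ul)  # 0.005 ... 500 fmol/uL
simulate_calibration_replicates <- function(registry, spike_ratio = 0.1,
                                            n_replicates = 6,
                                            noise = noise_model(),
                                            gain = 1e9, slope = 1,
                                            reconstitution_ul = 10,
                                            injection_ul = 2) {
  if (is.null(registry) || nrow(registry) == 0L)
    stop_invalid("empty standards registry")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  check_scalar_num(gain, "gain", positive = TRUE)
  check_scalar_num(injection_ul, "injection_ul", positive = TRUE)
  conc <- standard_concentrations(registry, spike_ratio, reconstitution_ul)

  with_seed(derive_seed(noise$seed, "calibration"), {
    n <- nrow(registry)
    out <- data.frame(
      replicate = rep(seq_len(n_replicates), each = n),
      protein_id = rep(registry$protein_id, times = n_replicates),
      nominal_conc_fmol_ul = rep(conc, times = n_replicates),
      on_column_fmol = rep(conc * injection_ul, times = n_replicates),
      stringsAsFactors = FALSE
    )
    out$intensity <- gain * out$nominal_conc_fmol_ul^slope *
      rlnorm_cv(nrow(out), noise$replicate_cv)
    detected <- runif(nrow(out)) < detection_prob(out$on_column_fmol, noise)
    out <- out[detected, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a patient cohort
#'
#' Draws each subject's marker concentrations from a zero-truncated normal
#' with the group's configured mean and SD (ng/mL) and attaches group, DM
#' type, DF status and treatment labels.
#'
#' @param specs List of [group_spec()] objects (default [df_group_specs()]).
#' @param noise A [noise_model()]; only its seed is used here.
#' @return A data.frame with manifest columns (`sample_id`, `group`,
#'   `dm_type`, `df_status`, `treatment`) followed by one concentration column
#'   per marker (ng/mL); marker names in `attr(, "markers")`.
#' @export
#' @examples
#' coh <- simulate_cohort(noise = noise_model(seed = 7))
#' nrow(coh)  # 179
simulate_cohort <- function(specs = df_group_specs(), noise = noise_model()) {
  if (length(specs) == 0L) stop_invalid("specs must be non-empty")
  markers <- names(specs[[1]]$marker_params)
  for (s in specs)
    if (!identical(sort(names(s$marker_params)), sort(markers)))
      stop_invalid("marker_params keys must be identical across groups")

  with_seed(derive_seed(noise$seed, "cohort"), {
    rows <- lapply(specs, function(s) {
      mat <- vapply(markers, function(m) {
        p <- s$marker_params[[m]]
        rtruncnorm_pos(s$n, p[1], p[2])
      }, numeric(s$n))
      if (s$n == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, markers))
      n_ins <- round(s$insulin_fraction * s$n)
      treatment <- if (s$dm_type == "none") rep("none", s$n)
        else c(rep("insulin", n_ins), rep("diet", s$n - n_ins))
      cbind(data.frame(sample_id = sprintf("%s_S%02d", s$group_id, seq_len(s$n)),
                       group = s$group_id, dm_type = s$dm_type,
                       df_status = s$df_positive, treatment = treatment,
                       stringsAsFactors = FALSE),
            as.data.frame(mat))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "markers") <- markers
    out
  })
}

# Zero-truncated normal by rejection; sd = 0 degenerates to the mean.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd < 0) stop_invalid("negative sd")
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Deterministic synthetic proteotypic peptide map
#'
#' Generates `n_peptides` unique synthetic tryptic-looking peptide sequences
#' per protein. Sequences are a deterministic function of the protein index so
#' the map is reproducible without a seed and peptides never collide across
#' proteins.
#'
#' @param protein_ids Character vector of protein identifiers.
#' @param n_peptides Peptides per protein.
#' @param peptide_length Residues per peptide (terminal K is appended).
#' @return Named list: protein id -> character vector of peptide sequences.
#' @export
default_peptide_map <- function(protein_ids, n_peptides = 3,
                                peptide_length = 11) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
  n_peptides <- check_count(n_peptides, "n_peptides")
  setNames(lapply(seq_along(protein_ids), function(i) {
    vapply(seq_len(n_peptides), function(j) {
      idx <- (i * 131 + j * 17 + seq_len(peptide_length) * 7 +
                (i + j) * seq_len(peptide_length)) %% length(aa) + 1
      paste0(paste(aa[idx], collapse = ""), "K")
    }, character(1))
  }), protein_ids)
}

#' True calibration curve implied by a standards registry
#'
#' Under the power-law intensity model with TIC normalization, the normalized
#' intensity of a standard at concentration C is `C^slope / sum_j(C_j^slope)`,
#' independent of the raw gain. Returns the slope and log10 intercept of that
#' line, for use as the forward model's generating curve.
#'
#' @inheritParams standard_concentrations
#' @param slope True log-log response slope.
#' @return List with `slope` and `intercept` (log10 normalized intensity at
#'   1 fmol/uL).
#' @export
calibration_truth <- function(registry, spike_ratio = 0.1, slope = 1,
                              reconstitution_ul = 10) {
  conc <- standard_concentrations(registry, spike_ratio, reconstitution_ul)
  list(slope = slope, intercept = -log10(sum(conc^slope)))
}

#' Forward-model a cohort to a peptide-level intensity table
#'
#' The inverse of quantification: for each subject and marker the target
#' TIC-normalized intensity is taken from the generating calibration curve at
#' the subject's true concentration, split across that marker's proteotypic
#' peptides, and perturbed by unit-mean lognormal technical noise. A bulk
#' background protein absorbs the remaining signal so that per-sample
#' normalization recovers the targets; with all noise at zero, quantification
#' returns the true concentrations exactly. Spectral counts are generated
#' proportional to intensity.
#'
#' Normalized intensities are fractions of the sample total, so markers whose
#' curve-predicted fraction would push the per-sample sum past the
#' compositional ceiling cannot be represented and raise an error; in
#' practice this confines the forward model to concentrations at or near the
#' calibration range.
#'
#' @param cohort Cohort data.frame from [simulate_cohort()] (ng/mL columns).
#' @param curve_truth List with `slope` and `intercept`
#'   (see [calibration_truth()]).
#' @param peptide_map Named list protein -> unique peptide sequences; must
#'   cover every forward-modelled marker plus `background_id`.
#' @param noise A [noise_model()].
#' @param markers Character vector of marker columns to forward-model
#'   (default: all cohort markers).
#' @param registry Marker registry supplying `mw_da` (default [df_markers()]).
#' @param injection_ul Injected volume (uL), for the dropout model.
#' @param total_intensity Raw total intensity of each sample (arbitrary).
#' @param background_id Identifier of the bulk background protein.
#' @param spc_scale Expected total spectral counts per sample.
#' @return A data.frame: `sample_id`, `protein_id`, `peptide_seq`,
#'   `intensity`, `spectral_count`.
#' @export
forward_model_intensities <- function(cohort, curve_truth, peptide_map,
                                      noise = noise_model(),
                                      markers = attr(cohort, "markers"),
                                      registry = df_markers(),
                                      injection_ul = 2,
                                      total_intensity = 1e9,
                                      background_id = "BKG001",
                                      spc_scale = 1e4) {
  if (is.null(markers)) stop_invalid("cohort carries no marker columns")
  missing_map <- setdiff(c(markers, background_id), names(peptide_map))
  if (length(missing_map))
    stop_invalid("peptide_map lacks entries for: ",
                 paste(missing_map, collapse = ", "))
  mw <- setNames(registry$mw_da, registry$gene)
  if (any(!markers %in% names(mw)))
    stop_invalid("registry lacks mw for: ",
                 paste(setdiff(markers, names(mw)), collapse = ", "))

  with_seed(derive_seed(noise$seed, "forward_model"), {
    out <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      conc_ng_ml <- as.numeric(cohort[i, markers])
      bio <- rlnorm_cv(length(markers), noise$biological_cv)
      conc_fmol_ul <- conc_ng_ml / (mw[markers] * 1e-3) * bio
      present <- conc_fmol_ul > 0
      p_det <- detection_prob(conc_fmol_ul * injection_ul, noise)
      present <- present & (runif(length(markers)) < p_det)

      target <- ifelse(present,
                       10^(curve_truth$intercept +
                             curve_truth$slope * log10(pmax(conc_fmol_ul, 1e-300))),
                       0)
      if (sum(target) >= 1)
        stop_compute("sample ", cohort$sample_id[i],
                     ": summed target normalized intensity ",
                     signif(sum(target), 3),
                     " exceeds the compositional ceiling (1); ",
                     "concentrations too far above the calibration range ",
                     "cannot be forward-modelled")

      rows <- lapply(which(present), function(k) {
        peps <- peptide_map[[markers[k]]]
        ints <- target[k] * total_intensity / length(peps) *
          rlnorm_cv(length(peps), noise$replicate_cv)
        data.frame(sample_id = cohort$sample_id[i], protein_id = markers[k],
                   peptide_seq = peps, intensity = ints,
                   stringsAsFactors = FALSE)
      })
      bkg_peps <- peptide_map[[background_id]]
      bkg <- data.frame(
        sample_id = cohort$sample_id[i], protein_id = background_id,
        peptide_seq = bkg_peps,
        intensity = (1 - sum(target)) * total_intensity / length(bkg_peps) *
          rlnorm_cv(length(bkg_peps), noise$replicate_cv),
        stringsAsFactors = FALSE)
      out[[i]] <- do.call(rbind, c(rows, list(bkg)))
    }
    tbl <- do.call(rbind, out)
    rownames(tbl) <- NULL
    tot <- tapply(tbl$intensity, tbl$sample_id, sum)[tbl$sample_id]
    tbl$spectral_count <- as.integer(pmax(1, round(tbl$intensity / tot * spc_scale)))
    tbl
  })
}

#' Simulate per-group protein detection sets
#'
#' Builds a presence/absence structure with a configurable number of proteins
#' shared by every group plus group-specific proteins, for exercising the
#' shared/specific set bookkeeping.
#'
#' @param n_shared Number of proteins detected in every group.
#' @param specific Named integer vector: group -> number of proteins detected
#'   only in that group.
#' @return Named list: group -> character vector of detected protein ids.
#' @export
#' @examples
#' sets <- simulate_protein_presence(321, c(G01 = 56, G02 = 37, G03 = 10,
#'                                          G04 = 34, G05 = 0))
#' length(Reduce(intersect, sets))  # 321
simulate_protein_presence <- function(n_shared,
                                      specific = c(G01 = 56, G02 = 37,
                                                   G03 = 10, G04 = 34,
                                                   G05 = 0)) {
  n_shared <- check_count(n_shared, "n_shared", min = 0L)
  if (is.null(names(specific))) stop_invalid("specific must be named by group")
  shared <- sprintf("SHR%04d", seq_len(n_shared))
  setNames(lapply(names(specific), function(g) {
    k <- check_count(specific[[g]], paste0("specific[", g, "]"), min = 0L)
    c(shared, if (k > 0) sprintf("%s_SPC%03d", g, seq_len(k)))
  }), names(specific))
}
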