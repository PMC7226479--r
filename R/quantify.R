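# Absolute quantification of proteins from peptide observations: restriction
# to proteotypic (unique) peptides, per-sample TIC normalization of total
# intensities, interpolation on the calibration curve, NSAF abundance
# ranking, and the detection-frequency and shared/group-specific set filters.

#' Restrict observations to proteotypic peptides
#'
#' Keeps peptide observations whose sequence maps to exactly one protein in
#' the supplied mapping; shared peptides are dropped. Every observed peptide
#' must be covered by the mapping.
#'
#' @param observations Peptide observation data.frame (needs `peptide_seq`).
#' @param peptide_to_proteins Named list: peptide sequence -> character
#'   vector of proteins carrying it.
#' @return The observations restricted to unique peptides.
#' @export
unique_peptides <- function(observations, peptide_to_proteins) {
  unmapped <- setdiff(unique(observations$peptide_seq),
                      names(peptide_to_proteins))
  if (length(unmapped))
    stop_invalid("unmapped peptide(s): ",
                 paste(utils::head(unmapped, 5), collapse = ", "),
                 if (length(unmapped) > 5) " ...")
  degree <- vapply(peptide_to_proteins, length, integer(1))
  keep <- observations$peptide_seq %in%
    names(peptide_to_proteins)[degree == 1L]
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Invert a protein -> peptides map into peptide -> proteins.
peptide_lookup <- function(peptide_map) {
  pep <- unlist(peptide_map, use.names = FALSE)
  prot <- rep(names(peptide_map), lengths(peptide_map))
  split(prot, pep)
}

#' Per-protein normalized total intensity
#'
#' For each sample, sums the unique-peptide intensities of each protein and
#' divides by the sample's total unique-peptide intensity, so normalized
#' intensities sum to 1 over the detected proteins of a sample.
#'
#' @param observations Unique-peptide observation data.frame (`sample_id`,
#'   `protein_id`, `intensity`, optionally `spectral_count`).
#' @return A data.frame: `sample_id`, `protein_id`, `n_unique_peptides`,
#'   `total_intensity`, `norm_intensity` and summed `spectral_count`.
#' @export
normalized_total_intensity <- function(observations) {
  if (nrow(observations) == 0L)
    stop_invalid("no observations to normalize")
  key <- paste(observations$sample_id, observations$protein_id, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    sample_id = observations$sample_id[first],
    protein_id = observations$protein_id[first],
    n_unique_peptides = as.integer(table(key)[key[first]]),
    total_intensity = as.numeric(rowsum(observations$intensity, key)[key[first], ]),
    stringsAsFactors = FALSE)
  out$spectral_count <-
    if ("spectral_count" %in% names(observations))
      as.integer(rowsum(as.numeric(observations$spectral_count), key)[key[first], ])
    else NA_integer_
  samp_tot <- tapply(out$total_intensity, out$sample_id, sum)
  if (any(samp_tot == 0))
    stop_compute("degenerate sample(s) with zero total intensity: ",
                 paste(names(samp_tot)[samp_tot == 0], collapse = ", "))
  out$norm_intensity <- out$total_intensity /
    as.numeric(samp_tot[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Normalized spectral abundance factor (NSAF)
#'
#' `NSAF_p = (SpC_p / L_p) / sum_q (SpC_q / L_q)` for one sample's proteins.
#'
#' @param spectral_counts Non-negative spectral counts, one per protein.
#' @param lengths_aa Positive sequence lengths (residues), same order.
#' @return NSAF values summing to 1.
#' @export
#' @examples
#' nsaf(c(10, 20), c(100, 400))  # 2/3, 1/3
nsaf <- function(spectral_counts, lengths_aa) {
  if (length(spectral_counts) != length(lengths_aa))
    stop_invalid("spectral_counts and lengths_aa must have equal length")
  if (any(lengths_aa <= 0)) stop_invalid("lengths must be > 0")
  if (any(spectral_counts < 0)) stop_invalid("spectral counts must be >= 0")
  saf <- spectral_counts / lengths_aa
  tot <- sum(saf)
  if (tot == 0) stop_compute("degenerate: all spectral counts are zero")
  saf / tot
}

#' Quantify one protein from its normalized intensity
#'
#' Interpolates the normalized total intensity on the calibration curve and
#' converts to mass concentration: `conc_ng_ml = conc_fmol_ul * mw_da / 1000`
#' (1 fmol/uL of a 50 kDa protein is 50 ng/mL). A zero intensity yields an
#' `undetected` flag and no concentration.
#'
#' @param curve A `"df_calib"` object.
#' @param norm_intensity Normalized total intensity (>= 0).
#' @param mw_da Molecular mass (Da); `NA` suppresses mass conversion.
#' @return One-row data.frame: `norm_intensity`, `conc_fmol_ul`,
#'   `conc_ng_ml`, `flags` (comma-separated).
#' @export
quantify_protein <- function(curve, norm_intensity, mw_da = NA_real_) {
  if (norm_intensity < 0) stop_invalid("norm_intensity must be >= 0")
  if (norm_intensity == 0)
    return(data.frame(norm_intensity = 0, conc_fmol_ul = NA_real_,
                      conc_ng_ml = NA_real_, flags = "undetected",
                      stringsAsFactors = FALSE))
  p <- predict(curve, norm_intensity)
  flags <- c(if (p$extrapolated) "extrapolated",
             if (p$unreliable_margin) "unreliable_margin")
  data.frame(norm_intensity = norm_intensity, conc_fmol_ul = p$conc_fmol_ul,
             conc_ng_ml = p$conc_fmol_ul * mw_da * 1e-3,
             flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
}

#' Quantify every sample in a peptide table
#'
#' The quantification stage: restrict to proteotypic peptides, compute
#' per-sample normalized total intensities, interpolate each detected protein
#' on the calibration curve, convert to mass units and attach NSAF ranks.
#'
#' @param peptides Peptide observation table (see [read_peptide_table()]).
#' @param curve A `"df_calib"` object.
#' @param peptide_map Named list protein -> peptide sequences; used both to
#'   identify proteotypic peptides and to attribute them.
#' @param registry Data.frame giving `mw_da` and `length_aa` per protein,
#'   keyed by `gene` or `protein_id` (default [df_markers()]); proteins
#'   absent from it get no mass concentration or NSAF length.
#' @return A data.frame: `sample_id`, `protein_id`, `n_unique_peptides`,
#'   `norm_intensity`, `conc_fmol_ul`, `conc_ng_ml`, `nsaf`, `flags`.
#' @export
quantify_samples <- function(peptides, curve, peptide_map,
                             registry = df_markers()) {
  obs <- unique_peptides(peptides, peptide_lookup(peptide_map))
  if (nrow(obs) == 0L) stop_compute("no proteotypic peptide observations")
  prot <- normalized_total_intensity(obs)

  key <- if ("gene" %in% names(registry)) registry$gene else registry$protein_id
  mw <- setNames(registry$mw_da, key)[prot$protein_id]
  len <- setNames(registry$length_aa, key)[prot$protein_id]

  q <- predict(curve, prot$norm_intensity)
  prot$conc_fmol_ul <- q$conc_fmol_ul
  prot$conc_ng_ml <- q$conc_fmol_ul * as.numeric(mw) * 1e-3
  prot$flags <- vapply(seq_len(nrow(q)), function(i)
    paste(c(if (q$extrapolated[i]) "extrapolated",
            if (q$unreliable_margin[i]) "unreliable_margin"),
          collapse = ","), character(1))

  # NSAF within each sample, over proteins with known length.
  prot$nsaf <- NA_real_
  for (s in unique(prot$sample_id)) {
    idx <- which(prot$sample_id == s & !is.na(len) & !is.na(prot$spectral_count))
    if (length(idx) && any(prot$spectral_count[idx] > 0))
      prot$nsaf[idx] <- nsaf(prot$spectral_count[idx], as.numeric(len[idx]))
  }
  prot[, c("sample_id", "protein_id", "n_unique_peptides", "norm_intensity",
           "conc_fmol_ul", "conc_ng_ml", "nsaf", "flags")]
}

#' Detection-frequency filter
#'
#' Per protein and group, frequency = (samples of the group in which the
#' protein was detected) / (group size). A protein is retained for a group
#' iff its frequency is at least `threshold` (default 1.0, i.e. detected in
#' every sample of the group).
#'
#' @param quant Quantification table (needs `sample_id`, `protein_id`).
#' @param manifest Sample manifest (needs `sample_id`, `group`).
#' @param threshold Retention threshold in (0, 1].
#' @return List with `records` (data.frame `protein_id`, `group`,
#'   `n_detected`, `group_size`, `frequency`, `retained`) and `retained`
#'   (named list group -> retained protein ids).
#' @export
frequency_filter <- function(quant, manifest, threshold = 1.0) {
  if (!(threshold > 0 && threshold <= 1))
    stop_invalid("threshold must be in (0, 1]")
  groups <- sort(unique(manifest$group))
  size <- table(manifest$group)
  grp_of <- setNames(manifest$group, manifest$sample_id)
  if (anyNA(grp_of[quant$sample_id]))
    stop_invalid("quant contains samples absent from the manifest")
  det <- unique(data.frame(protein_id = quant$protein_id,
                           group = grp_of[quant$sample_id],
                           sample_id = quant$sample_id,
                           stringsAsFactors = FALSE))
  proteins <- sort(unique(quant$protein_id))
  cnt <- table(factor(det$protein_id, proteins), factor(det$group, groups))
  rec <- expand.grid(protein_id = proteins, group = groups,
                     stringsAsFactors = FALSE)
  rec$n_detected <- as.integer(cnt[cbind(rec$protein_id, rec$group)])
  rec$group_size <- as.integer(size[rec$group])
  rec$frequency <- rec$n_detected / rec$group_size
  rec$retained <- rec$frequency >= threshold
  retained <- lapply(setNames(groups, groups), function(g)
    rec$protein_id[rec$group == g & rec$retained])
  list(records = rec, retained = retained)
}

#' Shared and group-specific protein sets
#'
#' Set bookkeeping over per-group retained protein sets: the intersection
#' over all groups (`shared_all`), each group's specific set (retained there
#' and in no other group), and pairwise intersection counts.
#'
#' @param sets Named list: group -> character vector of retained proteins
#'   (>= 2 groups).
#' @return List with `shared_all`, `specific` (named list), `counts`
#'   (named integer summary) and `pairwise` (matrix of intersection sizes).
#' @export
#' @examples
#' sets <- simulate_protein_presence(321, c(G01 = 56, G02 = 37, G03 = 10,
#'                                          G04 = 34, G05 = 0))
#' group_specific_sets(sets)$counts
group_specific_sets <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop_invalid("sets must be a named list of >= 2 groups")
  groups <- names(sets)
  shared <- Reduce(intersect, sets)
  specific <- lapply(setNames(groups, groups), function(g)
    setdiff(sets[[g]], unique(unlist(sets[setdiff(groups, g)]))))
  pairwise <- outer(groups, groups, Vectorize(function(a, b)
    length(intersect(sets[[a]], sets[[b]]))))
  dimnames(pairwise) <- list(groups, groups)
  counts <- c(shared_all = length(shared),
              setNames(lengths(specific), paste0("specific_", groups)))
  list(shared_all = shared, specific = specific, counts = counts,
       pairwise = pairwise)
}
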