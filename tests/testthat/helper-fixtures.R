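# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except what a test writes itself.

quiet_noise <- function(seed = NULL, replicate_cv = 0, biological_cv = 0) {
  # Detection essentially certain everywhere relevant.
  noise_model(replicate_cv = replicate_cv, biological_cv = biological_cv,
              dropout_midpoint_fmol = 1e-9, dropout_steepness = 8,
              seed = seed)
}

make_points <- function(conc, intensity, injection_ul = 2) {
  data.frame(protein_id = sprintf("P%02d", seq_along(conc)),
             nominal_conc_fmol_ul = conc,
             on_column_fmol = conc * injection_ul,
             n_detected = 6L, mean_intensity = intensity,
             cv = 0, selected = TRUE, rejection_reason = "none",
             stringsAsFactors = FALSE)
}

# A clean identity-like calibration: slope 1, intercept 0, valid range
# [1, 1000] fmol/uL.
identity_curve <- function() {
  fit_loglog(make_points(c(1, 10, 100, 1000), c(1, 10, 100, 1000)))
}

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_manifest <- function() {
  data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    group = c("G01", "G01", "G05", "G05"),
    dm_type = c("GDM", "GDM", "none", "none"),
    df_status = FALSE, treatment = c("diet", "insulin", "none", "none"),
    stringsAsFactors = FALSE)
}
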