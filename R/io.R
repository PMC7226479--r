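# Readers and writers for the pipeline's tabular formats. Everything is TSV
# with a header, UTF-8, '.' decimal separator; derived results go to JSON with
# a schema_version field. Readers validate every row and fail with located
# errors; they never silently coerce.

VALID_GROUPS <- paste0("G0", 1:5)
GROUP_DM <- c(G01 = "GDM", G02 = "GDM", G03 = "T2DM", G04 = "T2DM",
              G05 = "none")
DF_GROUPS <- c("G02", "G04")
AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
SCHEMA_VERSION <- "1.0"

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tbl <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop_invalid("missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", "))
  tbl
}

row_fail <- function(path, rows, msg) {
  stop_invalid(path, ": ", msg, " (row ", paste(rows, collapse = ", "), ")")
}

#' Read a peptide-level intensity table
#'
#' Expects tab-separated columns `sample_id`, `protein_id`, `peptide_seq`,
#' `intensity`, `spectral_count`. Rows are validated (non-negative intensity
#' and counts, amino-acid peptide sequences); duplicated
#' (sample, protein, peptide) rows are summed with a warning.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame of peptide observations.
#' @export
read_peptide_table <- function(path) {
  tbl <- read_tsv_checked(path, c("sample_id", "protein_id", "peptide_seq",
                                  "intensity", "spectral_count"))
  if (nrow(tbl) == 0L) {
    warning("empty peptide table: ", path)
    return(tbl)
  }
  bad <- which(!is.finite(tbl$intensity) | tbl$intensity < 0)
  if (length(bad)) row_fail(path, bad, "negative or non-numeric intensity")
  bad <- which(!is.finite(tbl$spectral_count) | tbl$spectral_count < 0 |
                 tbl$spectral_count != round(tbl$spectral_count))
  if (length(bad)) row_fail(path, bad, "invalid spectral_count")
  bad <- which(!grepl(AA_REGEX, tbl$peptide_seq))
  if (length(bad)) row_fail(path, bad, "invalid peptide sequence")

  key <- paste(tbl$sample_id, tbl$protein_id, tbl$peptide_seq, sep = "\r")
  if (anyDuplicated(key)) {
    warning("summing ", sum(duplicated(key)), " duplicated peptide row(s) in ",
            path)
    agg <- rowsum(tbl[, c("intensity", "spectral_count")], key, reorder = FALSE)
    first <- tbl[!duplicated(key), c("sample_id", "protein_id", "peptide_seq")]
    tbl <- cbind(first, agg)
    tbl$spectral_count <- as.integer(tbl$spectral_count)
    rownames(tbl) <- NULL
  }
  tbl
}

#' Write a peptide-level intensity table
#'
#' @param tbl Peptide observation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample manifest
#'
#' Expects columns `sample_id`, `group`, `dm_type`, `df_status`, `treatment`.
#' Enforces the group semantics: G01/G02 are GDM, G03/G04 are T2DM, G05 has
#' no diabetes; under the default labeling `df_status` is true exactly for
#' G02 and G04.
#'
#' @param path Path to the TSV manifest.
#' @param enforce_df_labels Require `df_status` to equal membership of
#'   G02/G04 (default TRUE).
#' @return A validated manifest data.frame with logical `df_status`.
#' @export
read_manifest <- function(path, enforce_df_labels = TRUE) {
  tbl <- read_tsv_checked(path, c("sample_id", "group", "dm_type",
                                  "df_status", "treatment"))
  bad <- which(!tbl$group %in% VALID_GROUPS)
  if (length(bad)) row_fail(path, bad, "unknown group label")
  bad <- which(tbl$dm_type != GROUP_DM[tbl$group])
  if (length(bad)) row_fail(path, bad, "group/dm_type inconsistency")
  df <- as.logical(tbl$df_status)
  if (anyNA(df)) row_fail(path, which(is.na(df)), "invalid df_status")
  tbl$df_status <- df
  if (enforce_df_labels) {
    bad <- which(df != tbl$group %in% DF_GROUPS)
    if (length(bad)) row_fail(path, bad, "df_status inconsistent with group")
  }
  if (anyDuplicated(tbl$sample_id))
    row_fail(path, which(duplicated(tbl$sample_id)), "duplicate sample_id")
  tbl
}

#' Write a sample manifest
#'
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a standards registry
#'
#' Expects columns `protein_id`, `amount_fmol`, `mw_da`, `length_aa` with
#' positive values and unique protein ids.
#'
#' @param path Path to the TSV registry.
#' @return A validated registry data.frame.
#' @export
read_standards <- function(path) {
  tbl <- read_tsv_checked(path, c("protein_id", "amount_fmol", "mw_da",
                                  "length_aa"))
  for (col in c("amount_fmol", "mw_da", "length_aa")) {
    bad <- which(!is.finite(tbl[[col]]) | tbl[[col]] <= 0)
    if (length(bad)) row_fail(path, bad, paste0("non-positive ", col))
  }
  if (anyDuplicated(tbl$protein_id))
    row_fail(path, which(duplicated(tbl$protein_id)), "duplicate protein_id")
  tbl
}

#' Write a standards registry
#'
#' @param registry Registry data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(registry, path) {
  write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write structured results to canonical JSON
#'
#' Serializes a (possibly nested) results list to JSON with keys in sorted
#' order, full double precision and a `schema_version` field, so reruns diff
#' cleanly. `NaN` values are serialized as `null` with a warning.
#'
#' @param results A serializable list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.list(results)) stop_invalid("results must be a list")
  if (has_nan(results)) warning("NaN value(s) serialized as null in ", path)
  results$schema_version <- SCHEMA_VERSION
  out <- tryCatch(
    jsonlite::toJSON(canonical_order(results), auto_unbox = TRUE, digits = NA,
                     na = "null", null = "null", dataframe = "columns"),
    error = function(e) stop_invalid("results not serializable: ",
                                     conditionMessage(e)))
  ok <- tryCatch({ writeLines(out, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_invalid("cannot write results to ", path)
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path Path to the JSON file.
#' @return The deserialized list.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

has_nan <- function(x) {
  if (is.list(x)) return(any(vapply(x, has_nan, logical(1))))
  is.numeric(x) && any(is.nan(x))
}

canonical_order <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(names(x)))
    x <- lapply(x[order(names(x))], canonical_order)
  x
}
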