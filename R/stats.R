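# Nonparametric statistical battery for quantified markers: Kruskal-Wallis
# across groups, pairwise Mann-Whitney, Fisher's exact tests, rank-correlation
# bias checks, fold changes, and a generic Fisher overrepresentation test
# with Bonferroni correction. Continuous marker contrasts use the rank tests;
# Fisher's exact is reserved for categorical/detection tables, with an
# optional dichotomize-at-median mode.

#' Kruskal-Wallis test across groups
#'
#' Rank-sum H statistic with midrank tie correction and chi-square p-value
#' (df = groups - 1), via [stats::kruskal.test()]. The degenerate case where
#' every observation is identical returns H = 0, p = 1.
#'
#' @param values A list of numeric vectors, one per group (>= 2 non-empty
#'   groups, >= 3 observations overall).
#' @param alpha Significance level for the `significant` flag.
#' @param exact If TRUE, replace the chi-square p with the exact permutation
#'   p (probability over all distinct group assignments of an H at least as
#'   large); only for total N <= 10.
#' @return A list: `test`, `statistic` (H), `df`, `p_value`, `significant`,
#'   `per_group` (n, mean, sd).
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
kruskal_wallis <- function(values, alpha = 0.05, exact = FALSE) {
  values <- lapply(values, function(v) v[!is.na(v)])
  values <- values[lengths(values) > 0]
  if (length(values) < 2L) stop_invalid("need >= 2 non-empty groups")
  x <- unlist(values, use.names = FALSE)
  if (length(x) < 3L) stop_invalid("need >= 3 observations")
  if (length(unique(x)) == 1L) {
    h <- 0; p <- 1
  } else {
    g <- factor(rep(seq_along(values), lengths(values)))
    kt <- kruskal.test(x, g)
    h <- unname(kt$statistic); p <- kt$p.value
    if (exact) {
      if (length(x) > 10L) stop_invalid("exact permutation p only for N <= 10")
      p <- kw_permutation_p(x, lengths(values), h)
    }
  }
  list(test = "kruskal_wallis", statistic = h, df = length(values) - 1L,
       p_value = p, significant = p < alpha,
       per_group = group_summaries(values))
}

# Exact permutation null of the (tie-corrected) H statistic: enumerate every
# distinct assignment of the pooled observations to groups of the given sizes
# and count those with H >= observed.
kw_permutation_p <- function(x, sizes, h_obs) {
  r <- rank(x)
  N <- length(r)
  combos <- function(idx, sizes) {
    if (length(sizes) == 1L) return(list(list(idx)))
    first <- utils::combn(seq_along(idx), sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- combos(idx[-f], sizes[-1])
      out <- c(out, lapply(rest, function(r2) c(list(idx[f]), r2)))
    }
    out
  }
  tie_corr <- 1 - sum(vapply(table(r), function(t) t^3 - t, numeric(1))) /
    (N^3 - N)
  h_of <- function(assign) {
    s <- vapply(assign, function(i) sum(r[i]), numeric(1))
    h <- 12 / (N * (N + 1)) * sum(s^2 / sizes) - 3 * (N + 1)
    h / tie_corr
  }
  hs <- vapply(combos(seq_len(N), sizes), h_of, numeric(1))
  mean(hs >= h_obs - 1e-10)
}

group_summaries <- function(values) {
  data.frame(group = if (is.null(names(values))) as.character(seq_along(values))
             else names(values),
             n = lengths(values),
             mean = vapply(values, mean, numeric(1)),
             sd = vapply(values, function(v)
               if (length(v) >= 2) sd(v) else NA_real_, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' Midrank U statistic via [stats::wilcox.test()]: exact p when the smaller
#' sample has at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param exact_max Largest `min(n_a, n_b)` for which the exact null
#'   distribution is used.
#' @return A list: `test`, `statistic` (U for the first sample), `p_value`,
#'   `exact`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney(1:3, 4:6)$p_value  # exact two-sided 0.1
mann_whitney <- function(values_a, values_b, exact_max = 8) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b))
    stop_invalid("both samples must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && min(length(values_a), length(values_b)) <= exact_max
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                     correct = TRUE))
  list(test = "mann_whitney", statistic = unname(wt$statistic),
       p_value = wt$p.value, exact = exact,
       n_a = length(values_a), n_b = length(values_b))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of tables at most as probable as the
#' observed one, via [stats::fisher.test()].
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A list: `test`, `p_value`, `odds_ratio`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value  # 0.1
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_invalid("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop_invalid("counts must be non-negative integers")
  ft <- fisher.test(table)
  list(test = "fisher_exact", p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' Spearman and Kendall rank correlations
#'
#' Spearman's rho (Pearson on midranks) and Kendall's tau-b (tie-corrected),
#' via [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `spearman_rho` and `kendall_tau`.
#' @export
rank_correlations <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("x and y must have equal length >= 3")
  list(spearman_rho = cor(x, y, method = "spearman"),
       kendall_tau = cor(x, y, method = "kendall"))
}

#' Fold change between group means
#'
#' @param group_mean_num,group_mean_den Means of the numerator and
#'   denominator groups (denominator > 0).
#' @return The plain ratio.
#' @export
#' @examples
#' fold_change(5.29, 1.97)  # CRP, DF-affected GDM vs control
fold_change <- function(group_mean_num, group_mean_den) {
  check_scalar_num(group_mean_num, "group_mean_num")
  check_scalar_num(group_mean_den, "group_mean_den")
  if (group_mean_den <= 0) stop_invalid("denominator mean must be > 0")
  group_mean_num / group_mean_den
}

#' Fisher overrepresentation test over annotation terms
#'
#' For each term, tests whether the study list is enriched for the term's
#' proteins relative to a reference list: one-sided hypergeometric upper-tail
#' p (k or more of the study's n proteins annotated, given K of the
#' reference's N are), Bonferroni-corrected over the number of tested terms.
#'
#' @param study_list Character vector of study proteins.
#' @param reference_list Character vector of reference proteins (the
#'   universe); study proteins absent from it are added.
#' @param annotation Named list: term -> character vector of proteins.
#' @return A data.frame sorted by corrected p: `term`, `k_study`, `n_study`,
#'   `K_ref`, `N_ref`, `enrichment`, `p_raw`, `p_bonferroni`.
#' @export
overrepresentation_test <- function(study_list, reference_list, annotation) {
  if (!length(annotation) || is.null(names(annotation)))
    stop_invalid("annotation must be a non-empty named list")
  study <- unique(study_list)
  ref <- union(unique(reference_list), study)
  n <- length(study); N <- length(ref)
  if (n == 0L || N == 0L) stop_invalid("study and reference must be non-empty")
  res <- do.call(rbind, lapply(names(annotation), function(t) {
    A <- intersect(annotation[[t]], ref)
    k <- length(intersect(study, A)); K <- length(A)
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k_study = k, n_study = n, K_ref = K, N_ref = N,
               enrichment = if (K == 0L) NA_real_ else (k / n) / (K / N),
               p_raw = p, stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- p.adjust(res$p_raw, method = "bonferroni")
  res <- res[order(res$p_bonferroni, res$p_raw, res$term), ]
  rownames(res) <- NULL
  res
}

#' Pivot a quantification table to a sample x marker matrix
#'
#' @param quant Quantification table from [quantify_samples()].
#' @param markers Marker (protein) ids to keep as columns.
#' @param value Which column to pivot (default `conc_ng_ml`).
#' @return A data.frame with `sample_id` and one column per marker;
#'   undetected combinations are `NA`.
#' @export
quant_to_matrix <- function(quant, markers, value = "conc_ng_ml") {
  samples <- unique(quant$sample_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (m in markers) {
    v <- setNames(rep(NA_real_, length(samples)), samples)
    rows <- quant$protein_id == m
    v[quant$sample_id[rows]] <- quant[[value]][rows]
    out[[m]] <- unname(v)
  }
  out
}

#' Per-marker group comparison report
#'
#' For each marker: per-group n/mean/SD over detected samples, the overall
#' Kruskal-Wallis p across groups, Mann-Whitney contrasts of each
#' DF-affected group against the pooled diabetic groups with healthy
#' newborns and against the control group, and fold changes of each group
#' mean over the control mean. Contrasts whose groups carry no detected
#' values are skipped with a warning.
#'
#' @param marker_table Data.frame with `sample_id` plus one concentration
#'   column per marker (`NA` = undetected), e.g. from [quant_to_matrix()].
#' @param manifest Sample manifest.
#' @param markers Marker columns to report (default: all non-id columns).
#' @param control Control group id (default `"G05"`).
#' @param df_groups DF-affected group ids (default `c("G02", "G04")`).
#' @param healthy_pool Groups pooled as the healthy-newborn diabetic
#'   comparator (default `c("G01", "G03")`).
#' @return A list of class `"df_group_report"`: `summary`, `kruskal`,
#'   `contrasts`, `fold_changes` data.frames.
#' @export
compare_groups <- function(marker_table, manifest,
                           markers = setdiff(names(marker_table), "sample_id"),
                           control = "G05", df_groups = c("G02", "G04"),
                           healthy_pool = c("G01", "G03")) {
  grp <- setNames(manifest$group, manifest$sample_id)[marker_table$sample_id]
  if (anyNA(grp)) stop_invalid("marker_table contains unmanifested samples")
  groups <- sort(unique(manifest$group))

  summaries <- list(); kw <- list(); contrasts <- list(); folds <- list()
  for (m in markers) {
    vals <- lapply(setNames(groups, groups), function(g)
      na.omit(marker_table[[m]][grp == g]))
    nz <- vals[lengths(vals) > 0]
    s <- group_summaries(vals)
    s$marker <- m
    summaries[[m]] <- s
    if (length(nz) >= 2 && sum(lengths(nz)) >= 3) {
      k <- kruskal_wallis(nz)
      kw[[m]] <- data.frame(marker = m, statistic = k$statistic, df = k$df,
                            p_value = k$p_value, stringsAsFactors = FALSE)
    } else warning("marker ", m, ": too few detected groups for Kruskal-Wallis")

    pool <- na.omit(unlist(vals[healthy_pool], use.names = FALSE))
    for (g in df_groups) {
      for (cmp in list(c(paste0(g, " vs pooled ",
                                paste(healthy_pool, collapse = "+")), "pool"),
                       c(paste0(g, " vs ", control), "ctrl"))) {
        other <- if (cmp[2] == "pool") pool else vals[[control]]
        if (length(vals[[g]]) == 0L || length(other) == 0L) {
          warning("marker ", m, ": contrast ", cmp[1],
                  " skipped (empty group)")
          next
        }
        mw <- mann_whitney(vals[[g]], other)
        contrasts[[paste(m, cmp[1])]] <-
          data.frame(marker = m, contrast = cmp[1], statistic = mw$statistic,
                     p_value = mw$p_value, stringsAsFactors = FALSE)
      }
    }
    if (length(vals[[control]]))
      folds[[m]] <- data.frame(
        marker = m, group = groups,
        fold_vs_control = vapply(groups, function(g)
          if (length(vals[[g]]))
            fold_change(mean(vals[[g]]), mean(vals[[control]]))
          else NA_real_, numeric(1)),
        stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
              kruskal = do.call(rbind, c(kw, list(make.row.names = FALSE))),
              contrasts = do.call(rbind, c(contrasts, list(make.row.names = FALSE))),
              fold_changes = do.call(rbind, c(folds, list(make.row.names = FALSE))))
  class(out) <- "df_group_report"
  out
}

#' @export
print.df_group_report <- function(x, ...) {
  cat("Group comparison report:",
      length(unique(x$summary$marker)), "marker(s)\n\n")
  cat("Kruskal-Wallis across groups:\n")
  print(x$kruskal, row.names = FALSE)
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("\nPairwise Mann-Whitney contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Dichotomize marker values at a group-blind median
#'
#' Utility for Fisher's-exact fidelity experiments on continuous markers:
#' splits values at the overall median and cross-tabulates against a
#' two-level grouping.
#'
#' @param values Numeric vector.
#' @param labels Logical or two-level factor of the same length.
#' @return A 2x2 contingency matrix (above/below median x label).
#' @export
dichotomize_at_median <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) != 2L) stop_invalid("labels must have 2 levels")
  table(values > median(values), labels)
}
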