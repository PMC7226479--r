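# Independent oracles used to freeze expected values: brute-force
# enumerations and closed forms, implemented without touching the package's
# own code paths.

# Closed-form simple OLS (textbook formulas).
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# Exact two-sided Mann-Whitney p by enumerating all C(n, n_a) arrangements
# (doubled smaller tail, capped at 1) -- only valid without ties.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  us <- vapply(utils::combn(n, na, simplify = FALSE), u_of, numeric(1))
  u_obs <- u_of(seq_len(na))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Two-sided Fisher exact p by enumerating every table with the observed
# margins and summing hypergeometric probabilities <= the observed one.
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper-tail (enrichment) p by direct summation.
oracle_hyper_tail <- function(k, K, N, n) {
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Trapezoidal area under the empirical ROC, built directly from threshold
# sweeps (independent of the package's roc_curve()).
oracle_auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- sort(unique(scores))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- c(1, fpr, 0); tpr <- c(1, tpr, 0)
  sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# Grid-search inversion of a log-log calibration line to ~1e-8 relative.
oracle_invert_curve <- function(slope, intercept, intensity) {
  f <- function(lc) abs(intercept + slope * lc - log10(intensity))
  lo <- -12; hi <- 12
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 2001)
    best <- grid[which.min(vapply(grid, f, numeric(1)))]
    step <- (hi - lo) / 2000
    lo <- best - step; hi <- best + step
  }
  10^((lo + hi) / 2)
}

# Monte-Carlo permutation p for the Kruskal-Wallis H (tie-corrected),
# independent of both kruskal.test and the package's enumeration.
oracle_kw_mc_p <- function(values, n_mc = 20000) {
  x <- unlist(values); sizes <- lengths(values)
  g <- rep(seq_along(sizes), sizes)
  h_stat <- function(xx) {
    r <- rank(xx)
    N <- length(r)
    s <- tapply(r, g, sum)
    h <- 12 / (N * (N + 1)) * sum(s^2 / sizes) - 3 * (N + 1)
    tc <- 1 - sum(vapply(table(r), function(t) t^3 - t, numeric(1))) / (N^3 - N)
    h / tc
  }
  h_obs <- h_stat(x)
  hs <- replicate(n_mc, h_stat(sample(x)))
  mean(hs >= h_obs - 1e-10)
}
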