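# Per-marker and integrative multi-marker ROC analysis. AUC is computed by
# rank (pair) counting with ties scored 1/2; the panel combiner is a
# ridge-stabilized logistic regression on z-scored markers (monotone-
# equivalent to LDA under binormality); confidence intervals come from a
# stratified percentile bootstrap; marker importance from leave-one-marker-
# out elimination.

#' Rank-based AUC
#'
#' `AUC = (# (pos, neg) pairs with pos > neg, ties counted 1/2) /
#' (n_pos * n_neg)`, computed from midranks.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors for the
#'   positive and negative class.
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(3, 1), c(2, 0))  # 0.75
auc_rank <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop_invalid("both classes must be non-empty")
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve
#'
#' False- and true-positive rates at every distinct score threshold
#' (classifying `score >= threshold` as positive), from (1,1) down to (0,0).
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels, TRUE = positive.
#' @return A data.frame `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels))
    stop_invalid("scores and logical labels must align")
  if (!any(labels) || all(labels)) stop_invalid("need both classes")
  th <- c(-Inf, sort(unique(scores)), Inf)
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[labels] >= t), numeric(1)))
}

#' Fit the integrative marker panel
#'
#' Z-scores each marker and fits a logistic regression of the class labels on
#' the standardized markers with a small L2 ridge penalty (`lambda`, default
#' 1e-6, on the slopes only) so complete separation still yields a finite
#' converged solution. The panel score is the linear predictor; the apparent
#' AUC is computed by rank counting.
#'
#' @param x Data.frame or matrix of marker values (>= 2 markers for
#'   elimination; 1 allowed); no missing values among included subjects.
#' @param labels Logical (or 0/1) labels, TRUE = positive class.
#' @param lambda Ridge penalty on standardized slopes.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class `"df_panel"`: `markers`, `coefficients`
#'   (intercept first), `center`, `scale`, `scores`, `auc`, `n_pos`,
#'   `n_neg`, `labels`, `x` (raw marker data), `converged`.
#' @export
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(100) + rep(c(0, 2), each = 50), b = rnorm(100))
#' fit <- df_panel(x, rep(c(FALSE, TRUE), each = 50))
#' fit$auc
df_panel <- function(x, labels, lambda = 1e-6, max_iter = 100, tol = 1e-10) {
  x <- as.data.frame(x)
  y <- as.numeric(as.logical(labels))
  if (nrow(x) != length(y)) stop_invalid("x and labels must align")
  if (anyNA(x) || anyNA(y))
    stop_invalid("missing marker values or labels are not allowed")
  if (length(unique(y)) < 2L) stop_invalid("labels contain a single class")
  if (ncol(x) < 1L) stop_invalid("need >= 1 marker")

  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, sd, numeric(1))
  if (any(scale == 0)) {
    warning("constant marker(s) carried with zero weight: ",
            paste(names(x)[scale == 0], collapse = ", "))
    scale[scale == 0] <- 1
  }
  X <- cbind(1, sweep(sweep(as.matrix(x), 2, center), 2, scale, "/"))

  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - 2 * pen %*% beta
    hess <- crossprod(X * w, X) + 2 * pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ridge IRLS did not fully converge in ", max_iter, " iterations")
  scores <- drop(X %*% beta)
  structure(list(
    markers = names(x),
    coefficients = setNames(drop(beta), c("(Intercept)", names(x))),
    center = center, scale = scale, lambda = lambda,
    scores = scores, labels = as.logical(y),
    auc = auc_rank(scores[y == 1], scores[y == 0]),
    n_pos = sum(y == 1), n_neg = sum(y == 0),
    x = x, converged = converged),
    class = "df_panel")
}

#' @export
coef.df_panel <- function(object, ...) object$coefficients

#' Panel score for new subjects
#'
#' @param object A `"df_panel"` object.
#' @param newdata Data.frame with the panel's marker columns; defaults to the
#'   training data.
#' @param type `"link"` for the linear panel score, `"response"` for the
#'   logistic probability.
#' @param ... Unused.
#' @return Numeric vector of scores or probabilities.
#' @export
predict.df_panel <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  s <- if (is.null(newdata)) object$scores else {
    miss <- setdiff(object$markers, names(newdata))
    if (length(miss)) stop_invalid("newdata lacks marker(s): ",
                                   paste(miss, collapse = ", "))
    Z <- sweep(sweep(as.matrix(newdata[object$markers]), 2, object$center),
               2, object$scale, "/")
    drop(cbind(1, Z) %*% object$coefficients)
  }
  if (type == "response") plogis(s) else s
}

#' @export
print.df_panel <- function(x, ...) {
  cat("Integrative marker panel (ridge-stabilized logistic score)\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("  n = %d positive / %d negative; apparent AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
summary.df_panel <- function(object, ...) {
  yp <- youden_point(object$scores, object$labels)
  out <- list(coef = coef(object), auc = object$auc,
              n_pos = object$n_pos, n_neg = object$n_neg,
              operating_point = yp)
  class(out) <- "summary.df_panel"
  out
}

#' @export
print.summary.df_panel <- function(x, ...) {
  cat(sprintf("Panel AUC = %.3f (%d pos / %d neg)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Operating point (Youden): threshold %.4g, sensitivity %.3f, specificity %.3f\n",
              x$operating_point$threshold, x$operating_point$sensitivity,
              x$operating_point$specificity))
  cat("Coefficients (z-scored markers):\n")
  print(x$coef)
  invisible(x)
}

#' Plot the panel ROC curve
#'
#' @param x A `"df_panel"` object.
#' @param ... Passed to [plot()].
#' @export
plot.df_panel <- function(x, ...) {
  rc <- roc_curve(x$scores, x$labels)
  plot(rc$fpr, rc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("Panel ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples subjects within each class, recomputes the rank AUC, and
#' returns the percentile interval.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling stream.
#' @return A list: `auc`, `ci` (length 2), `level`, `n_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = NULL) {
  labels <- as.logical(labels)
  n_boot <- check_count(n_boot, "n_boot", min = 200L)
  if (!any(labels) || all(labels)) stop_invalid("need both classes")
  pos <- scores[labels]; neg <- scores[!labels]
  with_seed(derive_seed(seed, "bootstrap"), {
    stat <- vapply(seq_len(n_boot), function(i)
      auc_rank(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
      numeric(1))
    a <- (1 - level) / 2
    list(auc = auc_rank(pos, neg),
         ci = unname(quantile(stat, c(a, 1 - a), type = 7)),
         level = level, n_boot = n_boot)
  })
}

#' Youden-optimal operating point
#'
#' Scans the midpoints between consecutive distinct scores (classifying
#' `score >= threshold` as positive) and returns the threshold maximizing
#' sensitivity + specificity - 1; ties resolve to the lowest threshold.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels.
#' @return A list: `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_point <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop_invalid("need both classes")
  u <- sort(unique(scores))
  th <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  sens <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!labels] < t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # which.max takes the first (lowest) on ties
  list(threshold = th[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' Leave-one-marker-out panel elimination
#'
#' Refits the panel without each marker in turn and reports the resulting
#' apparent AUC and its change from the full panel.
#'
#' @param panel A fitted `"df_panel"` with >= 2 markers.
#' @return A data.frame: `removed_marker`, `auc_without`, `delta_auc`,
#'   sorted by increasing `auc_without` (most damaging removal first).
#' @export
marker_elimination <- function(panel) {
  if (length(panel$markers) < 2L)
    stop_invalid("panel must have >= 2 markers")
  res <- do.call(rbind, lapply(panel$markers, function(m) {
    sub <- df_panel(panel$x[setdiff(panel$markers, m)], panel$labels,
                    lambda = panel$lambda)
    data.frame(removed_marker = m, auc_without = sub$auc,
               delta_auc = sub$auc - panel$auc, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$auc_without), ]
  rownames(res) <- NULL
  res
}

#' Full ROC characterization of a marker or panel score
#'
#' Bundles the rank AUC, stratified bootstrap CI and Youden operating point.
#'
#' @inheritParams bootstrap_auc_ci
#' @param name Identifier carried into the result.
#' @return A list of class `"roc_result"`: `marker_or_panel`, `auc`,
#'   `ci_95`, `sensitivity`, `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @export
roc_result <- function(scores, labels, name = "score", n_boot = 2000,
                       level = 0.95, seed = NULL) {
  labels <- as.logical(labels)
  bs <- bootstrap_auc_ci(scores, labels, n_boot, level, seed)
  yp <- youden_point(scores, labels)
  structure(list(marker_or_panel = name, auc = bs$auc, ci_95 = bs$ci,
                 sensitivity = yp$sensitivity, specificity = yp$specificity,
                 threshold = yp$threshold,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("%s: AUC = %.3f (95%% CI %.3f-%.3f), sens %.3f / spec %.3f at %.4g\n",
              x$marker_or_panel, x$auc, x$ci_95[1], x$ci_95[2],
              x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}
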