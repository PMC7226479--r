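# ROC machinery: rank AUC, curve construction, the logistic panel, bootstrap
# CI, Youden point and marker elimination.

test_that("rank AUC counts winning pairs with ties at one half", {
  expect_equal(auc_rank(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc_rank(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_rank(c(1, 1), c(1, 1)), 0.5)
  expect_error(auc_rank(numeric(0), 1), class = "fq_invalid")
})

test_that("rank AUC properties: monotone invariance and label flip", {
  set.seed(5)
  for (i in 1:10) {
    pos <- rnorm(20, 1); neg <- rnorm(15)
    a <- auc_rank(pos, neg)
    expect_equal(auc_rank(exp(pos), exp(neg)), a, tolerance = 1e-12)
    expect_equal(auc_rank(neg, pos), 1 - a, tolerance = 1e-12)
  }
})

test_that("pair counting equals trapezoidal ROC integration to 1e-12", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:40, 2)
    scores <- c(rnorm(n[1], 0.5), rnorm(n[2]))
    if (i %% 3 == 0) scores <- round(scores)  # force ties
    labels <- rep(c(TRUE, FALSE), n)
    expect_equal(auc_rank(scores[labels], scores[!labels]),
                 oracle_auc_trapezoid(scores, labels), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- rep(c(1, 0), c(30, 40))
  expect_equal(auc_rank(scores[labels == 1], scores[labels == 0]),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the empirical ROC curve spans (0,0) to (1,1)", {
  rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rc$fpr[1], 1); expect_equal(rc$tpr[1], 1)
  expect_equal(rc$fpr[nrow(rc)], 0); expect_equal(rc$tpr[nrow(rc)], 0)
  expect_true(all(diff(rc$fpr) <= 0) && all(diff(rc$tpr) <= 0))
})

test_that("a single-marker panel preserves the marker's AUC", {
  set.seed(13)
  x <- data.frame(m = c(rnorm(60, 1), rnorm(60)))
  labels <- rep(c(TRUE, FALSE), each = 60)
  panel <- df_panel(x, labels)
  expect_equal(panel$auc, auc_rank(x$m[labels], x$m[!labels]),
               tolerance = 1e-12)
})

test_that("ridge logistic matches glm on well-separated-but-finite data", {
  set.seed(17)
  x <- data.frame(a = rnorm(200), b = rnorm(200))
  eta <- 0.5 + 1.2 * scale(x$a)[, 1] - 0.7 * scale(x$b)[, 1]
  y <- runif(200) < plogis(eta)
  panel <- df_panel(x, y)
  z <- data.frame(a = scale(x$a)[, 1], b = scale(x$b)[, 1])
  ref <- glm(y ~ a + b, data = z, family = binomial())
  expect_equal(unname(coef(panel)), unname(coef(ref)), tolerance = 1e-4)
  expect_true(panel$converged)
})

test_that("an uninformative marker neither helps nor hurts the panel", {
  set.seed(19)
  n <- 250
  info <- c(rnorm(n, 1.2), rnorm(n))
  labels <- rep(c(TRUE, FALSE), each = n)
  solo <- df_panel(data.frame(info = info), labels)
  both <- df_panel(data.frame(info = info, junk = rnorm(2 * n)), labels)
  expect_lt(abs(both$auc - solo$auc), 0.02)
})

test_that("the fitted panel approaches the analytic binormal optimum", {
  # two independent binormal markers with unit variance and shifts d1, d2:
  # the optimal linear score has AUC pnorm(sqrt(d1^2 + d2^2) / sqrt(2))
  set.seed(23)
  n <- 2000; d1 <- 0.8; d2 <- 0.6
  x <- data.frame(m1 = c(rnorm(n, d1), rnorm(n)),
                  m2 = c(rnorm(n, d2), rnorm(n)))
  labels <- rep(c(TRUE, FALSE), each = n)
  panel <- df_panel(x, labels)
  expect_equal(panel$auc, pnorm(sqrt(d1^2 + d2^2) / sqrt(2)),
               tolerance = 0.02)
})

test_that("complete separation still yields a finite converged score", {
  x <- data.frame(m = c(1:10, 101:110))
  labels <- rep(c(FALSE, TRUE), each = 10)
  panel <- df_panel(x, labels)
  expect_true(all(is.finite(coef(panel))))
  expect_equal(panel$auc, 1)
})

test_that("panel predict is consistent between link and response", {
  set.seed(29)
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  panel <- df_panel(x, rbinom(50, 1, plogis(x$a)))
  s <- predict(panel, x)
  expect_equal(predict(panel), s, tolerance = 1e-12)
  expect_equal(predict(panel, x, type = "response"), plogis(s))
  expect_error(predict(panel, x["a"]), class = "fq_invalid")
})

test_that("the stratified bootstrap CI is deterministic and concentrates", {
  set.seed(2)
  scores <- c(rnorm(300, 10), rnorm(300))
  labels <- rep(c(TRUE, FALSE), each = 300)
  ci1 <- bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 3)
  ci2 <- bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 3)
  expect_identical(ci1, ci2)
  expect_equal(ci1$ci[2], 1)
  expect_lt(diff(ci1$ci), 0.05)
  expect_true(ci1$ci[1] <= ci1$auc && ci1$auc <= ci1$ci[2])
  expect_error(bootstrap_auc_ci(scores, labels, n_boot = 50),
               class = "fq_invalid")
})

test_that("the Youden point matches an exhaustive threshold scan", {
  pos <- c(0.9, 0.8, 0.4); neg <- c(0.6, 0.3, 0.2)
  scores <- c(pos, neg); labels <- rep(c(TRUE, FALSE), each = 3)
  yp <- youden_point(scores, labels)
  # brute force over a fine grid
  grid <- seq(0, 1, 1e-3)
  j <- vapply(grid, function(t)
    mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  expect_equal(yp$youden, max(j), tolerance = 1e-12)

  sep <- youden_point(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  # flipping labels under score negation mirrors the ROC: same optimum J,
  # with sensitivity and specificity exchanged across the mirrored thresholds
  yp_f <- youden_point(-scores, !labels)
  expect_equal(yp_f$youden, yp$youden, tolerance = 1e-12)
})

test_that("marker elimination quantifies each marker's contribution", {
  set.seed(31)
  n <- 250
  labels <- rep(c(TRUE, FALSE), each = n)
  info <- c(rnorm(n, 1.5), rnorm(n))
  x <- data.frame(info = info, junk = rnorm(2 * n))
  panel <- df_panel(x, labels)
  el <- marker_elimination(panel)
  expect_lt(abs(el$delta_auc[el$removed_marker == "junk"]), 0.02)
  expect_lt(abs(el$auc_without[el$removed_marker == "info"] - 0.5), 0.05)
  # removing from a 2-marker panel leaves the survivor's rank AUC
  expect_equal(el$auc_without[el$removed_marker == "junk"],
               auc_rank(info[labels], info[!labels]), tolerance = 1e-12)
  expect_error(marker_elimination(df_panel(x["info"], labels)),
               class = "fq_invalid")
})

test_that("roc_result bundles AUC, CI and operating point coherently", {
  set.seed(37)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(TRUE, FALSE), each = 40)
  rr <- roc_result(scores, labels, name = "demo", n_boot = 400, seed = 5)
  expect_s3_class(rr, "roc_result")
  expect_true(rr$ci_95[1] <= rr$auc && rr$auc <= rr$ci_95[2])
  expect_equal(rr$n_pos, 40L)
  expect_output(print(rr), "demo")
})
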