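# Spiked-standard calibration: replicate aggregation, CV gating, the
# prohibited low-amount margin, and ordinary least squares of
# log10(normalized intensity) on log10(concentration). The fitted curve is a
# classed model object ("df_calib") with the usual methods; predict() maps
# normalized intensities back to absolute concentrations with range and
# margin flags.

REJECTION_LEVELS <- c("none", "cv_fail", "top_cv_fail", "margin", "undetected")

#' Aggregate technical replicates into calibration points
#'
#' One calibration point per protein: arithmetic mean of the replicate
#' normalized intensities and their coefficient of variation (sample SD /
#' mean). Points with fewer than two detected replicates are marked
#' `undetected` and carry no CV.
#'
#' @param replicates Data.frame with columns `protein_id`,
#'   `nominal_conc_fmol_ul`, `on_column_fmol` and `norm_intensity` (one row
#'   per detected replicate).
#' @return A data.frame of calibration points: `protein_id`,
#'   `nominal_conc_fmol_ul`, `on_column_fmol`, `n_detected`,
#'   `mean_intensity`, `cv`, `selected`, `rejection_reason`.
#' @export
aggregate_replicates <- function(replicates) {
  need <- c("protein_id", "nominal_conc_fmol_ul", "on_column_fmol",
            "norm_intensity")
  if (!all(need %in% names(replicates)))
    stop_invalid("replicates must have columns: ", paste(need, collapse = ", "))
  sp <- split(replicates, replicates$protein_id)
  pts <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    m <- mean(d$norm_intensity)
    s <- if (n >= 2) sd(d$norm_intensity) else NA_real_
    if (n >= 2 && m == 0 && s > 0)
      stop_compute("undefined CV: zero mean with nonzero SD for protein ",
                   d$protein_id[1])
    cv <- if (n >= 2) { if (m == 0) 0 else s / m } else NA_real_
    data.frame(protein_id = d$protein_id[1],
               nominal_conc_fmol_ul = d$nominal_conc_fmol_ul[1],
               on_column_fmol = d$on_column_fmol[1],
               n_detected = n, mean_intensity = m, cv = cv,
               selected = n >= 2,
               rejection_reason = if (n >= 2) "none" else "undetected",
               stringsAsFactors = FALSE)
  }))
  pts <- pts[order(pts$nominal_conc_fmol_ul, pts$protein_id), ]
  rownames(pts) <- NULL
  pts
}

#' Coefficient-of-variation gate on calibration points
#'
#' Rejects points whose replicate CV exceeds `cv_max` (reason `cv_fail`), and
#' points at the top calibration concentration whose CV exceeds the stricter
#' `cv_max_top` (reason `top_cv_fail`). Recomputes CV-based decisions from
#' scratch, so the filter is idempotent; `undetected` and `margin` rejections
#' are left untouched.
#'
#' @param points Calibration-point data.frame from [aggregate_replicates()].
#' @param cv_max Maximum allowed CV (default 0.20).
#' @param cv_max_top Maximum CV at the top point (default 0.10); must satisfy
#'   `0 < cv_max_top <= cv_max`.
#' @param top_conc The top calibration concentration (fmol/uL, default 500).
#' @return `points` with updated `selected` / `rejection_reason`.
#' @export
cv_filter <- function(points, cv_max = 0.20, cv_max_top = 0.10,
                      top_conc = 500) {
  if (!(cv_max_top > 0 && cv_max_top <= cv_max))
    stop_invalid("need 0 < cv_max_top <= cv_max")
  reconsider <- points$rejection_reason %in% c("none", "cv_fail", "top_cv_fail")
  is_top <- abs(points$nominal_conc_fmol_ul - top_conc) <=
    1e-9 * max(top_conc, 1)
  reason <- points$rejection_reason
  reason[reconsider] <- "none"
  reason[reconsider & points$cv > cv_max] <- "cv_fail"
  reason[reconsider & is_top & points$cv > cv_max_top &
           points$cv <= cv_max] <- "top_cv_fail"
  points$rejection_reason <- reason
  points$selected <- reason == "none"
  points
}

#' Prohibited-margin gate on calibration points
#'
#' Rejects points whose on-column amount falls inside the half-open
#' prohibited band `[low, high)` fmol (reason `margin`). The boundary is
#' half-open so that the measured range starting exactly at the upper margin
#' is retained.
#'
#' @param points Calibration-point data.frame.
#' @param margin_fmol Length-2 numeric `c(low, high)` in on-column fmol.
#' @param injection_ul Injection volume (uL) used to recompute on-column
#'   amounts when `points` lacks an `on_column_fmol` column.
#' @return `points` with updated `selected` / `rejection_reason`.
#' @export
apply_prohibited_margin <- function(points, margin_fmol = c(0.5, 42),
                                    injection_ul = 2) {
  if (length(margin_fmol) != 2L || margin_fmol[1] >= margin_fmol[2])
    stop_invalid("margin_fmol must be c(low, high) with low < high")
  check_scalar_num(injection_ul, "injection_ul", positive = TRUE)
  oc <- if ("on_column_fmol" %in% names(points)) points$on_column_fmol
        else points$nominal_conc_fmol_ul * injection_ul
  inside <- oc >= margin_fmol[1] & oc < margin_fmol[2]
  hit <- inside & points$selected
  points$rejection_reason[hit] <- "margin"
  points$selected[hit] <- FALSE
  points
}

#' Fit the log-log calibration line
#'
#' Ordinary least squares of log10(mean normalized intensity) on
#' log10(nominal concentration) over the selected calibration points.
#'
#' @param points Calibration-point data.frame; only rows with
#'   `selected == TRUE` enter the fit. At least 3 selected points spanning at
#'   least 2 decades of concentration are required.
#' @param margin_fmol Prohibited on-column band carried into the fitted
#'   object for prediction-time flagging.
#' @param injection_ul Injection volume (uL) carried for the same purpose.
#' @return An object of class `"df_calib"`: list with `slope`, `intercept`
#'   (log10 intensity at 1 fmol/uL), `r_squared`, `valid_range_fmol_ul`,
#'   `n_points`, `points`, `margin_fmol`, `injection_ul` and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' pts <- data.frame(protein_id = c("a", "b", "c"),
#'                   nominal_conc_fmol_ul = c(1, 10, 100),
#'                   on_column_fmol = c(2, 20, 200),
#'                   n_detected = 6, mean_intensity = c(10, 100, 1000),
#'                   cv = 0, selected = TRUE, rejection_reason = "none")
#' fit <- fit_loglog(pts)
#' coef(fit)  # intercept 1, slope 1
fit_loglog <- function(points, margin_fmol = c(0.5, 42), injection_ul = 2) {
  sel <- points[points$selected, , drop = FALSE]
  if (nrow(sel) < 3L)
    stop_compute("insufficient calibration: ", nrow(sel),
                 " selected point(s), need >= 3")
  if (any(sel$mean_intensity <= 0))
    stop_compute("selected calibration points must have positive intensity")
  x <- log10(sel$nominal_conc_fmol_ul)
  if (diff(range(x)) < 2)
    stop_compute("selected points span ", signif(diff(range(x)), 3),
                 " decades; need >= 2")
  if (sd(x) == 0) stop_compute("degenerate calibration: zero variance in x")
  fit <- lm(log10(sel$mean_intensity) ~ x)
  # noiseless synthetic standards legitimately fit perfectly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2,
    valid_range_fmol_ul = range(sel$nominal_conc_fmol_ul),
    n_points = nrow(sel), points = points,
    margin_fmol = margin_fmol, injection_ul = injection_ul, lm_fit = fit),
    class = "df_calib")
}

#' Build a calibration curve from spiked-standard replicates
#'
#' The full calibration stage: per-replicate TIC normalization of raw
#' intensities, aggregation into one point per standard protein, the CV gates
#' (<= `cv_max` everywhere, <= `cv_max_top` at the top point), the prohibited
#' on-column margin, and the log-log regression.
#'
#' @param replicates Replicate intensity table as produced by
#'   [simulate_calibration_replicates()] (columns `replicate`, `protein_id`,
#'   `nominal_conc_fmol_ul`, `on_column_fmol`, `intensity`).
#' @inheritParams cv_filter
#' @inheritParams apply_prohibited_margin
#' @param normalize If TRUE (default) intensities are converted to per-
#'   replicate TIC fractions before aggregation; set FALSE if `intensity`
#'   is already normalized.
#' @return A `"df_calib"` object (see [fit_loglog()]).
#' @export
#' @examples
#' reg <- build_ups2_registry()
#' reps <- simulate_calibration_replicates(reg, noise = noise_model(seed = 1))
#' cal <- df_calibration(reps)
#' summary(cal)
df_calibration <- function(replicates, cv_max = 0.20, cv_max_top = 0.10,
                           top_conc = NULL, margin_fmol = c(0.5, 42),
                           injection_ul = 2, normalize = TRUE) {
  need <- c("replicate", "protein_id", "nominal_conc_fmol_ul", "intensity")
  if (!all(need %in% names(replicates)))
    stop_invalid("replicates must have columns: ", paste(need, collapse = ", "))
  if (!"on_column_fmol" %in% names(replicates))
    replicates$on_column_fmol <- replicates$nominal_conc_fmol_ul * injection_ul
  if (normalize) {
    tot <- tapply(replicates$intensity, replicates$replicate, sum)
    replicates$norm_intensity <- replicates$intensity /
      as.numeric(tot[as.character(replicates$replicate)])
  } else replicates$norm_intensity <- replicates$intensity
  if (is.null(top_conc)) top_conc <- max(replicates$nominal_conc_fmol_ul)
  pts <- aggregate_replicates(replicates)
  pts <- cv_filter(pts, cv_max, cv_max_top, top_conc)
  pts <- apply_prohibited_margin(pts, margin_fmol, injection_ul)
  fit_loglog(pts, margin_fmol, injection_ul)
}

#' Predict concentration from normalized intensity
#'
#' Inverts the calibration line: `C = 10^((log10 I - intercept) / slope)`.
#' Each prediction is flagged `extrapolated` if it falls outside the range of
#' selected calibration concentrations, and `unreliable_margin` if its
#' on-column amount (concentration x injection volume) falls inside the
#' prohibited band.
#'
#' @param object A `"df_calib"` object.
#' @param newdata Numeric vector of normalized intensities (> 0).
#' @param ... Unused.
#' @return A data.frame: `norm_intensity`, `conc_fmol_ul`, `extrapolated`,
#'   `unreliable_margin`.
#' @export
predict.df_calib <- function(object, newdata, ...) {
  if (missing(newdata))
    return(fitted(object$lm_fit))
  I <- as.numeric(newdata)
  if (any(!is.finite(I) | I <= 0))
    stop_invalid("normalized intensities must be positive and finite")
  if (object$slope == 0)
    stop_compute("non-invertible calibration: slope is 0")
  conc <- 10^((log10(I) - object$intercept) / object$slope)
  oc <- conc * object$injection_ul
  data.frame(
    norm_intensity = I, conc_fmol_ul = conc,
    extrapolated = conc < object$valid_range_fmol_ul[1] |
      conc > object$valid_range_fmol_ul[2],
    unreliable_margin = oc >= object$margin_fmol[1] & oc < object$margin_fmol[2])
}

#' @export
coef.df_calib <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.df_calib <- function(object, ...) residuals(object$lm_fit)

#' @export
fitted.df_calib <- function(object, ...) fitted(object$lm_fit)

#' @export
print.df_calib <- function(x, ...) {
  cat("Spiked-standard calibration curve (log10-log10 OLS)\n")
  cat(sprintf("  slope %.4f, intercept %.4f, r^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d selected points; valid range %.4g - %.4g fmol/uL\n",
              x$n_points, x$valid_range_fmol_ul[1], x$valid_range_fmol_ul[2]))
  cat(sprintf("  prohibited on-column margin [%g, %g) fmol at %g uL injected\n",
              x$margin_fmol[1], x$margin_fmol[2], x$injection_ul))
  invisible(x)
}

#' @export
summary.df_calib <- function(object, ...) {
  tally <- table(factor(object$points$rejection_reason,
                        levels = REJECTION_LEVELS))
  out <- list(coef = coef(object), r_squared = object$r_squared,
              valid_range_fmol_ul = object$valid_range_fmol_ul,
              n_points = object$n_points, rejection_tally = tally)
  class(out) <- "summary.df_calib"
  out
}

#' @export
print.summary.df_calib <- function(x, ...) {
  cat("Calibration fit\n")
  print(x$coef)
  cat(sprintf("r^2 = %.4f over %d points; valid range %.4g - %.4g fmol/uL\n",
              x$r_squared, x$n_points, x$valid_range_fmol_ul[1],
              x$valid_range_fmol_ul[2]))
  cat("Point disposition:\n")
  print(x$rejection_tally)
  invisible(x)
}

#' Plot a calibration curve
#'
#' Log-log scatter of calibration points (selected in black, rejected in
#' red) with the fitted line.
#'
#' @param x A `"df_calib"` object.
#' @param ... Passed to [plot()].
#' @export
plot.df_calib <- function(x, ...) {
  p <- x$points[x$points$mean_intensity > 0 & !is.na(x$points$mean_intensity), ]
  plot(log10(p$nominal_conc_fmol_ul), log10(p$mean_intensity),
       col = ifelse(p$selected, "black", "red"),
       pch = ifelse(p$selected, 19, 4),
       xlab = "log10 concentration (fmol/uL)",
       ylab = "log10 normalized intensity", ...)
  graphics::abline(x$intercept, x$slope)
  graphics::legend("topleft", c("selected", "rejected"), col = c("black", "red"),
                   pch = c(19, 4), bty = "n")
  invisible(x)
}
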