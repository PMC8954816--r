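# Weighted quadratic calibration curves, back-calculation, and the
# fit-for-purpose qualification statistics (+/-25% acceptance band).

#' Fit a 1/x^2-weighted quadratic calibration curve
#'
#' Fits `area_ratio = a*x^2 + b*x + c` by weighted least squares with
#' weights `1/nominal^2`, the standard bioanalytical choice that equalizes
#' relative (rather than absolute) residuals across a wide calibration
#' range. The quality metric is the Pearson correlation coefficient
#' between observed and fitted area ratios, which equals 1 exactly for
#' noiseless data.
#'
#' @param standards data.frame with columns `nominal_conc` (ng/mL, > 0) and
#'   `area_ratio` (analyte peak area / internal-standard peak area);
#'   typically duplicate standards at each level.
#' @param min_levels minimum number of distinct concentration levels
#'   (default 6; the qualification design uses 8).
#' @return an object of class `calibration_fit` with components
#'   `coefficients` (`c`, `b`, `a` — intercept, linear, quadratic),
#'   `corr_coeff`, `range` (`lloq`, `uloq` = min/max nominal), `fitted`,
#'   `residuals`, `weights` and `data`.
#' @seealso [back_calculate()], [predict.calibration_fit()]
#' @examples
#' batch <- sim_calibration_batch(seed = 1)
#' fit <- fit_calibration(batch$standards)
#' fit$corr_coeff
#' @export
fit_calibration <- function(standards, min_levels = 6L) {
  stopifnot(all(c("nominal_conc", "area_ratio") %in% names(standards)))
  x <- as.numeric(standards$nominal_conc)
  y <- as.numeric(standards$area_ratio)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all nominal concentrations must be positive")
  if (any(!is.finite(y)) || any(y < 0))
    stop("area ratios must be non-negative")
  n_lev <- length(unique(x))
  if (n_lev < 3L) stop("calibration is underdetermined: need >= 3 distinct levels")
  if (n_lev < min_levels)
    stop(sprintf("need >= %d distinct calibration levels, got %d",
                 min_levels, n_lev))
  w <- 1 / x^2
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  structure(list(
    coefficients = c(c = unname(cf[1]), b = unname(cf[2]), a = unname(cf[3])),
    corr_coeff = stats::cor(y, fitted),
    range = c(lloq = min(x), uloq = max(x)),
    weighting = "1/x^2",
    fitted = fitted,
    residuals = y - fitted,
    weights = w,
    data = data.frame(nominal_conc = x, area_ratio = y)
  ), class = "calibration_fit")
}

#' @export
coef.calibration_fit <- function(object, ...) object$coefficients

#' @export
residuals.calibration_fit <- function(object, ...) object$residuals

#' Predicted area ratio at given concentrations
#'
#' Evaluates the forward calibration model `a*conc^2 + b*conc + c`.
#'
#' @param object a `calibration_fit`.
#' @param conc concentrations (ng/mL); defaults to the fitted standards.
#' @param ... unused.
#' @return predicted area ratios.
#' @export
predict.calibration_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) return(object$fitted)
  cf <- object$coefficients
  cf[["a"]] * conc^2 + cf[["b"]] * conc + cf[["c"]]
}

#' @export
print.calibration_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Weighted quadratic calibration (weights 1/x^2)\n")
  cat(sprintf("  ratio = %.6g*x^2 + %.6g*x + %.6g\n",
              cf[["a"]], cf[["b"]], cf[["c"]]))
  cat(sprintf("  range: %.4g - %.4g ng/mL,  r = %.4f,  n = %d\n",
              x$range[["lloq"]], x$range[["uloq"]], x$corr_coeff,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  bc <- back_calculate(object$data$area_ratio, object)
  acc <- bc$conc / object$data$nominal_conc * 100
  out <- list(fit = object,
              back_calc = data.frame(nominal_conc = object$data$nominal_conc,
                                     measured = bc$conc, accuracy_pct = acc))
  class(out) <- "summary.calibration_fit"
  out
}

#' @export
print.summary.calibration_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBack-calculated standards:\n")
  agg <- stats::aggregate(accuracy_pct ~ nominal_conc, data = x$back_calc, mean)
  agg$accuracy_pct <- signif(agg$accuracy_pct, 3)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$nominal_conc, d$area_ratio, log = "xy",
                 xlab = "Nominal concentration (ng/mL)",
                 ylab = "Area ratio (analyte / ISTD)", ...)
  xs <- exp(seq(log(x$range[["lloq"]]), log(x$range[["uloq"]]),
                length.out = 200))
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts the quadratic calibration model by solving
#' `a*x^2 + b*x + (c - ratio) = 0` and selecting the real root in
#' `[0, 2*ULOQ]`; when both roots qualify, the one inside the calibrated
#' range wins, and a still-ambiguous inversion is an error rather than a
#' guess. The result is multiplied by `dilution_factor`. Values outside
#' the calibrated range (before dilution correction) are flagged BLQ / ALQ
#' but never clamped.
#'
#' @param area_ratio numeric vector of observed area ratios.
#' @param fit a [fit_calibration()] object.
#' @param dilution_factor dilution factor (>= 1) applied to each sample.
#' @return data.frame with columns `conc` (ng/mL, dilution-corrected) and
#'   `flag` (`"ok"`, `"BLQ"`, `"ALQ"`).
#' @export
back_calculate <- function(area_ratio, fit, dilution_factor = 1) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  cf <- fit$coefficients
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
  lloq <- fit$range[["lloq"]]; uloq <- fit$range[["uloq"]]
  dilution_factor <- rep_len(dilution_factor, length(area_ratio))
  one <- function(ratio) {
    if (abs(a) < .Machine$double.eps * max(1, abs(b))) {
      if (b == 0) stop("degenerate calibration: a = b = 0")
      roots <- (ratio - cc) / b
    } else {
      disc <- b^2 - 4 * a * (cc - ratio)
      if (disc < 0) stop(sprintf("no real root for area ratio %.6g", ratio))
      roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    }
    adm <- roots[roots >= 0 & roots <= 2 * uloq]
    if (length(adm) == 0L)
      stop(sprintf("no admissible root in [0, %.4g] for area ratio %.6g",
                   2 * uloq, ratio))
    if (length(adm) > 1L) {
      inside <- adm[adm >= lloq & adm <= uloq]
      if (length(inside) == 1L) adm <- inside
      else stop(sprintf("ambiguous calibration inversion for area ratio %.6g",
                        ratio))
    }
    adm
  }
  conc <- vapply(area_ratio, one, 0)
  flag <- ifelse(conc < lloq, "BLQ", ifelse(conc > uloq, "ALQ", "ok"))
  data.frame(conc = conc * dilution_factor, flag = flag,
             stringsAsFactors = FALSE)
}

#' Mean accuracy and precision of replicate measurements
#'
#' Mean accuracy is `mean(measured)/nominal * 100`; precision is the
#' coefficient of variation `sd(measured)/mean(measured) * 100` using the
#' sample (n-1) standard deviation. Both are scale-equivariant.
#'
#' @param measured numeric vector of measured concentrations (ng/mL).
#' @param nominal the nominal (theoretical) concentration (> 0).
#' @return list with `mean_accuracy_pct`, `cv_pct`, `n`, `mean_measured`.
#'   `cv_pct` is `NA` for a single replicate.
#' @examples
#' accuracy_precision(c(14.5, 15.0, 15.5), 15.0)  # 100%, 3.33%
#' @export
accuracy_precision <- function(measured, nominal) {
  if (length(measured) == 0L) stop("no measurements supplied")
  if (!is.finite(nominal) || nominal <= 0) stop("nominal must be positive")
  m <- mean(measured)
  list(mean_accuracy_pct = m / nominal * 100,
       cv_pct = if (length(measured) >= 2L) stats::sd(measured) / m * 100 else NA_real_,
       n = length(measured),
       mean_measured = m)
}

qc_eval_row <- function(run, condition, nominal, measured, criteria_pct) {
  ap <- accuracy_precision(measured, nominal)
  data.frame(run = run, condition = condition, nominal_conc = nominal,
             n = ap$n, mean_measured = ap$mean_measured,
             mean_accuracy_pct = ap$mean_accuracy_pct, cv_pct = ap$cv_pct,
             pass = ap$mean_accuracy_pct >= 100 - criteria_pct &
                    ap$mean_accuracy_pct <= 100 + criteria_pct,
             stringsAsFactors = FALSE)
}

#' Intra- and inter-run QC evaluation
#'
#' Computes per-run (intra) accuracy/precision at each QC level and an
#' inter-run evaluation pooling all replicates of all runs, with pass
#' flags against a symmetric acceptance band (default +/-25%, the
#' fit-for-purpose criterion for discovery-stage assays).
#'
#' @param qc data.frame with columns `run_id`, `nominal_conc` and
#'   `measured_conc` (back-calculated, dilution-corrected).
#' @param criteria_pct half-width of the acceptance band in percent.
#' @param levels optional vector of known QC levels; when given, a QC row
#'   whose nominal is not one of them is an error.
#' @return data.frame of QC evaluations: one row per run x level plus
#'   `"inter-run"` rows pooling runs per level.
#' @export
evaluate_run <- function(qc, criteria_pct = 25, levels = NULL) {
  stopifnot(all(c("run_id", "nominal_conc", "measured_conc") %in% names(qc)))
  if (!is.null(levels) && any(!qc$nominal_conc %in% levels))
    stop("unknown QC level: ",
         paste(unique(qc$nominal_conc[!qc$nominal_conc %in% levels]),
               collapse = ", "))
  rows <- list()
  for (run in unique(qc$run_id)) {
    sub <- qc[qc$run_id == run, ]
    for (nom in sort(unique(sub$nominal_conc))) {
      rows[[length(rows) + 1L]] <- qc_eval_row(
        as.character(run), "intra-run", nom,
        sub$measured_conc[sub$nominal_conc == nom], criteria_pct)
    }
  }
  for (nom in sort(unique(qc$nominal_conc))) {
    rows[[length(rows) + 1L]] <- qc_eval_row(
      "all", "inter-run", nom,
      qc$measured_conc[qc$nominal_conc == nom], criteria_pct)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dilution integrity evaluation
#'
#' Assesses whether samples above the calibrated range can be diluted into
#' range without bias: the supplied measurements must already include the
#' dilution factor (see [back_calculate()]), and are compared to the
#' theoretical pre-dilution concentration with the usual accuracy/precision
#' statistics and acceptance band.
#'
#' @param measured dilution-corrected measured concentrations (ng/mL).
#' @param dilution_factor the fold-dilution applied (>= 1; 5, 10 and 30 in
#'   the qualification design).
#' @param theoretical the theoretical (pre-dilution) concentration.
#' @param criteria_pct acceptance half-width in percent.
#' @return one QC-evaluation row (see [evaluate_run()]) with a
#'   `dilution_factor` column.
#' @export
dilution_integrity <- function(measured, dilution_factor, theoretical,
                               criteria_pct = 25) {
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  out <- qc_eval_row("dilution", sprintf("%g-fold", dilution_factor),
                     theoretical, measured, criteria_pct)
  out$dilution_factor <- dilution_factor
  out
}

#' Stability evaluation by storage condition
#'
#' Groups condition-labelled QC measurements (e.g. `short_term`,
#' `long_term`, `freeze_thaw`) by condition and level and applies the
#' accuracy/precision statistics with the acceptance band.
#'
#' @param qc data.frame with columns `condition`, `nominal_conc`,
#'   `measured_conc`.
#' @param criteria_pct acceptance half-width in percent.
#' @return data.frame of QC evaluations, one row per condition x level.
#' @export
stability_evaluate <- function(qc, criteria_pct = 25) {
  stopifnot(all(c("condition", "nominal_conc", "measured_conc") %in% names(qc)))
  rows <- list()
  for (cond in unique(qc$condition)) {
    sub <- qc[qc$condition == cond, ]
    for (nom in sort(unique(sub$nominal_conc))) {
      rows[[length(rows) + 1L]] <- qc_eval_row(
        "stability", cond, nom,
        sub$measured_conc[sub$nominal_conc == nom], criteria_pct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
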