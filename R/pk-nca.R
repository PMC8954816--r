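# Non-compartmental IV-bolus pharmacokinetics, Hamilton AUC-proportional
# pooling, and dose-proportionality assessment.

#' Build a concentration-time profile
#'
#' @param subject_id subject label.
#' @param dose dose in mg/kg (> 0).
#' @param times sampling times in minutes, strictly increasing.
#' @param concs concentrations in ng/mL (>= 0).
#' @param blq logical mask of below-limit-of-quantification observations;
#'   default none.
#' @return a list of class `pk_profile`.
#' @export
pk_profile <- function(subject_id, dose, times, concs, blq = NULL) {
  times <- as.numeric(times); concs <- as.numeric(concs)
  if (length(times) != length(concs)) stop("times and concs lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  if (is.null(blq)) blq <- rep(FALSE, length(times))
  stopifnot(length(blq) == length(times))
  structure(list(subject_id = as.character(subject_id), dose = dose,
                 times = times, concs = concs, blq = as.logical(blq)),
            class = "pk_profile")
}

#' Linear trapezoidal AUC and AUMC
#'
#' Area under `c(t)` and under `t*c(t)` by the linear trapezoidal rule up
#' to the last supplied point.
#'
#' @param times sampling times (minutes), strictly increasing, >= 2 points.
#' @param concs concentrations (ng/mL).
#' @return list with `auc_last` (min*ng/mL) and `aumc_last` (min^2*ng/mL).
#' @export
auc_trapezoid <- function(times, concs) {
  if (length(times) < 2L) stop("need at least 2 points for a trapezoid")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) != length(concs)) stop("times and concs lengths differ")
  dt <- diff(times)
  list(auc_last = sum(dt * (utils::head(concs, -1) + utils::tail(concs, -1)) / 2),
       aumc_last = sum(dt * (utils::head(times * concs, -1) +
                             utils::tail(times * concs, -1)) / 2))
}

#' Terminal elimination rate constant (lambda-z)
#'
#' Fits `log(conc)` against time by ordinary least squares over candidate
#' terminal windows — the last k points for k = 3 up to all positive
#' post-Tmax points, always excluding Tmax itself — and keeps the window
#' with the highest adjusted R-squared, ties broken toward more points.
#' The slope must be negative (`lambda_z > 0`), otherwise the terminal
#' phase is undefined.
#'
#' @param times,concs the profile (or pass a [pk_profile()] as `times`).
#' @return list with `lambda_z` (1/min), `n_points`, `adj_r2`,
#'   `intercept` (log ng/mL) and `t_half` = ln(2)/lambda_z (min).
#' @export
fit_lambda_z <- function(times, concs = NULL) {
  if (inherits(times, "pk_profile")) { concs <- times$concs; times <- times$times }
  keep <- concs > 0
  # trailing BLQ/zero observations carry no terminal-phase information
  times <- times[keep]; concs <- concs[keep]
  i_max <- which.max(concs)
  post <- seq_along(times) > i_max
  if (sum(post) < 3L)
    stop("need >= 3 positive post-Tmax points for lambda-z")
  t_post <- times[post]; c_post <- concs[post]
  n <- length(t_post)
  best <- NULL
  for (k in 3:n) {
    idx <- (n - k + 1):n
    # a window with no real log-decline (flat profile) has no terminal phase
    if (diff(range(log(c_post[idx]))) < 1e-10) next
    f <- stats::lm(log(c_post[idx]) ~ t_post[idx])
    slope <- unname(stats::coef(f)[2])
    if (!is.finite(slope) || slope >= 0) next
    r2 <- suppressWarnings(summary(f)$adj.r.squared)  # noiseless data fits exactly
    if (!is.finite(r2)) next  # zero-variance window (flat profile)
    if (is.null(best) || r2 > best$adj_r2 + 1e-12 ||
        (abs(r2 - best$adj_r2) <= 1e-12 && k > best$n_points)) {
      best <- list(lambda_z = -slope, n_points = k, adj_r2 = r2,
                   intercept = unname(stats::coef(f)[1]))
    }
  }
  if (is.null(best))
    stop("terminal phase undefined: no window with a negative slope")
  best$t_half <- log(2) / best$lambda_z
  best
}

#' Non-compartmental analysis of an IV-bolus profile
#'
#' Model-free PK parameter estimation: Cmax/Tmax are read off the maximum
#' observation; AUC/AUMC to the last point use the linear trapezoidal rule,
#' with the 0-to-first-sample segment covered by log-linear
#' back-extrapolation of C(0) from the first two positive concentrations
#' (an IV bolus has its true maximum at t = 0); the extrapolated tails are
#' `clast/lambda_z` for AUC and `clast*tlast/lambda_z + clast/lambda_z^2`
#' for AUMC. Clearance uses the extrapolated AUC:
#' `Cl = dose / AUC_inf` (dose converted to ng/kg so Cl is in mL/min/kg),
#' `MRT = AUMC_inf/AUC_inf`, `Vss = Cl * MRT`.
#'
#' @param profile a [pk_profile()].
#' @param extrapolate_c0 back-extrapolate C(0) log-linearly from the first
#'   two positive concentrations (default `TRUE`); when `FALSE`, AUC starts
#'   at the first sample.
#' @return object of class `nca_result`: list with `cmax` (ng/mL), `tmax`
#'   (min), `c0`, `auc_last`, `auc_inf` (min*ng/mL), `aumc_last`,
#'   `aumc_inf` (min^2*ng/mL), `lambda_z` (1/min), `lambda_z_n_points`,
#'   `lambda_z_adj_r2`, `t_half` (min), `cl` (mL/min/kg), `mrt` (min),
#'   `vss` (mL/kg), `dose`, `subject_id`.
#' @export
nca_iv_bolus <- function(profile, extrapolate_c0 = TRUE) {
  stopifnot(inherits(profile, "pk_profile"))
  times <- profile$times; concs <- profile$concs
  concs[profile$blq & seq_along(concs) < which.max(concs > 0)] <- 0
  # drop trailing BLQ observations
  pos <- which(concs > 0)
  if (length(pos) == 0L) stop("profile is entirely BLQ")
  last_pos <- max(pos)
  times_q <- times[seq_len(last_pos)]; concs_q <- concs[seq_len(last_pos)]
  i_max <- which.max(concs_q)
  cmax <- concs_q[i_max]; tmax <- times_q[i_max]
  c0 <- NA_real_
  if (extrapolate_c0 && times_q[1] > 0 && length(pos) >= 2L) {
    i1 <- pos[1]; i2 <- pos[2]
    slope <- (log(concs[i2]) - log(concs[i1])) / (times[i2] - times[i1])
    c0 <- exp(log(concs[i1]) - slope * times[i1])
    times_q <- c(0, times_q); concs_q <- c(c0, concs_q)
  }
  auc <- auc_trapezoid(times_q, concs_q)
  lz <- fit_lambda_z(times, concs)
  clast <- concs_q[length(concs_q)]; tlast <- times_q[length(times_q)]
  auc_inf <- auc$auc_last + clast / lz$lambda_z
  aumc_inf <- auc$aumc_last + clast * tlast / lz$lambda_z +
    clast / lz$lambda_z^2
  dose_ng_kg <- profile$dose * 1e6  # mg/kg -> ng/kg
  cl <- dose_ng_kg / auc_inf        # mL/min/kg
  mrt <- aumc_inf / auc_inf
  structure(list(subject_id = profile$subject_id, dose = profile$dose,
                 cmax = cmax, tmax = tmax, c0 = c0,
                 auc_last = auc$auc_last, auc_inf = auc_inf,
                 aumc_last = auc$aumc_last, aumc_inf = aumc_inf,
                 lambda_z = lz$lambda_z, lambda_z_n_points = lz$n_points,
                 lambda_z_adj_r2 = lz$adj_r2, t_half = lz$t_half,
                 cl = cl, mrt = mrt, vss = cl * mrt),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA (IV bolus) subject %s, dose %g mg/kg\n",
              x$subject_id, x$dose))
  cat(sprintf("  Cmax %.4g ng/mL @ %g min   T1/2 %.4g min (lambda-z %.4g /min, %d pts, adj R2 %.4f)\n",
              x$cmax, x$tmax, x$t_half, x$lambda_z, x$lambda_z_n_points,
              x$lambda_z_adj_r2))
  cat(sprintf("  AUClast %.6g  AUCinf %.6g min*ng/mL   Cl %.4g mL/min/kg   Vss %.4g mL/kg   MRT %.4g min\n",
              x$auc_last, x$auc_inf, x$cl, x$vss, x$mrt))
  invisible(x)
}

#' Summarize NCA results by dose group
#'
#' Mean and SD of the headline parameters per dose group, the layout of a
#' standard PK summary table.
#'
#' @param results list of [nca_iv_bolus()] results.
#' @param params parameters to summarize.
#' @return data.frame with one row per dose, columns `<param>_mean` /
#'   `<param>_sd` plus `n`.
#' @export
nca_summary <- function(results,
                        params = c("t_half", "cmax", "auc_last", "cl", "vss")) {
  stopifnot(length(results) > 0)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(dose = r$dose, as.data.frame(r[params]))))
  doses <- sort(unique(df$dose))
  out <- data.frame(dose = doses, n = NA_integer_)
  for (p in params) {
    out[[paste0(p, "_mean")]] <- NA_real_
    out[[paste0(p, "_sd")]] <- NA_real_
  }
  for (i in seq_along(doses)) {
    sub <- df[df$dose == doses[i], ]
    out$n[i] <- nrow(sub)
    for (p in params) {
      out[[paste0(p, "_mean")]][i] <- mean(sub[[p]])
      out[[paste0(p, "_sd")]][i] <- stats::sd(sub[[p]])
    }
  }
  out
}

#' Hamilton AUC-proportional pooling weights
#'
#' Per-time-point relative plasma volumes proportional to the trapezoidal
#' time weights `(t[i+1] - t[i-1])/2` (half-intervals at the ends),
#' normalized to sum to 1. Pooling aliquots with these volumes makes the
#' pooled concentration equal `AUC_last / (t_last - t_first)` for any
#' profile, so a single pooled sample represents the average exposure.
#'
#' @param times sampling times in minutes (>= 2 points, increasing).
#' @return numeric vector of fractional volume weights summing to 1
#'   (class `pooling_plan`).
#' @examples
#' hamilton_pool(c(0, 1, 2, 3, 4))  # 0.125 0.25 0.25 0.25 0.125
#' @export
hamilton_pool <- function(times) {
  if (length(times) < 2L) stop("need >= 2 time points to pool")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  w <- numeric(n)
  w[1] <- (times[2] - times[1]) / 2
  w[n] <- (times[n] - times[n - 1]) / 2
  if (n > 2L)
    w[2:(n - 1)] <- (times[3:n] - times[1:(n - 2)]) / 2
  structure(w / sum(w), class = "pooling_plan")
}

#' @export
print.pooling_plan <- function(x, ...) {
  cat("Hamilton pooling weights:\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Concentration of a Hamilton-pooled sample
#'
#' The volume-weighted mean concentration, equal to
#' `AUC_last / (t_last - t_first)` by construction of the weights.
#'
#' @param times,concs the profile.
#' @return pooled concentration (ng/mL).
#' @export
pooled_concentration <- function(times, concs) {
  sum(hamilton_pool(times) * concs)
}

#' Dose-proportionality assessment
#'
#' Dose-normalized AUC and Cmax ratios between consecutive dose levels,
#' plus the power-model exponent from ordinary least squares of `log(AUC)`
#' on `log(dose)` (exponent 1 = exactly proportional). A dose-normalized
#' AUC ratio above `threshold` flags supra-proportionality, i.e. exposure
#' growing faster than dose, the signature of saturable elimination.
#'
#' @param dose numeric vector of dose levels (>= 2).
#' @param auc AUC per dose level (group means are fine).
#' @param cmax optional Cmax per dose level.
#' @param threshold dose-normalized AUC ratio above which a dose step is
#'   flagged supra-proportional (default 1.25).
#' @return list of class `dose_proportionality`: `steps` data.frame (one
#'   row per consecutive dose pair with `auc_ratio_norm`,
#'   `cmax_ratio_norm`, `supra_proportional`), `power_exponent`, and
#'   `supra_proportional` (any step flagged).
#' @export
dose_proportionality <- function(dose, auc, cmax = NULL, threshold = 1.25) {
  if (length(dose) < 2L) stop("need >= 2 dose levels")
  stopifnot(length(auc) == length(dose))
  ord <- order(dose)
  dose <- dose[ord]; auc <- auc[ord]
  if (!is.null(cmax)) cmax <- cmax[ord]
  i <- seq_len(length(dose) - 1L)
  auc_norm <- auc / dose
  steps <- data.frame(
    dose_from = dose[i], dose_to = dose[i + 1L],
    auc_ratio_norm = auc_norm[i + 1L] / auc_norm[i],
    cmax_ratio_norm = if (is.null(cmax)) NA_real_
                      else (cmax[i + 1L] / dose[i + 1L]) / (cmax[i] / dose[i])
  )
  steps$supra_proportional <- steps$auc_ratio_norm > threshold
  exponent <- unname(stats::coef(stats::lm(log(auc) ~ log(dose)))[2])
  structure(list(steps = steps, power_exponent = exponent,
                 threshold = threshold,
                 supra_proportional = any(steps$supra_proportional)),
            class = "dose_proportionality")
}

#' @export
print.dose_proportionality <- function(x, ...) {
  cat(sprintf("Dose proportionality (power exponent %.3f, threshold %.3g):\n",
              x$power_exponent, x$threshold))
  s <- x$steps
  s$auc_ratio_norm <- round(s$auc_ratio_norm, 3)
  s$cmax_ratio_norm <- round(s$cmax_ratio_norm, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
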