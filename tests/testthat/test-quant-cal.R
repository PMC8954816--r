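test_that("noiseless calibration recovers generating coefficients to machine precision", {
  batch <- sim_calibration_batch(seed = 4, noise_cv = 0)
  fit <- fit_calibration(batch$standards)
  expect_equal(unname(coef(fit)[c("a", "b", "c")]),
               unname(batch$coef[c("a", "b", "c")]), tolerance = 1e-10)
  expect_equal(fit$corr_coeff, 1, tolerance = 1e-12)
  expect_identical(unname(fit$range), c(1.02, 2220))
  expect_s3_class(fit, "calibration_fit")
})

test_that("5% proportional noise still yields correlation coefficient >= 0.99", {
  fit <- fit_calibration(sim_calibration_batch(seed = 1, noise_cv = 0.05)$standards)
  expect_gte(fit$corr_coeff, 0.99)
})

test_that("correlation approaches 1 as noise shrinks", {
  rs <- vapply(c(0.05, 0.01, 0), function(cv)
    fit_calibration(sim_calibration_batch(seed = 8, noise_cv = cv)$standards)$corr_coeff,
    0)
  expect_true(all(diff(rs) >= 0))
  expect_equal(rs[3], 1, tolerance = 1e-12)
})

test_that("underdetermined calibrations are rejected", {
  d <- data.frame(nominal_conc = c(1, 1, 10, 10), area_ratio = c(1, 1, 2, 2))
  expect_error(fit_calibration(d), "underdetermined|levels")
  d8 <- sim_calibration_batch(seed = 2)$standards
  expect_error(fit_calibration(d8[d8$nominal_conc < 30, ]), "levels")
  expect_error(fit_calibration(transform(d8, nominal_conc = -nominal_conc)),
               "positive")
})

test_that("weighted residuals are orthogonal to the design columns", {
  fit <- fit_calibration(sim_calibration_batch(seed = 9, noise_cv = 0.05)$standards)
  x <- fit$data$nominal_conc
  r <- residuals(fit)
  w <- fit$weights
  scale <- sum(abs(fit$data$area_ratio))
  for (col in list(rep(1, length(x)), x, x^2)) {
    expect_lt(abs(sum(w * r * col)) / scale, 1e-8)
  }
})

test_that("back-calculation inverts the forward model across the range and applies dilution", {
  fit <- fit_calibration(sim_calibration_batch(seed = 5, noise_cv = 0.05)$standards)
  concs <- exp(seq(log(1.02), log(2220), length.out = 25))
  bc <- back_calculate(predict(fit, concs), fit)
  expect_equal(bc$conc, concs, tolerance = 1e-6)
  expect_true(all(bc$flag == "ok"))
  # 10-fold dilution of a 6670 ng/mL sample measured at 667 in-range
  r667 <- predict(fit, 667)
  expect_equal(back_calculate(r667, fit, dilution_factor = 10)$conc, 6670,
               tolerance = 1e-6)
  # out-of-range flags, never clamped
  expect_identical(back_calculate(predict(fit, 0.5), fit)$flag, "BLQ")
  expect_identical(back_calculate(predict(fit, 3000), fit)$flag, "ALQ")
  expect_error(back_calculate(r667, fit, dilution_factor = 0.5), ">= 1")
})

test_that("a linear (a = 0) calibration inverts through its unique root", {
  x <- rep(c(1.02, 3.05, 9.14, 27.4, 82.3, 247, 741, 2220), each = 2)
  d <- data.frame(nominal_conc = x, area_ratio = 2e-3 * x + 1e-3)
  fit <- fit_calibration(d)
  expect_lt(abs(coef(fit)[["a"]]), 1e-12)
  expect_equal(back_calculate(predict(fit, 165), fit)$conc, 165,
               tolerance = 1e-8)
})

test_that("accuracy and precision follow the mean/nominal and sample-SD/mean definitions", {
  ap <- accuracy_precision(c(15, 15, 15), 15)
  expect_identical(ap$mean_accuracy_pct, 100)
  expect_identical(ap$cv_pct, 0)
  ap2 <- accuracy_precision(c(14.5, 15.0, 15.5), 15.0)
  expect_equal(ap2$mean_accuracy_pct, 100, tolerance = 1e-12)
  expect_equal(ap2$cv_pct, 3.33, tolerance = 1e-2)
  # dilution-integrity arithmetic from reported mean concentrations
  expect_equal(signif(accuracy_precision(7550, 6670)$mean_accuracy_pct, 3), 113)
  expect_equal(signif(accuracy_precision(19300, 20000)$mean_accuracy_pct, 3), 96.5)
  expect_error(accuracy_precision(numeric(0), 15), "no measurements")
  expect_error(accuracy_precision(c(1, 2), 0), "positive")
})

test_that("accuracy and precision are scale-equivariant", {
  set.seed(41)
  m <- rlnorm(6, log(100), 0.1)
  base <- accuracy_precision(m, 100)
  for (k in c(0.01, 3, 1e4)) {
    sc <- accuracy_precision(m * k, 100 * k)
    expect_equal(sc$mean_accuracy_pct, base$mean_accuracy_pct, tolerance = 1e-12)
    expect_equal(sc$cv_pct, base$cv_pct, tolerance = 1e-12)
  }
})

test_that("intra/inter-run evaluation pools runs and applies the +/-25% band", {
  set.seed(6)
  qc <- do.call(rbind, lapply(1:3, function(run) {
    data.frame(run_id = paste0("run", run),
               nominal_conc = rep(c(15, 165, 1820), each = 3),
               measured_conc = rep(c(15, 165, 1820), each = 3) *
                 rlnorm_like(9, 0.08))
  }))
  ev <- evaluate_run(qc)
  expect_identical(nrow(ev), 12L)  # 3 runs x 3 levels + 3 inter-run rows
  expect_true(all(ev$pass))
  inter <- ev[ev$condition == "inter-run", ]
  expect_identical(inter$n, rep(9L, 3))
  # a level biased to 70% fails
  bad <- qc
  bad$measured_conc[bad$nominal_conc == 15] <- 15 * 0.70
  expect_false(all(evaluate_run(bad)$pass))
  # single run: inter-run equals intra-run statistics
  one <- qc[qc$run_id == "run1", ]
  ev1 <- evaluate_run(one)
  expect_equal(ev1$mean_accuracy_pct[ev1$condition == "intra-run"],
               ev1$mean_accuracy_pct[ev1$condition == "inter-run"])
  expect_error(evaluate_run(qc, levels = c(15, 165)), "unknown QC level")
})

test_that("dilution integrity reproduces reported accuracies from mean concentrations", {
  # 5-fold: mean 7550 vs theoretical 6670
  d5 <- dilution_integrity(c(7550, 7550, 7550), 5, 6670)
  expect_equal(signif(d5$mean_accuracy_pct, 3), 113)
  expect_true(d5$pass)
  # 10-fold: 19300 vs 20000
  d10 <- dilution_integrity(rep(19300, 3), 10, 20000)
  expect_equal(signif(d10$mean_accuracy_pct, 3), 96.5)
  # 30-fold: 6220/6670 rounds half-up to 93.3 at 3 s.f.
  d30 <- dilution_integrity(rep(6220, 3), 30, 6670)
  expect_equal(signif(d30$mean_accuracy_pct, 3), 93.3)
  expect_identical(dilution_integrity(20000, 1, 20000)$mean_accuracy_pct, 100)
  expect_error(dilution_integrity(100, 0.5, 100), ">= 1")
})

test_that("stability evaluation groups by condition and flags degraded sets", {
  set.seed(12)
  qc <- expand.grid(condition = c("short_term", "long_term", "freeze_thaw"),
                    nominal_conc = c(15, 165, 1820), rep = 1:3,
                    stringsAsFactors = FALSE)
  qc$measured_conc <- qc$nominal_conc * rlnorm_like(nrow(qc), 0.05)
  st <- stability_evaluate(qc)
  expect_identical(nrow(st), 9L)
  expect_true(all(st$pass))
  # 117% mean accuracy passes the +/-25% band; 60% fails
  hot <- data.frame(condition = "freeze_thaw", nominal_conc = 165,
                    measured_conc = 165 * 1.17)
  expect_true(stability_evaluate(hot)$pass)
  cold <- data.frame(condition = "long_term", nominal_conc = 165,
                     measured_conc = 165 * 0.60)
  expect_false(stability_evaluate(cold)$pass)
})
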