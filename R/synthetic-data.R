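# Seeded generators emulating every input the wet-lab study produced:
# duplicate 8-level calibration batches, triplicate QC sets, two-compartment
# IV-bolus profiles on the study sampling grid, and paired (+/- TiCl3)
# peak tables with product-ion spectra from a ground-truth metabolite set.

#' Study calibration and QC concentration levels
#'
#' The eight standard levels (1.02-2220 ng/mL) and three QC levels used in
#' the qualification design.
#' @name study_levels
#' @export
CAL_LEVELS <- c(1.02, 3.05, 9.14, 27.4, 82.3, 247, 741, 2220)

#' @rdname study_levels
#' @export
QC_LEVELS <- c(15.0, 165, 1820)

#' Study blood-sampling grid (minutes)
#' @export
PK_TIMES <- c(2, 10, 30, 60, 120, 240, 420)

# mean-1 multiplicative lognormal noise at a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a calibration batch with QC sets
#'
#' Area ratios are generated from a quadratic forward model
#' `a*x^2 + b*x + c` with mean-1 multiplicative lognormal noise at the
#' requested CV — the natural noise model for a ratio of positive peak
#' areas. Duplicate standards per level and triplicate QCs per level, as
#' in the qualification design. Identical seeds give identical batches.
#'
#' @param seed integer RNG seed.
#' @param noise_cv proportional noise CV (fraction, < 0.5).
#' @param levels standard concentrations (ng/mL); default [CAL_LEVELS].
#' @param qc_levels QC concentrations; default [QC_LEVELS].
#' @param coef generating coefficients `c(a, b, c)` of the quadratic;
#'   defaults give a mildly saturating, monotone response over
#'   `[0, 2*ULOQ]`.
#' @param n_std,n_qc replicates per standard / QC level.
#' @return list with `standards` and `qc` data.frames (`level_id`,
#'   `nominal_conc`, `area_ratio`, `replicate`) and the generating `coef`.
#' @export
sim_calibration_batch <- function(seed = 1, noise_cv = 0.05,
                                  levels = CAL_LEVELS, qc_levels = QC_LEVELS,
                                  coef = c(a = -1e-7, b = 2e-3, c = 1e-3),
                                  n_std = 2L, n_qc = 3L) {
  if (noise_cv < 0 || noise_cv >= 0.5) stop("noise_cv must be in [0, 0.5)")
  set.seed(seed)
  forward <- function(x) coef[["a"]] * x^2 + coef[["b"]] * x + coef[["c"]]
  gen <- function(conc, n, prefix) {
    conc <- rep(conc, each = n)
    data.frame(level_id = paste0(prefix, rep(seq_along(unique(conc)), each = n)),
               nominal_conc = conc,
               area_ratio = forward(conc) * rlnorm_cv(length(conc), noise_cv),
               replicate = rep(seq_len(n), times = length(conc) / n),
               stringsAsFactors = FALSE)
  }
  list(standards = gen(sort(levels), n_std, "STD"),
       qc = gen(sort(qc_levels), n_qc, "QC"),
       coef = coef)
}

#' Simulate IV-bolus concentration-time profiles
#'
#' Two-compartment disposition in macro-constant form,
#' `c(t) = dose * (A*exp(-alpha*t) + B*exp(-beta*t))` with `A`, `B` in
#' ng/mL per mg/kg, multiplied by mean-1 lognormal noise. The optional
#' saturable mode shrinks the terminal rate constant at doses above
#' `sat_dose`, emulating saturation of the elimination pathway that makes
#' high-dose exposure supra-proportional.
#'
#' @param seed integer RNG seed.
#' @param doses dose groups in mg/kg.
#' @param n_subjects subjects per group.
#' @param times sampling grid (min); default [PK_TIMES].
#' @param A,B macro-constant coefficients (ng/mL per mg/kg dose).
#' @param alpha,beta distribution and terminal rate constants (1/min),
#'   `alpha > beta > 0`.
#' @param noise_cv lognormal noise CV.
#' @param saturable enable dose-dependent terminal slowing.
#' @param sat_dose,sat_scale above `sat_dose`, the effective beta is
#'   `beta / (1 + (dose - sat_dose)/sat_scale)`.
#' @return list of [pk_profile()] objects.
#' @export
sim_pk_profiles <- function(seed = 1, doses = c(5, 10, 30), n_subjects = 3L,
                            times = PK_TIMES, A = 960, B = 220,
                            alpha = 0.08, beta = 0.0131, noise_cv = 0.10,
                            saturable = FALSE, sat_dose = 10, sat_scale = 20) {
  if (!(alpha > beta && beta > 0)) stop("need alpha > beta > 0")
  if (A < 0 || B < 0 || A + B <= 0) stop("invalid macro-constants")
  set.seed(seed)
  profiles <- list()
  for (dose in doses) {
    beta_eff <- if (saturable && dose > sat_dose)
      beta / (1 + (dose - sat_dose) / sat_scale) else beta
    for (s in seq_len(n_subjects)) {
      mu <- dose * (A * exp(-alpha * times) + B * exp(-beta_eff * times))
      conc <- mu * rlnorm_cv(length(times), noise_cv)
      profiles[[length(profiles) + 1L]] <- pk_profile(
        sprintf("d%g_s%d", dose, s), dose, times, conc)
    }
  }
  profiles
}

#' Default ground-truth metabolite set for the peak-table generator
#'
#' One row per species of the characterization table, with its chain-step
#' counts, the amine-side share of those steps (from the reported
#' product-ion shift patterns: N-oxide oxygens sit on the pyridine
#' nitrogen of the acyl half, remaining oxidations and all desaturations
#' on the 4-butylpiperidine half), and the N-oxide flag.
#'
#' @return [daporinad_metabolites()] extended with list columns `steps`
#'   and `amine_steps` and logical `n_oxide`.
#' @export
daporinad_ground_truth <- function() {
  tbl <- daporinad_metabolites()
  steps_of <- function(tr) switch(
    tr,
    "Parent" = integer(0),
    "Amide hydrolysis" = c(amide_hydrolysis = 1L),
    "Amide hydrolysis followed by carboxylation" = c(hydrolysis_carboxylation = 1L),
    "Amide hydrolysis followed by hydroxylation" = c(hydrolysis_hydroxylation = 1L),
    "Oxidation" = c(oxidation = 1L),
    "Di-oxidation" = c(oxidation = 2L),
    "Tri-oxidation" = c(oxidation = 3L),
    "Saturation" = c(saturation = 1L),
    "Desaturation" = c(desaturation = 1L),
    "Di-desaturation" = c(desaturation = 2L),
    "Desaturation + Oxidation" = c(desaturation = 1L, oxidation = 1L),
    stop("no step mapping for transformation: ", tr)
  )
  # amine-side step share per species, from the product-ion shift patterns:
  # oxidations sit on the pyridine N for the N-oxides (acyl side), on the
  # piperidine half otherwise; desaturations sit on the piperidine half.
  n_ox <- c("M6", "M10", "M11", "M18", "M22", "M25")
  amine_of <- function(label, steps) {
    if (length(steps) == 0L) return(steps)
    amine <- steps
    if (label %in% n_ox && "oxidation" %in% names(steps))
      amine[["oxidation"]] <- steps[["oxidation"]] - 1L
    if (startsWith(label, "M") && label %in% c("M1", "M20", "M21"))
      amine <- steps[integer(0)]  # scaffold cleaved; localization n/a
    amine[amine > 0]
  }
  tbl$steps <- lapply(tbl$transformation, steps_of)
  tbl$amine_steps <- mapply(amine_of, tbl$label, tbl$steps, SIMPLIFY = FALSE)
  tbl$n_oxide <- tbl$label %in% n_ox
  tbl
}

#' Simulate paired control/TiCl3 peak tables and product-ion spectra
#'
#' Builds a centroided peak table from a ground-truth metabolite set: each
#' species becomes a peak at its theoretical m/z perturbed by normal ppm
#' jitter, at its reference retention time. Product-ion spectra are
#' generated from the parent's fragment template with each fragment
#' shifted by the exact mass of the ground-truth steps assigned to its
#' moiety. In the TiCl3-treated table, N-oxide species lose 95% of their
#' intensity and the species one oxygen lighter (their reduction product)
#' gains the difference.
#'
#' @param seed integer RNG seed.
#' @param ground_truth data.frame like `daporinad_ground_truth()` (the
#'   default): columns `label`, `mz`, `rt_min`, list columns `steps` and
#'   `amine_steps`, logical `n_oxide`.
#' @param ppm_jitter SD of the mass-accuracy jitter in ppm.
#' @param intensity base peak intensity (arbitrary units).
#' @param rules rule set used to compute fragment shifts.
#' @param template fragment template of the parent.
#' @return list with `control` and `ticl3` peak tables, `spectra` (named
#'   list of data.frames `fragment_mz`/`intensity` per label, with
#'   `precursor_mz` attribute) and the `ground_truth` used.
#' @export
sim_peak_tables <- function(seed = 1, ground_truth = daporinad_ground_truth(),
                            ppm_jitter = 1.5, intensity = 1e5,
                            rules = default_biotransform_rules(),
                            template = daporinad_fragment_template()) {
  set.seed(seed)
  gt <- ground_truth
  n <- nrow(gt)
  if (n == 0L) stop("ground truth must at least contain the parent")
  eps <- stats::rnorm(n, 0, ppm_jitter) * 1e-6
  obs_mz <- gt$mz * (1 + eps)
  base_int <- intensity * ifelse(gt$label == "Parent", 1, 0.12)
  control <- peak_table("control", gt$rt_min, obs_mz, base_int)
  trt_int <- base_int
  o_mass <- .ATOMIC_MASS[["O"]]
  new_rt <- numeric(0); new_mz <- numeric(0); new_int <- numeric(0)
  for (i in which(gt$n_oxide)) {
    lost <- 0.95 * base_int[i]
    trt_int[i] <- base_int[i] - lost
    pm <- gt$mz[i] - o_mass
    # the reduction product co-elutes with an existing one-oxygen-lighter
    # species when one exists (never another N-oxide, whose own peak is
    # collapsing); otherwise it shows up as a new peak at the N-oxide's rt
    partner <- which(abs(gt$mz - pm) < 5e-4 & !gt$n_oxide)
    if (length(partner)) {
      trt_int[partner[1]] <- trt_int[partner[1]] + lost
    } else {
      new_rt <- c(new_rt, gt$rt_min[i])
      new_mz <- c(new_mz, pm * (1 + stats::rnorm(1, 0, ppm_jitter) * 1e-6))
      new_int <- c(new_int, lost)
    }
  }
  ticl3 <- peak_table("ticl3", c(gt$rt_min, new_rt), c(obs_mz, new_mz),
                      c(trt_int, new_int))
  step_mass <- vapply(rules, function(r) delta_mass(r$delta), 0)
  spectra <- list()
  for (i in seq_len(n)) {
    steps <- gt$steps[[i]]; amine <- gt$amine_steps[[i]]
    if (gt$label[i] %in% c("M1", "M20", "M21")) {
      # cleaved scaffold: only the unmodified amine-secondary and acyl
      # -HCN fragments survive
      frag <- template$mz[template$relation %in% c("secondary", "-HCN")]
    } else {
      amine_shift <- if (length(amine)) sum(amine * step_mass[names(amine)]) else 0
      total_shift <- if (length(steps)) sum(steps * step_mass[names(steps)]) else 0
      shift <- ifelse(template$moiety == "amine_side", amine_shift,
                      total_shift - amine_shift)
      frag <- template$mz + shift
    }
    sp <- data.frame(fragment_mz = round_half_up(sort(frag), 2),
                     intensity = rep(1000, length(frag)))
    attr(sp, "precursor_mz") <- gt$mz[i]
    spectra[[gt$label[i]]] <- sp
  }
  list(control = control, ticl3 = ticl3, spectra = spectra,
       ground_truth = gt)
}
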