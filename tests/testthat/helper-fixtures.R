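# Shared fixtures built in code.

# Rich sampling grid used for estimator-recovery properties (the sparse
# 7-point study grid is tested separately for its discretization bias).
RICH_GRID <- c(1, 2, 4, 7, 10, 15, 20, 30, 40, 50, 60, 80, 100, 120,
               150, 180, 210, 240, 280, 320, 360, 420)

# Mean-1 multiplicative lognormal noise at a given CV (mirrors the
# generators' noise model for building small ad-hoc QC sets).
rlnorm_like <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# True clearance (mL/min/kg) of the default two-compartment generator at a
# given dose: dose / analytic AUCinf of the noiseless model.
true_cl <- function(dose, A = 960, B = 220, alpha = 0.08, beta = 0.0131) {
  auc_inf <- dose * (A / alpha + B / beta)
  dose * 1e6 / auc_inf
}

# Independent brute-force localization oracle: enumerates every per-step
# moiety assignment vector (2^n_steps full expansion, no per-rule count
# shortcut) and scores predicted fragments against the spectrum.
oracle_localize <- function(steps, frag_mz,
                            template = daporinad_fragment_template(),
                            rules = default_biotransform_rules(),
                            frag_tol_mda = 10, min_matches = 2L) {
  steps <- steps[steps > 0]
  if (length(frag_mz) == 0L || length(steps) == 0L) return("unlocalized")
  step_rules <- rep(names(steps), times = steps)
  masses <- vapply(rules[step_rules],
                   function(r) dmpkid:::delta_mass(r$delta), 0)
  n <- length(step_rules)
  assign_grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  tol <- frag_tol_mda / 1000
  score <- integer(nrow(assign_grid))
  cls <- character(nrow(assign_grid))
  for (i in seq_len(nrow(assign_grid))) {
    amine <- as.logical(assign_grid[i, ])
    sh_am <- sum(masses[amine]); sh_ac <- sum(masses[!amine])
    pred <- template$mz + ifelse(template$moiety == "amine_side", sh_am, sh_ac)
    score[i] <- sum(vapply(pred, function(p) any(abs(frag_mz - p) <= tol), TRUE))
    cls[i] <- if (all(amine)) "amine_side" else if (all(!amine)) "acyl_side" else "both"
  }
  best <- max(score)
  if (best < min_matches) return("unlocalized")
  win_cls <- unique(cls[score == best])
  if (length(win_cls) > 1L) "unlocalized" else win_cls
}

# A small random ground-truth set for N-oxide round trips: n species built
# from random oxidative chains on the parent, a subset flagged as N-oxides.
random_ground_truth <- function(seed, n = 20L, n_oxide = 6L) {
  set.seed(seed)
  rules <- default_biotransform_rules()
  chains <- list(c(oxidation = 1L), c(oxidation = 2L), c(oxidation = 3L),
                 c(desaturation = 1L, oxidation = 1L),
                 c(desaturation = 1L), c(saturation = 1L))
  parent <- daporinad_formula()
  rows <- list(list(label = "Parent", steps = list(integer(0)),
                    amine_steps = list(integer(0)), n_oxide = FALSE,
                    mz = round_half_up(adduct_mz(parent), 4), rt_min = 22.31))
  picks <- sample(seq_along(chains), n, replace = TRUE)
  # only oxidized species can be N-oxides
  ox_idx <- which(vapply(picks, function(p) "oxidation" %in% names(chains[[p]]), TRUE))
  nox_rows <- sample(ox_idx, min(n_oxide, length(ox_idx)))
  rts <- sort(round(stats::runif(n, 2, 30), 2))
  mz_of <- function(steps) {
    delta <- integer(0)
    for (nm in names(steps)) {
      d <- rules[[nm]]$delta * steps[[nm]]
      for (el in names(d))
        delta[el] <- (if (el %in% names(delta)) delta[[el]] else 0L) + d[[el]]
    }
    round_half_up(adduct_mz(formula_shift(parent, delta)), 4)
  }
  for (i in seq_len(n)) {
    steps <- chains[[picks[i]]]
    is_nox <- i %in% nox_rows
    amine <- steps
    if (is_nox) amine[["oxidation"]] <- amine[["oxidation"]] - 1L
    rows[[length(rows) + 1L]] <- list(label = paste0("S", i),
                                      steps = list(steps),
                                      amine_steps = list(amine[amine > 0]),
                                      n_oxide = is_nox, mz = mz_of(steps),
                                      rt_min = rts[i])
  }
  # every N-oxide needs its one-oxygen-lighter reduction product in the set
  have_mz <- vapply(rows, function(r) r$mz, 0)
  extra_rt <- 31
  for (r in rows[vapply(rows, function(r) isTRUE(r$n_oxide), TRUE)]) {
    red <- r$steps[[1]]
    red[["oxidation"]] <- red[["oxidation"]] - 1L
    red <- red[red > 0]
    red_mz <- if (length(red)) mz_of(red) else round_half_up(adduct_mz(parent), 4)
    if (!any(abs(have_mz - red_mz) < 5e-4)) {
      extra_rt <- extra_rt + 1
      rows[[length(rows) + 1L]] <- list(label = paste0("R", length(rows)),
                                        steps = list(red),
                                        amine_steps = list(red),
                                        n_oxide = FALSE, mz = red_mz,
                                        rt_min = extra_rt)
      have_mz <- c(have_mz, red_mz)
    }
  }
  gt <- do.call(rbind, lapply(rows, function(r)
    data.frame(label = r$label, mz = r$mz, rt_min = r$rt_min,
               n_oxide = r$n_oxide, stringsAsFactors = FALSE)))
  gt$steps <- lapply(rows, function(r) r$steps[[1]])
  gt$amine_steps <- lapply(rows, function(r) r$amine_steps[[1]])
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
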