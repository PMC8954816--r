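PARENT <- "C24H29N3O2"

test_that("chain enumeration produces the oxidation ladder and composite chains", {
  rules <- default_biotransform_rules()
  ox_only <- enumerate_chains(PARENT, rules["oxidation"], max_steps = 3,
                              include_parent = FALSE)
  expect_identical(round_half_up(sort(ox_only$mz), 4),
                   c(408.2282, 424.2231, 440.2180))
  two <- enumerate_chains(PARENT, rules[c("desaturation", "oxidation")],
                          max_steps = 2)
  desox <- two[two$formula == "C24H27N3O3", ]
  expect_identical(nrow(desox), 1L)
  expect_identical(round_half_up(desox$mz, 4), 406.2125)
  expect_identical(desox$name, "Desaturation + Oxidation")
  expect_error(enumerate_chains(PARENT, rules, max_steps = 0), "max_steps")
  none <- enumerate_chains(PARENT, list(), max_steps = 2, include_parent = FALSE)
  expect_identical(nrow(none), 0L)
})

test_that("chains are deduplicated by net composition with fewest steps winning, and sorted by m/z", {
  rules <- default_biotransform_rules()
  ch <- enumerate_chains(PARENT, rules, max_steps = 3)
  expect_false(any(duplicated(ch$formula)))
  expect_true(!is.unsorted(ch$mz))
  # desaturation + saturation cancels to the parent: the 0-step chain wins
  parent_row <- ch[ch$formula == "C24H29N3O2", ]
  expect_identical(parent_row$n_steps, 0L)
  expect_identical(parent_row$name, "Parent")
  # per-rule multiplicity caps are respected
  expect_true(all(vapply(ch$steps, function(s) {
    all(s <= vapply(rules[names(s)], `[[`, 0L, "max_multiplicity"))
  }, TRUE)))
})

test_that("peak annotation matches within tolerance and ranks by steps then |ppm|", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  peaks <- peak_table("plasma", c(22.31, 11.99, 5.0),
                      c(392.2333, 408.2282, 500.0), 1e5)
  ann <- annotate_peaks(peaks, ch, tol_ppm = 5)
  best <- ann$annotations[ann$annotations$rank == 1L, ]
  expect_identical(best$chain[best$mz == 392.2333], "Parent")
  expect_equal(best$ppm[best$mz == 392.2333], 0, tolerance = 0.15)
  expect_identical(best$chain[best$mz == 408.2282], "Oxidation")
  expect_identical(ann$unmatched$mz, 500.0)
  # empty peak list is an empty result, not an error
  ann0 <- annotate_peaks(peak_table(character(0), numeric(0), numeric(0),
                                    numeric(0)), ch)
  expect_identical(nrow(ann0$annotations), 0L)
  expect_error(annotate_peaks(peaks, ch, tol_ppm = 0), "positive")
})

test_that("shrinking the ppm tolerance never adds annotations", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  set.seed(21)
  mzs <- ch$mz[sample(nrow(ch), 15, replace = TRUE)] *
    (1 + rnorm(15, 0, 3) * 1e-6)
  peaks <- peak_table("x", seq(1, 15), mzs, 1)
  tols <- c(10, 5, 2.5, 1, 0.5)
  counts <- vapply(tols, function(tl)
    nrow(annotate_peaks(peaks, ch, tl)$annotations), 0L)
  expect_true(all(diff(counts) <= 0))
  # every annotation at the tighter tolerance exists at the looser one
  a5 <- annotate_peaks(peaks, ch, 5)$annotations
  a10 <- annotate_peaks(peaks, ch, 10)$annotations
  expect_true(all(paste(a5$peak_id, a5$formula) %in%
                  paste(a10$peak_id, a10$formula)))
})

test_that("the full characterization-table peak list annotates with matching transformation names", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  tbl <- daporinad_metabolites()
  peaks <- daporinad_peaks(conditions = "mouse_plasma")
  ann <- annotate_peaks(peaks, ch, tol_ppm = 5)
  expect_identical(nrow(ann$unmatched), 0L)
  best <- ann$annotations[ann$annotations$rank == 1L, ]
  m <- merge(best, tbl[, c("rt_min", "transformation")], by = "rt_min")
  expect_identical(m$chain, m$transformation)
  # 25 non-parent peaks assigned, matching the reported metabolite count
  expect_identical(sum(best$chain != "Parent"), 25L)
})

test_that("fragment template m/z derive from their formulas", {
  tpl <- daporinad_fragment_template()
  expect_identical(round_half_up(tpl$mz, 4),
                   c(261.1961, 244.1696, 140.1434, 132.0444, 105.0335, 104.0495))
  expect_identical(tpl$moiety,
                   rep(c("amine_side", "acyl_side"), each = 3))
  expect_error(fragment_template("C2H4", "middle", "primary"), "moiety")
})

test_that("localization reproduces the reported shift patterns", {
  # desaturation + oxidation, amine-side fragments shifted by +14
  expect_identical(as.character(localize_modification(
    c(desaturation = 1L, oxidation = 1L),
    c(275.18, 258.15, 154.12, 132.04, 105.03, 104.05))), "amine_side")
  # mono-oxidation with acyl fragments shifted by +16
  expect_identical(as.character(localize_modification(
    c(oxidation = 1L),
    c(261.20, 244.17, 140.14, 148.04, 120.04, 105.03))), "acyl_side")
  # di-oxidation split across both moieties
  expect_identical(as.character(localize_modification(
    c(oxidation = 2L),
    c(277.19, 156.14, 148.04, 120.04, 105.03))), "both")
  # di-desaturation on the amine side (-4 amu fragments)
  expect_identical(as.character(localize_modification(
    c(desaturation = 2L),
    c(257.16, 240.14, 136.11, 132.04, 105.03, 104.05))), "amine_side")
  # empty spectrum is unlocalized, not an error
  expect_identical(as.character(localize_modification(
    c(oxidation = 1L), numeric(0))), "unlocalized")
  # spectrum matching fewer than 2 predicted fragments is unlocalized
  expect_identical(as.character(localize_modification(
    c(oxidation = 1L), c(999.9, 888.8))), "unlocalized")
})

test_that("localization agrees with the exhaustive per-step assignment oracle", {
  set.seed(31)
  tpl <- daporinad_fragment_template()
  chains <- list(c(oxidation = 1L), c(oxidation = 2L), c(oxidation = 3L),
                 c(desaturation = 1L), c(desaturation = 2L),
                 c(desaturation = 1L, oxidation = 1L),
                 c(desaturation = 1L, oxidation = 2L),
                 c(saturation = 1L, oxidation = 1L))
  rules <- default_biotransform_rules()
  step_mass <- vapply(rules, function(r) dmpkid:::delta_mass(r$delta), 0)
  for (rep in 1:40) {
    steps <- chains[[sample(length(chains), 1)]]
    # random true partition, random fragment subset, 2-dp reported spectrum
    amine_k <- vapply(steps, function(k) sample(0:k, 1), 0L)
    shift <- ifelse(tpl$moiety == "amine_side",
                    sum(amine_k * step_mass[names(steps)]),
                    sum((steps - amine_k) * step_mass[names(steps)]))
    frag <- round(tpl$mz + shift, 2)
    keep <- runif(length(frag)) < 0.8
    frag <- frag[keep]
    got <- as.character(localize_modification(steps, frag))
    want <- oracle_localize(steps, frag)
    expect_identical(got, want,
                     label = paste("steps:", paste(names(steps), steps,
                                                   collapse = " "),
                                   "amine:", paste(amine_k, collapse = "")))
  }
})

test_that("TiCl3 differential flags exactly the designated N-oxides and none on identical input", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  sim <- sim_peak_tables(seed = 7)
  ann <- annotate_peaks(sim$control, ch, 5)
  flagged <- detect_n_oxide(sim$control, sim$ticl3, ann)
  truth <- sim$ground_truth[sim$ground_truth$n_oxide, ]
  expect_identical(sort(flagged$rt_min[flagged$n_oxide == "yes"]),
                   sort(truth$rt_min))
  # the six designated species are the oxidation/desat+ox/tri-ox set
  expect_setequal(truth$label, c("M6", "M10", "M11", "M18", "M22", "M25"))
  # non-oxidized chains are untested
  expect_true(all(flagged$n_oxide[
    !vapply(flagged$steps, function(s) "oxidation" %in% names(s), TRUE)] ==
    "untested"))
  # control == treated: zero flags at any threshold
  for (df in c(0.5, 0.8, 0.99)) {
    same <- detect_n_oxide(sim$control, sim$control, ann, drop_fraction = df)
    expect_identical(sum(same$n_oxide == "yes"), 0L)
  }
})

test_that("N-oxide round trip recovers a random 20-species ground truth", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  for (sd in c(5, 17)) {
    gt <- random_ground_truth(seed = sd, n = 20, n_oxide = 6)
    sim <- sim_peak_tables(seed = sd, ground_truth = gt)
    ann <- annotate_peaks(sim$control, ch, 5)
    flagged <- detect_n_oxide(sim$control, sim$ticl3, ann,
                              drop_fraction = 0.8)
    expect_identical(sort(flagged$rt_min[flagged$n_oxide == "yes"]),
                     sort(gt$rt_min[gt$n_oxide]), label = paste("seed", sd))
  }
})

test_that("annotations missing from the control list come back untested with a warning record", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  sim <- sim_peak_tables(seed = 3)
  ann <- annotate_peaks(sim$control, ch, 5)
  # drop the M22 control peak (oxidation at rt 24.04)
  ctrl <- sim$control[abs(sim$control$rt_min - 24.04) > 0.01, ]
  flagged <- detect_n_oxide(ctrl, sim$ticl3, ann)
  expect_identical(flagged$n_oxide[abs(flagged$rt_min - 24.04) < 0.01],
                   "untested")
  expect_true(length(attr(flagged, "warnings")) >= 1L)
})

test_that("the metabolite report is rt-ordered with per-condition presence and deterministic labels", {
  ch <- enumerate_chains(PARENT, max_steps = 3)
  tbl <- daporinad_metabolites()
  ann <- annotate_peaks(daporinad_peaks(), ch, 5)
  rep <- build_metabolite_report(ann)
  expect_identical(nrow(rep), 26L)
  expect_true(!is.unsorted(rep$rt_min))
  # parent sits between the carboxylation and hydroxylation hydrolysis products
  i <- which(rep$transformation == "Parent")
  expect_identical(rep$label[i], "Parent")
  expect_identical(rep$rt_min[c(i - 1L, i, i + 1L)], c(21.25, 22.31, 22.76))
  # presence flags reproduce the fixture's detection matrix
  for (cd in c("mouse_liver_microsome", "human_liver_microsome", "mouse_plasma")) {
    expect_identical(rep[[cd]], tbl[[cd]], label = cd)
  }
  # theoretical m/z reported at 4 dp
  expect_identical(rep$theoretical_mz, tbl$mz)
  # empty input: header-only table
  rep0 <- build_metabolite_report(
    annotate_peaks(peak_table(character(0), numeric(0), numeric(0),
                              numeric(0)), ch))
  expect_identical(nrow(rep0), 0L)
  # duplicate supplied labels are suffixed deterministically
  rep2 <- build_metabolite_report(ann, labels = rep("M", 26))
  expect_identical(anyDuplicated(rep2$label), 0L)
  expect_identical(rep2$label[1:3], c("M", "M_1", "M_2"))
})
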