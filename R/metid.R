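# Biotransformation-chain enumeration, exact-mass peak annotation,
# fragment-shift moiety localization and the TiCl3 N-oxide differential.

#' Define a biotransformation rule
#'
#' A rule is a signed elemental delta applied to the parent scaffold, with a
#' cap on how many times it may occur in one chain and a mechanistic
#' category.
#'
#' @param name machine name (unique within a rule set).
#' @param display human-readable name used in chain labels.
#' @param delta named signed element-count change, e.g. `c(O = 1)`.
#' @param max_multiplicity maximum applications of this rule in one chain.
#' @param category one of `"hydrolytic"`, `"oxidative"`, `"reductive"`,
#'   `"desaturative"`.
#' @param display_order sort key used when composing multi-rule chain names.
#' @return a `biotransform_rule` list.
#' @export
biotransform_rule <- function(name, display, delta, max_multiplicity = 1L,
                              category = c("oxidative", "hydrolytic",
                                           "reductive", "desaturative"),
                              display_order = 100L) {
  category <- match.arg(category)
  delta <- delta[delta != 0]
  if (length(delta) == 0L) stop("rule delta must be nonzero")
  if (max_multiplicity < 1L) stop("max_multiplicity must be >= 1")
  structure(list(name = name, display = display, delta = delta,
                 max_multiplicity = as.integer(max_multiplicity),
                 category = category,
                 display_order = as.integer(display_order)),
            class = "biotransform_rule")
}

#' Default phase-I biotransformation rule set
#'
#' The six phase-I reactions observed for Daporinad: oxidation (up to
#' tri-oxidation), desaturation (up to di-), saturation, amide hydrolysis
#' (net loss of the pyridine-acryloyl acyl moiety C8H5NO, a 131 amu nominal
#' loss), and the two amide-hydrolysis follow-ups (carboxylation and
#' hydroxylation of the liberated amine), expressed as net deltas from the
#' parent.
#'
#' @return named list of [biotransform_rule()] objects.
#' @export
default_biotransform_rules <- function() {
  rules <- list(
    biotransform_rule("desaturation", "Desaturation", c(H = -2),
                      max_multiplicity = 2, category = "desaturative",
                      display_order = 10),
    biotransform_rule("saturation", "Saturation", c(H = 2),
                      max_multiplicity = 1, category = "reductive",
                      display_order = 20),
    biotransform_rule("oxidation", "Oxidation", c(O = 1),
                      max_multiplicity = 3, category = "oxidative",
                      display_order = 30),
    biotransform_rule("amide_hydrolysis", "Amide hydrolysis",
                      c(C = -8, H = -5, N = -1, O = -1),
                      max_multiplicity = 1, category = "hydrolytic",
                      display_order = 40),
    # net parent -> C16H21NO3: hydrolysis then amine -> carboxylic acid
    biotransform_rule("hydrolysis_carboxylation",
                      "Amide hydrolysis followed by carboxylation",
                      c(C = -8, H = -8, N = -2, O = 1),
                      max_multiplicity = 1, category = "hydrolytic",
                      display_order = 50),
    # net parent -> C16H23NO2: hydrolysis then amine -> hydroxyl
    biotransform_rule("hydrolysis_hydroxylation",
                      "Amide hydrolysis followed by hydroxylation",
                      c(C = -8, H = -6, N = -2),
                      max_multiplicity = 1, category = "hydrolytic",
                      display_order = 60)
  )
  names(rules) <- vapply(rules, `[[`, "", "name")
  rules
}

.MULT_PREFIX <- c("", "Di-", "Tri-", "Tetra-", "Penta-")

chain_name <- function(steps, rules) {
  active <- steps[steps > 0]
  if (length(active) == 0L) return("Parent")
  ord <- order(vapply(rules[names(active)], `[[`, 0L, "display_order"))
  active <- active[ord]
  parts <- mapply(function(nm, k) {
    disp <- rules[[nm]]$display
    if (k == 1L) disp
    else paste0(.MULT_PREFIX[k], tolower(substr(disp, 1, 1)), substr(disp, 2, nchar(disp)))
  }, names(active), active)
  paste(parts, collapse = " + ")
}

#' Enumerate biotransformation chains on a parent scaffold
#'
#' Generates every multiset of rule applications with at most `max_steps`
#' total steps (and each rule within its own multiplicity cap), prunes
#' chains whose net formula would have a negative element count, and
#' deduplicates chains with identical net elemental change, keeping the one
#' with fewest steps. Each chain carries its net formula and theoretical
#' `[M+H]+` m/z.
#'
#' @param parent parent molecular formula (string or `elemental_formula`).
#' @param rules named list of [biotransform_rule()]s;
#'   default [default_biotransform_rules()].
#' @param max_steps maximum total rule applications per chain (>= 1).
#' @param include_parent if `TRUE` (default) the zero-step "Parent" chain is
#'   included so the unmetabolized drug annotates itself.
#' @param adduct [adduct_spec()] for the theoretical m/z.
#' @return a data.frame of class `biotransform_chains`, sorted by
#'   theoretical m/z, with columns `name`, `formula`, `mz`, `n_steps` and a
#'   list column `steps` (named per-rule application counts).
#' @examples
#' ch <- enumerate_chains("C24H29N3O2", max_steps = 3)
#' subset(ch, name == "Tri-oxidation")$mz  # 440.218
#' @export
enumerate_chains <- function(parent, rules = default_biotransform_rules(),
                             max_steps = 3L, include_parent = TRUE,
                             adduct = adduct_spec()) {
  if (max_steps < 1L) stop("max_steps must be >= 1")
  parent <- as_formula(parent)
  if (length(rules) == 0L) {
    combos <- if (include_parent) list(integer(0)) else list()
  } else {
    caps <- pmin(vapply(rules, `[[`, 0L, "max_multiplicity"), max_steps)
    grid <- do.call(expand.grid, lapply(caps, function(k) 0:k))
    keep <- rowSums(grid) <= max_steps & (include_parent | rowSums(grid) > 0)
    grid <- grid[keep, , drop = FALSE]
    combos <- lapply(seq_len(nrow(grid)), function(i) {
      v <- as.integer(grid[i, ])
      names(v) <- names(rules)
      v[v > 0]
    })
  }
  rows <- list()
  for (steps in combos) {
    delta <- integer(0)
    for (nm in names(steps)) {
      d <- rules[[nm]]$delta * steps[[nm]]
      for (el in names(d)) delta[el] <- (if (el %in% names(delta)) delta[[el]] else 0L) + d[[el]]
    }
    f <- tryCatch(formula_shift(parent, delta), error = function(e) NULL)
    if (is.null(f)) next  # impossible on this scaffold
    rows[[length(rows) + 1L]] <- list(
      name = chain_name(steps, rules),
      formula = formula_string(f),
      mz = adduct_mz(f, adduct),
      n_steps = sum(steps),
      steps = steps
    )
  }
  if (length(rows) == 0L) {
    out <- data.frame(name = character(0), formula = character(0),
                      mz = numeric(0), n_steps = integer(0))
    out$steps <- list()
  } else {
    out <- data.frame(
      name = vapply(rows, `[[`, "", "name"),
      formula = vapply(rows, `[[`, "", "formula"),
      mz = vapply(rows, `[[`, 0, "mz"),
      n_steps = vapply(rows, `[[`, 0L, "n_steps"),
      stringsAsFactors = FALSE
    )
    out$steps <- lapply(rows, `[[`, "steps")
    # dedupe identical net formulas (same net delta on this parent): fewest steps wins
    out <- out[order(out$n_steps), ]
    out <- out[!duplicated(out$formula), ]
    out <- out[order(out$mz, out$n_steps), ]
  }
  rownames(out) <- NULL
  attr(out, "parent") <- formula_string(parent)
  class(out) <- c("biotransform_chains", "data.frame")
  out
}

#' Build a validated peak table
#'
#' @param condition condition label per peak (e.g. `"mouse_plasma"` or
#'   `"control"` / `"ticl3"`).
#' @param rt_min retention time in minutes, >= 0.
#' @param mz m/z in Th, > 0.
#' @param intensity peak intensity in arbitrary units, >= 0.
#' @return a data.frame with the four validated columns.
#' @export
peak_table <- function(condition, rt_min, mz, intensity) {
  n <- length(mz)
  condition <- rep_len(as.character(condition), n)
  intensity <- rep_len(as.numeric(intensity), n)
  stopifnot(length(rt_min) == n)
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("peak m/z must be positive")
  if (any(!is.finite(rt_min)) || any(rt_min < 0)) stop("rt_min must be >= 0")
  if (any(!is.finite(intensity)) || any(intensity < 0)) stop("intensity must be >= 0")
  data.frame(condition = condition, rt_min = as.numeric(rt_min),
             mz = as.numeric(mz), intensity = as.numeric(intensity),
             stringsAsFactors = FALSE)
}

#' Annotate a peak list against biotransformation chains
#'
#' Every chain whose theoretical m/z lies within `tol_ppm` of a peak's m/z
#' becomes a candidate annotation for that peak. Candidates are ranked by
#' fewest chain steps, then smallest absolute ppm error; all surviving
#' candidates are kept (rank 1 is the preferred call). Peaks matching no
#' chain are returned separately, never dropped.
#'
#' @param peaks a peak data.frame from [peak_table()] / [read_peak_table()].
#' @param chains a `biotransform_chains` object from [enumerate_chains()].
#' @param tol_ppm annotation mass tolerance in ppm (> 0); default 5.
#' @return an object of class `metid_annotation`: list with `annotations`
#'   (one row per peak x candidate chain, with `peak_id`, peak columns,
#'   chain columns, `ppm`, `rank`), `unmatched` (peak rows with no
#'   candidate) and the tolerance used.
#' @export
annotate_peaks <- function(peaks, chains, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  stopifnot(all(c("condition", "rt_min", "mz", "intensity") %in% names(peaks)))
  ann <- list()
  unmatched <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    ppm <- ppm_error(peaks$mz[i], chains$mz)
    hit <- which(abs(ppm) <= tol_ppm)
    if (length(hit) == 0L) { unmatched <- c(unmatched, i); next }
    ord <- hit[order(chains$n_steps[hit], abs(ppm[hit]))]
    a <- data.frame(peak_id = i,
                    condition = peaks$condition[i], rt_min = peaks$rt_min[i],
                    mz = peaks$mz[i], intensity = peaks$intensity[i],
                    chain = chains$name[ord], formula = chains$formula[ord],
                    theoretical_mz = chains$mz[ord], n_steps = chains$n_steps[ord],
                    ppm = ppm[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
    a$steps <- chains$steps[ord]
    ann[[length(ann) + 1L]] <- a
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else {
    a <- data.frame(peak_id = integer(0), condition = character(0),
                    rt_min = numeric(0), mz = numeric(0), intensity = numeric(0),
                    chain = character(0), formula = character(0),
                    theoretical_mz = numeric(0), n_steps = integer(0),
                    ppm = numeric(0), rank = integer(0))
    a$steps <- list()
    a
  }
  rownames(annotations) <- NULL
  structure(list(annotations = annotations,
                 unmatched = peaks[unmatched, , drop = FALSE],
                 tol_ppm = tol_ppm),
            class = "metid_annotation")
}

#' @export
print.metid_annotation <- function(x, ...) {
  n_peak <- length(unique(x$annotations$peak_id))
  cat(sprintf("<metid_annotation> %d peak(s) annotated (%d candidate chains), %d unmatched, tol %.3g ppm\n",
              n_peak, nrow(x$annotations), nrow(x$unmatched), x$tol_ppm))
  best <- x$annotations[x$annotations$rank == 1L, , drop = FALSE]
  if (nrow(best)) {
    best <- best[order(best$rt_min), c("condition", "rt_min", "mz", "chain",
                                       "formula", "ppm")]
    best$ppm <- round(best$ppm, 2)
    print(utils::head(best, 30), row.names = FALSE)
    if (nrow(best) > 30) cat("...", nrow(best) - 30, "more rows\n")
  }
  invisible(x)
}

#' Diagnostic fragment template of Daporinad
#'
#' The parent's product-ion scan gives three amine-side fragments from the
#' 4-butyl(piperidine) half (m/z 261.1961 from amide-bond cleavage, its
#' ammonia loss at 244.1696, and the secondary 140.1434) and three
#' acyl-side fragments from the pyridine-acryloyl half (132.0444, its HCN
#' loss 105.0335 and CO loss 104.0495). Fragments are stored as neutral
#' formulas with the observed m/z being the protonated form, so modified
#' metabolites shift them by the exact mass of whatever steps landed on
#' their moiety.
#'
#' @return a data.frame of class `fragment_template` with columns
#'   `formula`, `moiety` (`"amine_side"`/`"acyl_side"`), `relation`
#'   (`"primary"`, `"-NH3"`, `"-CO"`, `"-HCN"`, `"secondary"`) and the
#'   derived `mz`.
#' @export
daporinad_fragment_template <- function() {
  fragment_template(
    formula = c("C16H24N2O", "C16H21NO", "C9H17N",
                "C8H5NO", "C7H4O", "C7H5N"),
    moiety = c("amine_side", "amine_side", "amine_side",
               "acyl_side", "acyl_side", "acyl_side"),
    relation = c("primary", "-NH3", "secondary",
                 "primary", "-HCN", "-CO")
  )
}

#' Build a fragment template
#'
#' @param formula character vector of neutral fragment formulas.
#' @param moiety `"amine_side"` or `"acyl_side"` per fragment.
#' @param relation relation to the parent fragment (free text:
#'   `"primary"`, `"-NH3"`, `"-CO"`, `"-HCN"`, `"secondary"`, ...).
#' @param adduct [adduct_spec()] used to derive observed fragment m/z.
#' @return a `fragment_template` data.frame (see
#'   [daporinad_fragment_template()]).
#' @export
fragment_template <- function(formula, moiety, relation,
                              adduct = adduct_spec()) {
  stopifnot(length(formula) == length(moiety),
            length(formula) == length(relation))
  if (!all(moiety %in% c("amine_side", "acyl_side")))
    stop("moiety must be 'amine_side' or 'acyl_side'")
  out <- data.frame(formula = formula, moiety = moiety, relation = relation,
                    mz = vapply(formula, adduct_mz, 0, adduct = adduct),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fragment_template", "data.frame")
  out
}

# Normalize the many ways a chain's steps can be supplied to localization.
as_step_counts <- function(steps) {
  if (is.data.frame(steps) && "steps" %in% names(steps)) {
    if (nrow(steps) != 1L) stop("supply a single chain row")
    steps <- steps$steps[[1]]
  }
  if (is.list(steps) && !is.null(steps$steps)) steps <- steps$steps
  if (!is.numeric(steps) || is.null(names(steps)))
    stop("'steps' must be a named per-rule count vector or one chain row")
  steps <- steps[steps > 0]
  storage.mode(steps) <- "integer"
  steps
}

#' Localize a metabolite's modifications from product-ion shifts
#'
#' Brute-forces every partition of a chain's steps between the two moieties
#' of the scaffold. For each partition, every template fragment's m/z is
#' predicted shifted by the exact mass of the steps assigned to its moiety;
#' the partition's score is the number of predicted fragments found in the
#' spectrum within `frag_tol_mda`. The moiety assignment of the best
#' partition is returned: `"amine_side"` (all steps on the amine half),
#' `"acyl_side"`, or `"both"` (split). A tie between partitions with
#' different assignments, or a best score below `min_matches`, gives
#' `"unlocalized"`; so does an empty spectrum.
#'
#' @param steps a named per-rule application count vector, or a single chain
#'   row from [enumerate_chains()].
#' @param spectrum product-ion spectrum: numeric vector of fragment m/z, or
#'   a data.frame with an `mz` (or `fragment_mz`) column.
#' @param template a [fragment_template()];
#'   default [daporinad_fragment_template()].
#' @param rules rule set supplying per-step elemental deltas.
#' @param frag_tol_mda fragment match tolerance in mDa (default 10, suited
#'   to fragment m/z reported at 2 decimal places).
#' @param min_matches minimum matched fragments for a confident call.
#' @return a length-1 character: `"amine_side"`, `"acyl_side"`, `"both"` or
#'   `"unlocalized"`, with attributes `score` (matches of the winning
#'   partition) and `partition` (amine-side step counts).
#' @export
localize_modification <- function(steps, spectrum,
                                  template = daporinad_fragment_template(),
                                  rules = default_biotransform_rules(),
                                  frag_tol_mda = 10, min_matches = 2L) {
  if (frag_tol_mda <= 0) stop("frag_tol_mda must be positive")
  steps <- as_step_counts(steps)
  frag_mz <- if (is.data.frame(spectrum)) {
    col <- intersect(c("mz", "fragment_mz"), names(spectrum))[1]
    if (is.na(col)) stop("spectrum must have an 'mz' or 'fragment_mz' column")
    spectrum[[col]]
  } else as.numeric(spectrum)
  unloc <- function() structure("unlocalized", score = 0L,
                                partition = steps[integer(0)])
  if (length(frag_mz) == 0L) return(unloc())
  if (length(steps) == 0L) return(unloc())
  step_mass <- vapply(names(steps), function(nm) delta_mass(rules[[nm]]$delta), 0)
  tol <- frag_tol_mda / 1000
  # amine-side counts per rule: 0..k_r each
  grid <- do.call(expand.grid, lapply(steps, function(k) 0:k))
  score <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    amine_k <- as.numeric(grid[i, ])
    shift <- ifelse(template$moiety == "amine_side",
                    sum(amine_k * step_mass),
                    sum((steps - amine_k) * step_mass))
    pred <- template$mz + shift
    score[i] <- sum(vapply(pred, function(p) any(abs(frag_mz - p) <= tol), TRUE))
  }
  best <- max(score)
  if (best < min_matches) return(unloc())
  winners <- which(score == best)
  cls <- vapply(winners, function(i) {
    amine_k <- as.integer(grid[i, ])
    if (all(amine_k == steps)) "amine_side"
    else if (all(amine_k == 0L)) "acyl_side"
    else "both"
  }, "")
  if (length(unique(cls)) > 1L) return(structure("unlocalized", score = best,
                                                 partition = steps[integer(0)]))
  w <- winners[1]
  part <- as.integer(grid[w, ]); names(part) <- names(steps)
  structure(cls[1], score = best, partition = part)
}

# Total intensity of peaks within mz (ppm) and optional rt windows.
.match_intensity <- function(peaks, mz, rt = NULL, mz_tol_ppm = 5, rt_tol = 0.2) {
  sel <- abs(ppm_error(peaks$mz, mz)) <= mz_tol_ppm
  if (!is.null(rt)) sel <- sel & abs(peaks$rt_min - rt) <= rt_tol
  sum(peaks$intensity[sel])
}

# TRUE when any single treated peak at the target m/z exceeds the control
# intensity at its own (mz, rt) coordinate — a per-peak gain, robust to
# co-eluting species at the same m/z dropping simultaneously.
.any_peak_gain <- function(control, treated, mz, rt = NULL,
                           mz_tol_ppm = 5, rt_tol = 0.2) {
  sel <- abs(ppm_error(treated$mz, mz)) <= mz_tol_ppm
  if (!is.null(rt)) sel <- sel & abs(treated$rt_min - rt) <= rt_tol
  for (j in which(sel)) {
    ref <- .match_intensity(control, treated$mz[j], treated$rt_min[j],
                            mz_tol_ppm, 0.2)
    if (treated$intensity[j] > ref) return(TRUE)
  }
  FALSE
}

#' Flag N-oxide metabolites from a TiCl3 reduction differential
#'
#' Titanium(III) chloride chemically reduces N-oxides back to the parent
#' amine, so an N-oxide's peak collapses in the treated sample while a peak
#' one oxygen lighter gains intensity. An annotation carrying at least one
#' oxidation step is flagged `yes` when (a) its treated intensity falls to
#' at most `(1 - drop_fraction)` of its control intensity, and (b) some
#' individual peak at m/z - 15.9949 gains intensity under treatment
#' relative to its own control counterpart (peak-wise, so co-eluting
#' N-oxides at the partner m/z dropping at the same time cannot mask the
#' gain). Oxidized annotations
#' failing either test get `no`; annotations without an oxidation step are
#' `untested`. The reduced partner is searched at any retention time by
#' default, because the reduction product elutes wherever the one-oxygen-
#' lighter species elutes, which need not be near the N-oxide.
#'
#' @param control,treated peak tables (same m/z / rt coordinate convention)
#'   acquired without and with TiCl3 treatment.
#' @param annotations a `metid_annotation` (its rank-1 calls are used) or a
#'   data.frame with columns `rt_min`, `mz` and list column `steps`.
#' @param drop_fraction minimum fractional intensity loss of the N-oxide
#'   under treatment (default 0.8, i.e. an 80% drop).
#' @param mz_tol_ppm m/z matching tolerance in ppm.
#' @param rt_tol rt matching window in minutes for pairing the annotation's
#'   own peak across the two tables.
#' @param partner_rt_tol rt window for the reduced partner; `NULL`
#'   (default) searches all retention times.
#' @return the annotation data.frame with an `n_oxide` column
#'   (`"yes"`/`"no"`/`"untested"`); annotations missing from the control
#'   table are `untested` and collected in the `"warnings"` attribute.
#' @export
detect_n_oxide <- function(control, treated, annotations,
                           drop_fraction = 0.8, mz_tol_ppm = 5,
                           rt_tol = 0.2, partner_rt_tol = NULL) {
  if (drop_fraction <= 0 || drop_fraction > 1)
    stop("drop_fraction must be in (0, 1]")
  ann <- if (inherits(annotations, "metid_annotation")) {
    annotations$annotations[annotations$annotations$rank == 1L, , drop = FALSE]
  } else annotations
  o_mass <- .ATOMIC_MASS[["O"]]
  flags <- character(nrow(ann))
  warnings <- character(0)
  for (i in seq_len(nrow(ann))) {
    steps <- ann$steps[[i]]
    oxidized <- !is.null(steps) && "oxidation" %in% names(steps) &&
      steps[["oxidation"]] >= 1L
    if (!oxidized) { flags[i] <- "untested"; next }
    ctrl_int <- .match_intensity(control, ann$mz[i], ann$rt_min[i],
                                 mz_tol_ppm, rt_tol)
    if (ctrl_int == 0) {
      flags[i] <- "untested"
      warnings <- c(warnings, sprintf(
        "annotation at m/z %.4f rt %.2f not found in control peak list",
        ann$mz[i], ann$rt_min[i]))
      next
    }
    trt_int <- .match_intensity(treated, ann$mz[i], ann$rt_min[i],
                                mz_tol_ppm, rt_tol)
    dropped <- trt_int <= (1 - drop_fraction) * ctrl_int
    partner_rt <- if (is.null(partner_rt_tol)) NULL else ann$rt_min[i]
    # anchor the partner search on the annotation's theoretical m/z when
    # available: the assigned composition is mass-error-free, so only the
    # partner peak's own jitter enters the ppm window
    base_mz <- if ("theoretical_mz" %in% names(ann)) ann$theoretical_mz[i]
               else ann$mz[i]
    gained <- .any_peak_gain(control, treated, base_mz - o_mass, partner_rt,
                             mz_tol_ppm, partner_rt_tol %||% Inf)
    flags[i] <- if (dropped && gained) "yes" else "no"
  }
  ann$n_oxide <- flags
  attr(ann, "warnings") <- warnings
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a metabolite characterization report
#'
#' Clusters rank-1 annotations across acquisition conditions (same chain,
#' retention times within `rt_tol`) into one row per metabolite species,
#' sorted by retention time, with per-condition presence flags — the layout
#' of a classic metabolite-characterization table.
#'
#' @param annotations a `metid_annotation`, or an annotation data.frame
#'   (rank-1 rows are used when a `rank` column is present). Optional
#'   columns `localization` and `n_oxide` are carried through.
#' @param labels optional character vector of species labels in rt order;
#'   auto-generated (`M1`, `M2`, ... with the 0-step chain as `Parent`)
#'   when omitted. Duplicates are suffixed deterministically (`_2`, `_3`).
#' @param conditions conditions to report presence for; default all present.
#' @param rt_tol rt window (minutes) for clustering the same species across
#'   conditions.
#' @return data.frame with columns `label`, `transformation`,
#'   `theoretical_mz` (4 dp), `formula`, `rt_min`, `ppm`, `localization`,
#'   `n_oxide` and one logical presence column per condition.
#' @export
build_metabolite_report <- function(annotations, labels = NULL,
                                    conditions = NULL, rt_tol = 0.2) {
  ann <- if (inherits(annotations, "metid_annotation")) annotations$annotations
         else annotations
  if ("rank" %in% names(ann)) ann <- ann[ann$rank == 1L, , drop = FALSE]
  if (is.null(conditions)) conditions <- unique(ann$condition)
  empty_cols <- c("label", "transformation", "theoretical_mz", "formula",
                  "rt_min", "ppm", "localization", "n_oxide")
  if (nrow(ann) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(empty_cols)),
                                  empty_cols))
    for (cd in conditions) out[[cd]] <- logical(0)
    return(out)
  }
  if (!"localization" %in% names(ann)) ann$localization <- "unlocalized"
  if (!"n_oxide" %in% names(ann)) ann$n_oxide <- "untested"
  ann <- ann[order(ann$rt_min), , drop = FALSE]
  # greedy rt clustering within identical chain assignment
  cluster <- integer(nrow(ann))
  anchors <- list()  # list of (chain, rt)
  for (i in seq_len(nrow(ann))) {
    hit <- 0L
    for (j in seq_along(anchors)) {
      if (anchors[[j]]$chain == ann$chain[i] &&
          abs(anchors[[j]]$rt - ann$rt_min[i]) <= rt_tol) { hit <- j; break }
    }
    if (hit == 0L) {
      anchors[[length(anchors) + 1L]] <- list(chain = ann$chain[i],
                                              rt = ann$rt_min[i])
      hit <- length(anchors)
    }
    cluster[i] <- hit
  }
  rows <- lapply(seq_along(anchors), function(j) {
    g <- ann[cluster == j, , drop = FALSE]
    loc <- setdiff(unique(g$localization), "unlocalized")
    nox <- setdiff(unique(g$n_oxide), "untested")
    out <- data.frame(
      transformation = g$chain[1],
      theoretical_mz = round_half_up(g$theoretical_mz[1], 4),
      formula = g$formula[1],
      rt_min = g$rt_min[1],
      ppm = g$ppm[which.min(abs(g$ppm))],
      localization = if (length(loc) == 1L) loc else g$localization[1],
      n_oxide = if (length(nox) == 1L) nox else g$n_oxide[1],
      stringsAsFactors = FALSE
    )
    for (cd in conditions) out[[cd]] <- cd %in% g$condition
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rt_min), , drop = FALSE]
  if (is.null(labels)) {
    labels <- character(nrow(out))
    is_parent <- out$transformation == "Parent"
    labels[is_parent] <- "Parent"
    labels[!is_parent] <- paste0("M", seq_len(sum(!is_parent)))
  }
  if (length(labels) != nrow(out))
    stop("length of 'labels' must equal the number of report rows")
  dup <- duplicated(labels)
  if (any(dup)) labels <- make.unique(labels, sep = "_")
  out <- cbind(data.frame(label = labels, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Corrected metabolite characterization table of Daporinad
#'
#' The 26-row characterization table (parent plus 25 phase-I metabolites)
#' with label, transformation, theoretical `[M+H]+` m/z, formula, retention
#' time and per-matrix presence flags. Two printed formulas that are
#' internally inconsistent with their own m/z and transformation (the amide
#' hydrolysis and di-desaturation rows) are corrected in the `formula`
#' column; the as-printed strings are kept in `formula_printed` and the
#' `note` column records each correction.
#'
#' @return data.frame with one row per species, in retention-time order.
#' @export
daporinad_metabolites <- function() {
  path <- system.file("extdata", "daporinad_metabolites.csv",
                      package = "dmpkid", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("mouse_liver_microsome", "human_liver_microsome", "mouse_plasma"))
    tbl[[cl]] <- tbl[[cl]] == "O"
  tbl
}

#' Daporinad parent formula
#'
#' @return the `elemental_formula` C24H29N3O2.
#' @export
daporinad_formula <- function() parse_formula("C24H29N3O2")

#' Peak list transcribed from the Daporinad characterization table
#'
#' Expands [daporinad_metabolites()] into a centroided peak table: one peak
#' per species per matrix in which it was detected, at the table's m/z and
#' retention time. Intensities are a fixed arbitrary placeholder (relative
#' abundances are not part of the characterization table).
#'
#' @param conditions matrices to include.
#' @param intensity placeholder intensity.
#' @return a peak data.frame as from [peak_table()].
#' @export
daporinad_peaks <- function(conditions = c("mouse_liver_microsome",
                                           "human_liver_microsome",
                                           "mouse_plasma"),
                            intensity = 1e5) {
  tbl <- daporinad_metabolites()
  rows <- lapply(conditions, function(cd) {
    sub <- tbl[tbl[[cd]], , drop = FALSE]
    peak_table(cd, sub$rt_min, sub$mz, intensity)
  })
  do.call(rbind, rows)
}
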