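# CSV readers/writers for the tabular dialects used across the package.
# Units are fixed by column name, never guessed: rt in minutes, m/z in Th,
# concentrations in ng/mL, times in minutes.

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- list()
  for (cl in numeric_cols) {
    raw <- tbl[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    nas <- which(is.na(val) & !is.na(raw) & nzchar(trimws(as.character(raw))))
    if (length(nas))
      bad[[cl]] <- data.frame(line = nas + 1L, column = cl,
                              value = as.character(raw[nas]),
                              stringsAsFactors = FALSE)
    tbl[[cl]] <- val
  }
  if (length(bad)) {
    report <- do.call(rbind, bad)
    stop("non-numeric values in numeric column(s):\n",
         paste(sprintf("  line %d, column %s: '%s'", report$line,
                       report$column, report$value), collapse = "\n"))
  }
  tbl
}

#' Read a centroided peak table
#'
#' CSV with required header `condition,rt_min,mz,intensity`.
#'
#' @param path path to the CSV file.
#' @return a validated peak data.frame (see [peak_table()]).
#' @export
read_peak_table <- function(path) {
  tbl <- read_checked_csv(path, c("condition", "rt_min", "mz", "intensity"),
                          c("rt_min", "mz", "intensity"))
  if (nrow(tbl) == 0L)
    return(peak_table(character(0), numeric(0), numeric(0), numeric(0)))
  peak_table(tbl$condition, tbl$rt_min, tbl$mz, tbl$intensity)
}

#' Read a product-ion spectrum table
#'
#' CSV with required header `precursor_mz,fragment_mz,intensity`. Rows are
#' grouped by precursor m/z.
#'
#' @param path path to the CSV file.
#' @return named list of spectra (data.frames `fragment_mz`, `intensity`,
#'   each with a `precursor_mz` attribute), names formatted from the
#'   precursor m/z.
#' @export
read_ms2_table <- function(path) {
  tbl <- read_checked_csv(path, c("precursor_mz", "fragment_mz", "intensity"),
                          c("precursor_mz", "fragment_mz", "intensity"))
  if (any(tbl$fragment_mz >= tbl$precursor_mz + 0.5))
    stop("fragment m/z above precursor m/z + 0.5: not a product-ion spectrum")
  out <- lapply(split(tbl, format(tbl$precursor_mz, nsmall = 4)), function(g) {
    sp <- data.frame(fragment_mz = g$fragment_mz, intensity = g$intensity)
    attr(sp, "precursor_mz") <- g$precursor_mz[1]
    sp
  })
  out
}

#' Read concentration-time profiles
#'
#' CSV with required header
#' `subject_id,dose_mg_kg,time_min,conc_ng_ml` and optional `blq` column.
#'
#' @param path path to the CSV file.
#' @return list of [pk_profile()] objects, one per subject.
#' @export
read_pk_profiles <- function(path) {
  tbl <- read_checked_csv(path,
                          c("subject_id", "dose_mg_kg", "time_min", "conc_ng_ml"),
                          c("dose_mg_kg", "time_min", "conc_ng_ml"))
  lapply(split(tbl, tbl$subject_id), function(g) {
    g <- g[order(g$time_min), ]
    blq <- if ("blq" %in% names(g)) as.logical(g$blq) else NULL
    pk_profile(g$subject_id[1], g$dose_mg_kg[1], g$time_min, g$conc_ng_ml, blq)
  })
}

#' Read a bioanalytical batch table
#'
#' CSV with required header
#' `run_id,sample_type,level_id,nominal_conc,area_ratio` and optional
#' `dilution_factor` and `condition` columns. `sample_type` distinguishes
#' `STD`, `QC`, `DIL`, `STAB` and `UNK` rows.
#'
#' @param path path to the CSV file.
#' @return the validated data.frame, with `dilution_factor` defaulting to 1
#'   and `condition` to `""` when absent.
#' @export
read_calibration_batch <- function(path) {
  tbl <- read_checked_csv(path,
                          c("run_id", "sample_type", "level_id",
                            "nominal_conc", "area_ratio"),
                          c("nominal_conc", "area_ratio"))
  if (!"dilution_factor" %in% names(tbl)) tbl$dilution_factor <- 1
  else tbl$dilution_factor <- as.numeric(tbl$dilution_factor)
  if (!"condition" %in% names(tbl)) tbl$condition <- ""
  tbl
}

#' Write a report table deterministically
#'
#' Writes records as TSV or a GitHub-style markdown table with a
#' deterministic column order and formatting (m/z columns at 4 decimal
#' places, percentage columns at 3 significant figures), so identical
#' input yields byte-identical files.
#'
#' @param records a data.frame.
#' @param path output file path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  fmt <- records
  for (cl in names(fmt)) {
    if (grepl("(^|_)mz$|^mz(_|$)|theoretical_mz", cl) && is.numeric(fmt[[cl]]))
      fmt[[cl]] <- sprintf("%.4f", round_half_up(fmt[[cl]], 4))
    else if (grepl("_pct$|accuracy|cv", cl) && is.numeric(fmt[[cl]]))
      fmt[[cl]] <- signif(fmt[[cl]], 3)
  }
  if (format == "tsv") {
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    cells <- vapply(fmt, function(x) as.character(x), character(nrow(fmt)))
    if (nrow(fmt) == 1L) cells <- matrix(cells, nrow = 1)
    lines <- c(paste0("| ", paste(names(fmt), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|"),
               if (nrow(fmt))
                 apply(cells, 1, function(r)
                   paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, path)
  }
  invisible(path)
}
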