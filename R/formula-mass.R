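# Monoisotopic atomic masses (Da), pinned so results are bit-reproducible.
# Values for the most abundant isotope of each element.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668
)

# Integer (nominal) masses for the same elements.
.NOMINAL_MASS <- c(
  C = 12L, H = 1L, N = 14L, O = 16L, S = 32L, P = 31L, Cl = 35L,
  F = 19L, Br = 79L, I = 127L, Na = 23L, K = 39L
)

#' Mass of a proton in Da
#'
#' The electron-corrected proton mass used for protonated-adduct m/z,
#' as opposed to the hydrogen-atom mass (1.00782503207 Da).
#' @export
PROTON_MASS <- 1.00727646

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' ("round half-up" for positive values), the convention used when
#' reporting theoretical m/z at 4 decimal places. Base [round()] uses
#' round-half-to-even and can differ on exact ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse a molecular formula string
#'
#' Parses Hill-style molecular formulas such as `"C24H29N3O2"` into a named
#' integer vector of element counts. Underscores and whitespace are stripped
#' before parsing, so the subscript rendering `"C_24_H_29_N_3_O_2_"` found in
#' typeset tables parses identically to the plain string. An element symbol
#' without a following number has an implicit count of 1.
#'
#' @param text a single formula string.
#' @return An object of class `elemental_formula`: a named integer vector of
#'   element counts with zero-count elements absent, sorted in Hill order
#'   (C, H, then alphabetical).
#' @examples
#' parse_formula("C24H29N3O2")
#' parse_formula("C_16_H_23_NO_2_")  # same as "C16H23NO2"
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single formula string")
  clean <- gsub("[_[:space:]]", "", text)
  if (!nzchar(clean))
    stop("empty formula string")
  counts <- integer(0)
  rest <- clean
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop(sprintf("cannot parse formula at '%s'", rest))
    sym <- m[2]
    if (!sym %in% names(.ATOMIC_MASS))
      stop(sprintf("unknown element symbol '%s' in '%s'", sym, text))
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }
  new_formula(counts)
}

# Constructor: drops zero counts, orders Hill-style, validates non-negativity.
new_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L))
    stop("invalid transformation: negative element count for ",
         paste(names(counts)[counts < 0L], collapse = ", "))
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  counts <- counts[ord]
  storage.mode(counts) <- "integer"
  structure(counts, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", formula_string(x), "\n")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(unclass(new_formula(unclass(e1))), unclass(new_formula(unclass(e2))))
}

#' Render a formula as a Hill-order string
#'
#' @param f an `elemental_formula` (or named count vector).
#' @return a single string, e.g. `"C24H29N3O2"`; `""` for the empty formula.
#' @export
formula_string <- function(f) {
  f <- unclass(f)
  f <- f[f != 0]
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) return(new_formula(as.integer(f)))
  stop("cannot interpret 'f' as a molecular formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element count times monoisotopic atomic mass, using pinned
#' atomic-mass constants (H 1.00782503207, C 12 exactly, N 14.0030740048,
#' O 15.9949146196, ...).
#'
#' @param f an `elemental_formula`, a formula string, or a named count vector.
#' @return neutral monoisotopic mass in Da; 0 for the empty formula.
#' @examples
#' monoisotopic_mass("C24H29N3O2")  # 391.2260 Da
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(unclass(f) * .ATOMIC_MASS[names(f)])
}

#' Nominal (integer) mass of a molecular formula
#'
#' Used for the whole-amu mass-difference taxonomy of biotransformations
#' (e.g. an amide-bond cleavage losing C8H5NO is a 131 amu loss).
#'
#' @inheritParams monoisotopic_mass
#' @return integer nominal mass.
#' @export
nominal_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0L)
  as.integer(sum(unclass(f) * .NOMINAL_MASS[names(f)]))
}

#' Adduct specification
#'
#' Describes an ionization adduct as a proton count and a charge. The
#' default `[M+H]+` covers positive-mode protonation; the type is pluggable
#' for other proton-transfer adducts.
#'
#' @param name display name, e.g. `"[M+H]+"`.
#' @param proton_count number of protons added (may be negative).
#' @param charge nonzero integer charge.
#' @return an `adduct_spec` list.
#' @export
adduct_spec <- function(name = "[M+H]+", proton_count = 1L, charge = 1L) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) stop("adduct charge must be nonzero")
  structure(list(name = name, proton_count = as.integer(proton_count),
                 charge = charge),
            class = "adduct_spec")
}

#' Theoretical adduct m/z
#'
#' m/z = (monoisotopic mass + proton_count x 1.00727646) / |charge|.
#' Full double precision is kept internally; report at 4 decimal places with
#' [round_half_up()] to match conventional table formatting.
#'
#' @inheritParams monoisotopic_mass
#' @param adduct an [adduct_spec()]; default `[M+H]+`.
#' @return theoretical m/z (unrounded).
#' @examples
#' round_half_up(adduct_mz("C24H29N3O2"))  # 392.2333
#' @export
adduct_mz <- function(f, adduct = adduct_spec()) {
  if (!inherits(adduct, "adduct_spec")) stop("'adduct' must be an adduct_spec")
  (monoisotopic_mass(f) + adduct$proton_count * PROTON_MASS) / abs(adduct$charge)
}

#' Signed ppm mass error
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z, must be > 0.
#' @return (observed - theoretical) / theoretical x 1e6, signed.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Apply an elemental delta to a formula
#'
#' Element-wise sum of a formula and a signed element-count delta; the
#' primitive behind biotransformation chains (e.g. oxidation is `{O:+1}`,
#' desaturation `{H:-2}`). A delta driving any count negative signals an
#' impossible transformation on this scaffold and is an error.
#'
#' @inheritParams monoisotopic_mass
#' @param delta named numeric/integer vector of signed element-count changes.
#' @return the shifted `elemental_formula`.
#' @examples
#' formula_shift("C24H29N3O2", c(O = 1))   # C24H29N3O3
#' formula_shift("C24H29N3O2", c(H = -2))  # C24H27N3O2
#' @export
formula_shift <- function(f, delta) {
  f <- unclass(as_formula(f))
  delta <- delta[delta != 0]
  if (length(delta)) {
    if (is.null(names(delta)) || any(!nzchar(names(delta))))
      stop("'delta' must be a named vector of element-count changes")
    unknown <- setdiff(names(delta), names(.ATOMIC_MASS))
    if (length(unknown))
      stop("unknown element symbol in delta: ", paste(unknown, collapse = ", "))
    for (el in names(delta)) {
      cur <- if (el %in% names(f)) f[[el]] else 0L
      f[el] <- cur + as.integer(delta[[el]])
    }
  }
  new_formula(f)
}

# Monoisotopic mass change of a signed elemental delta.
delta_mass <- function(delta) {
  delta <- delta[delta != 0]
  if (length(delta) == 0L) return(0)
  sum(delta * .ATOMIC_MASS[names(delta)])
}
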