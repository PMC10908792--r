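# Element mass data (IUPAC 2021 atomic masses / isotopic compositions).
# .monoisotopic holds the mass of the principal (most abundant, for these
# elements also the lightest) isotope; .isotopes holds the full natural
# isotope distributions used for fine-structure simulation.

.monoisotopic <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.9769265325,
  Se = 79.9165213
)

.isotopes <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785), abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378),          abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.99913170, 17.9991610),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376163, abundance = 1.0),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.9897692809, abundance = 1.0),
  K  = list(mass = c(38.96370668, 40.96182576), abundance = c(0.932581, 0.067302 + 0.000117)),
  Cl = list(mass = c(34.96885268, 36.96590259), abundance = c(0.7576, 0.2424)),
  F  = list(mass = 18.99840322, abundance = 1.0),
  Br = list(mass = c(78.9183371, 80.9162906), abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.904473, abundance = 1.0),
  Si = list(mass = c(27.9769265325, 28.976494700, 29.97377017),
            abundance = c(0.92223, 0.04685, 0.03092)),
  Se = list(mass = 79.9165213, abundance = 1.0)
)

.electron_mass <- 0.000548579909
.proton_mass <- 1.00727646688

#' Parse a molecular formula string
#'
#' Parses a Hill-notation-like formula string (element symbols with optional
#' integer counts, e.g. `"C5H9NO2"`) into a named count vector. Only elements
#' with a bundled monoisotopic mass are accepted.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts, class `"chem_formula"`.
#' @examples
#' parse_formula("C5H9NO2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("formula must be a single non-empty string")
  text <- trimws(text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: ", text)
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(.monoisotopic))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(cnts <= 0L)) stop("non-positive element count in formula: ", text)
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out[order(names(out))], class = "chem_formula")
}

#' Format element counts as a canonical Hill-order formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (all elements alphabetical when no carbon is present).
#'
#' @param formula Named count vector as returned by [parse_formula()].
#' @return Formula string.
#' @export
format_formula <- function(formula) {
  formula <- as_formula(formula)
  syms <- names(formula)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(formula[ord] > 1L, formula[ord], ""), collapse = "")
}

# Accept either a formula string or an already-parsed count vector.
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x <= 0)) stop("non-positive element count")
    unknown <- setdiff(names(x), names(.monoisotopic))
    if (length(unknown)) stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    return(structure(as.integer(x), names = names(x), class = "chem_formula"))
  }
  stop("cannot interpret object as a chemical formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the principal-isotope mass from the
#' bundled IUPAC table, in Da.
#'
#' @param formula Formula string or parsed count vector.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(.monoisotopic[names(f)] * as.numeric(f))
}

#' Electrospray adduct rules
#'
#' The adduct set used throughout: protonation/deprotonation as the base
#' ionisation plus sodium, potassium (positive) and chloride (negative)
#' attachment. Mass deltas account for the electron mass; all species are
#' singly charged.
#'
#' @return `data.frame` with columns `name`, `polarity`, `mass_delta`, `charge`.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+Cl]-"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    mass_delta = c(
      .proton_mass,
      .monoisotopic[["Na"]] - .electron_mass,
      .monoisotopic[["K"]] - .electron_mass,
      -.proton_mass,
      .monoisotopic[["Cl"]] + .electron_mass
    ),
    charge = c(1L, 1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

adduct_rule <- function(name, adducts = default_adducts()) {
  i <- match(name, adducts$name)
  if (is.na(i)) stop("unknown adduct: ", name)
  adducts[i, , drop = FALSE]
}

#' Theoretical m/z of an adduct ion
#'
#' @param formula Formula string or parsed count vector (the neutral molecule).
#' @param adduct Adduct name (see [default_adducts()]) or a one-row adduct
#'   `data.frame` with `mass_delta` and `charge`.
#' @return m/z in Da for the singly charged ion.
#' @examples
#' theoretical_mz("C5H9NO2", "[M+H]+") # 116.070605
#' @export
theoretical_mz <- function(formula, adduct) {
  if (is.character(adduct)) adduct <- adduct_rule(adduct)
  if (adduct$charge == 0L) stop("adduct charge must be non-zero")
  (monoisotopic_mass(formula) + adduct$mass_delta) / abs(adduct$charge)
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}
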