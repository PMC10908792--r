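# Isotopic fine-structure simulation and pattern scoring.
#
# At FT-ICR resolving power (~488,000 at m/z 400) isotopologue fine structure
# is partially resolved; a simulated pattern at the instrument's resolution is
# compared against the observed pattern to confirm a formula assignment.

# Convolve two (mass, abundance) distributions, pruning tiny terms.
.convolve_dist <- function(a, b, prune) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance, `*`)
  keep <- ab >= prune * max(ab)
  d <- list(mass = mass[keep], abundance = ab[keep])
  # collapse numerically identical masses to keep the term count bounded
  key <- round(d$mass * 2e5)
  ab2 <- rowsum(d$abundance, key)
  m2 <- rowsum(d$mass * d$abundance, key) / ab2
  list(mass = as.numeric(m2), abundance = as.numeric(ab2))
}

# Distribution of n atoms of one element, by binary exponentiation.
.element_dist <- function(element, n, prune) {
  iso <- .isotopes[[element]]
  single <- list(mass = iso$mass, abundance = iso$abundance)
  if (length(iso$mass) == 1L)
    return(list(mass = iso$mass * n, abundance = 1.0))
  result <- NULL
  power <- single
  while (n > 0L) {
    if (n %% 2L == 1L)
      result <- if (is.null(result)) power else .convolve_dist(result, power, prune)
    n <- n %/% 2L
    if (n > 0L) power <- .convolve_dist(power, power, prune)
  }
  result
}

#' Simulate the isotopic fine structure of a molecular formula
#'
#' Expands the multinomial isotopologue distribution over natural isotope
#' abundances, truncates below a relative-abundance floor, and merges peaks
#' closer than the FWHM implied by the resolving power using an
#' abundance-weighted centroid.
#'
#' @param formula Formula string or parsed count vector.
#' @param resolving_power Mass resolving power (FWHM definition); default
#'   488000, the instrument's value at m/z 400.
#' @param floor Minimum relative abundance (fraction of the base peak) kept.
#' @return `data.frame` of class `"isotope_pattern"` with columns `mz`
#'   (increasing) and `abundance` (base peak = 1).
#' @examples
#' isotope_pattern("C5H9NO2")
#' @export
isotope_pattern <- function(formula, resolving_power = 488000, floor = 1e-4) {
  if (resolving_power <= 0) stop("resolving_power must be positive")
  f <- as_formula(formula)
  prune <- floor * 1e-3
  dist <- NULL
  for (el in names(f)) {
    d <- .element_dist(el, f[[el]], prune)
    dist <- if (is.null(dist)) d else .convolve_dist(dist, d, prune)
  }
  ord <- order(dist$mass)
  mz <- dist$mass[ord]
  ab <- dist$abundance[ord]
  # merge peaks unresolved at the given resolving power
  fwhm <- mz / resolving_power
  grp <- cumsum(c(1, as.integer(diff(mz) > fwhm[-length(fwhm)])))
  ab_m <- as.numeric(rowsum(ab, grp))
  mz_m <- as.numeric(rowsum(mz * ab, grp)) / ab_m
  rel <- ab_m / max(ab_m)
  keep <- rel >= floor
  out <- data.frame(mz = mz_m[keep], abundance = rel[keep])
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Shift an isotope pattern from the neutral to an adduct-ion m/z scale
#'
#' @param pattern Pattern from [isotope_pattern()].
#' @param adduct Adduct name or one-row adduct data frame.
#' @return The pattern with `mz` shifted by the adduct mass delta.
#' @export
shift_pattern <- function(pattern, adduct) {
  if (is.character(adduct)) adduct <- adduct_rule(adduct)
  pattern$mz <- (pattern$mz + adduct$mass_delta) / abs(adduct$charge)
  pattern
}

#' Score the fit between an observed and a theoretical isotope pattern
#'
#' Both patterns must be on the same m/z scale (use [shift_pattern()] to move
#' a theoretical neutral pattern onto the ion scale). Each theoretical peak is
#' matched to the nearest observed peak within a ppm tolerance. The score is
#' 1000 times the weighted root-mean-square relative deviation of matched
#' abundances, with weights proportional to the square root of the theoretical
#' abundance; theoretical peaks above the floor with no observed match count
#' as full (100%) deviation. 0 is a perfect fit; assignments are
#' conventionally rejected above 300.
#'
#' @param observed,theoretical Patterns as returned by [isotope_pattern()]
#'   (data frames with `mz` and `abundance`).
#' @param tol_ppm Match tolerance on m/z, relative to the base-peak m/z.
#' @param floor Theoretical peaks below this relative abundance are ignored.
#' @return Non-negative score (dimensionless).
#' @export
isotope_fit_score <- function(observed, theoretical, tol_ppm = 2, floor = 1e-3) {
  if (NROW(observed) == 0L || NROW(theoretical) == 0L)
    stop("both patterns must be non-empty")
  th_base <- theoretical$mz[which.max(theoretical$abundance)]
  tol_da <- tol_ppm * 1e-6 * th_base
  if (min(abs(observed$mz - th_base)) > tol_da)
    stop("no matchable base peak")
  th <- theoretical[theoretical$abundance >= floor, , drop = FALSE]
  dev <- vapply(seq_len(nrow(th)), function(i) {
    d <- abs(observed$mz - th$mz[i])
    j <- which.min(d)
    if (d[j] <= tol_da) (observed$abundance[j] - th$abundance[i]) / th$abundance[i] else 1.0
  }, numeric(1))
  w <- sqrt(th$abundance)
  1000 * sqrt(sum(w * dev^2) / sum(w))
}
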