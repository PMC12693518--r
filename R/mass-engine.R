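## Oligonucleotide mass arithmetic: elemental compositions, neutral masses and
## negative-mode charge-state conversion. Residue formulas and atomic masses
## are shipped as data (inst/extdata/residues.json).

.ELEMENTS <- c("C", "H", "N", "O", "P", "C13", "N15")

#' @keywords internal
.residueConfig <- function() {
  if (is.null(.bermass_cache$residues)) {
    path <- system.file("extdata", "residues.json", package = "bermass",
                        mustWork = TRUE)
    .bermass_cache$residues <- jsonlite::read_json(path)
  }
  .bermass_cache$residues
}

#' @keywords internal
.emptyComposition <- function() setNames(numeric(length(.ELEMENTS)), .ELEMENTS)

#' Elemental composition of a single residue
#'
#' Returns the formula of a nucleotide residue as it enters an
#' oligonucleotide chain: the 5'-monophosphate free acid (the chain total is
#' corrected by one water per phosphodiester linkage in
#' \code{\link{fragmentComposition}}). Heavy residues (fully
#' \eqn{^{13}C,^{15}N}-substituted dAMP/dGMP) book their carbon and nitrogen
#' under separate \code{C13}/\code{N15} counts.
#'
#' @param code residue code: \code{A, C, G, T, U, AP, rAP, F}.
#' @param heavy logical; full isotopic substitution (A and G only).
#' @return named numeric vector over \code{C, H, N, O, P, C13, N15}.
#' @examples
#' residueComposition("A")            # dAMP: C10 H14 N5 O6 P
#' residueComposition("G", heavy = TRUE)
#' @export
residueComposition <- function(code, heavy = FALSE) {
  cfg <- .residueConfig()
  f <- cfg$residues[[code]]
  if (is.null(f)) stop("unknown residue code: ", code, call. = FALSE)
  comp <- .emptyComposition()
  for (e in names(f)) comp[e] <- as.numeric(f[[e]])
  if (heavy) {
    sub <- cfg$heavy_substitution[[code]]
    if (is.null(sub))
      stop("heavy labeling is only supported for A and G", call. = FALSE)
    comp["C13"] <- as.numeric(sub$C13); comp["C"] <- comp["C"] - comp["C13"]
    comp["N15"] <- as.numeric(sub$N15); comp["N"] <- comp["N"] - comp["N15"]
    if (comp["C"] < 0 || comp["N"] < 0)
      stop("heavy substitution exceeds residue formula", call. = FALSE)
  }
  comp
}

#' Elemental composition of a DNA fragment
#'
#' Sums residue formulas and applies the linkage correction
#' \eqn{-(n-1)\,\mathrm{H_2O}}, then adjusts the 5' end: residue formulas
#' carry a 5'-phosphate, so a 5'-hydroxyl fragment loses one HPO3. A
#' 3'-phosphate (rare here; restriction cuts leave 3'-OH) adds one HPO3.
#'
#' @param residues character vector of residue codes, 5' to 3'.
#' @param heavy logical vector parallel to \code{residues} (default all
#'   light).
#' @param fivePrime \code{"phosphate"} (default; restriction cut chemistry) or
#'   \code{"hydroxyl"}.
#' @param threePrime \code{"hydroxyl"} (default) or \code{"phosphate"}.
#' @return named numeric composition vector.
#' @examples
#' fragmentComposition(c("A", "C", "G", "T"))
#' @export
fragmentComposition <- function(residues, heavy = rep(FALSE, length(residues)),
                                fivePrime = c("phosphate", "hydroxyl"),
                                threePrime = c("hydroxyl", "phosphate")) {
  fivePrime <- match.arg(fivePrime)
  threePrime <- match.arg(threePrime)
  if (!length(residues)) stop("empty fragment", call. = FALSE)
  if (length(heavy) != length(residues))
    stop("heavy must be parallel to residues", call. = FALSE)
  comp <- .emptyComposition()
  for (i in seq_along(residues))
    comp <- comp + residueComposition(residues[i], heavy[i])
  n <- length(residues)
  h2o <- c(C = 0, H = 2, N = 0, O = 1, P = 0, C13 = 0, N15 = 0)
  hpo3 <- c(C = 0, H = 1, N = 0, O = 3, P = 1, C13 = 0, N15 = 0)
  comp <- comp - (n - 1) * h2o[.ELEMENTS]
  if (fivePrime == "hydroxyl") comp <- comp - hpo3[.ELEMENTS]
  if (threePrime == "phosphate") comp <- comp + hpo3[.ELEMENTS]
  if (any(comp < 0)) stop("negative element count in composition", call. = FALSE)
  comp
}

#' Neutral mass of an elemental composition
#'
#' @param comp named composition vector (as returned by
#'   \code{\link{fragmentComposition}}), or a character vector of residue
#'   codes which is first passed through \code{fragmentComposition} with
#'   default end chemistry.
#' @param ... passed to \code{fragmentComposition} when \code{comp} is a
#'   residue vector.
#' @return named numeric vector \code{c(monoisotopic =, average =)} in Da.
#' @examples
#' neutralMass(fragmentComposition("A"))   # dAMP, 331.0682 Da monoisotopic
#' @export
neutralMass <- function(comp, ...) {
  if (is.character(comp)) comp <- fragmentComposition(comp, ...)
  cfg <- .residueConfig()
  am <- cfg$atomic_masses
  mono <- sum(vapply(.ELEMENTS, function(e)
    comp[[e]] * am[[e]]$monoisotopic, numeric(1)))
  avg <- sum(vapply(.ELEMENTS, function(e)
    comp[[e]] * am[[e]]$average, numeric(1)))
  c(monoisotopic = mono, average = avg)
}

#' Mass shift of one heavy-to-light replacement
#'
#' The monoisotopic mass decrease when one fully substituted heavy residue is
#' replaced by its normal-mass counterpart during repair synthesis:
#' \eqn{10\,( ^{13}C - ^{12}C) + 5\,( ^{15}N - ^{14}N) \approx 15.0187} Da for
#' dAMP and dGMP alike. This is the spacing of the assay's mass ladder.
#'
#' @param code \code{"A"} or \code{"G"}.
#' @return mass difference in Da (positive).
#' @export
heavyMassShift <- function(code = "G") {
  h <- neutralMass(residueComposition(code, heavy = TRUE))
  l <- neutralMass(residueComposition(code, heavy = FALSE))
  unname(h["monoisotopic"] - l["monoisotopic"])
}

## Charge-carrier constant. The assay's stated reduction uses 1.008 Da per
## charge (negative mode, deprotonation); the physically exact proton mass is
## selectable.
PROTON_PAPER <- 1.008
PROTON_EXACT <- 1.007276466

#' Negative-mode m/z for a neutral mass
#'
#' @param M neutral mass in Da.
#' @param z charge magnitude (positive integer).
#' @param proton charge-carrier mass per unit charge; default 1.008 Da
#'   (\code{PROTON_PAPER}), with \code{PROTON_EXACT} available.
#' @return m/z value(s); exact inverse of \code{\link{deconvolveMz}}.
#' @examples
#' mzForCharge(6000.048, 6)   # 999.0
#' @export
mzForCharge <- function(M, z, proton = PROTON_PAPER) {
  z <- as.integer(z)
  if (any(z < 1L)) stop("charge z must be a positive integer", call. = FALSE)
  M / z - proton
}

#' Deconvolve an m/z value to neutral mass
#'
#' Negative-ion mode: measured neutral mass \eqn{M = (m/z + 1.008) \cdot z}.
#'
#' @param mz observed m/z.
#' @param z charge magnitude (positive integer).
#' @param proton charge-carrier mass (see \code{\link{mzForCharge}}).
#' @return neutral mass in Da.
#' @examples
#' deconvolveMz(999.0, 6)   # 6000.048
#' @export
deconvolveMz <- function(mz, z, proton = PROTON_PAPER) {
  z <- as.integer(z)
  if (any(z < 1L)) stop("charge z must be a positive integer", call. = FALSE)
  (mz + proton) * z
}
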