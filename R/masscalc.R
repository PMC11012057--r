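# Exact-mass arithmetic: monoisotopic masses, adduct ion m/z with electron
# correction, ppm errors, mass defect, and constrained CHNO formula
# enumeration.

# Monoisotopic atomic masses (Da), IUPAC/CODATA values.  Orbitrap-level mass
# accuracy (sub-ppm at m/z 100-1000) demands >= 8 decimal places here: a
# 1e-6 Da slip is already 0.002 ppm at m/z 500.
ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268
)

ELECTRON_MASS <- 0.000548579909
# A protonated ion gains a hydrogen nucleus, not a hydrogen atom: the charge
# carrier has lost its electron.  Using the H-atom mass instead shifts every
# [M+H]+ m/z by +0.00055 Da, i.e. about +1.2 ppm at m/z 433.
PROTON_MASS <- ATOMIC_MASS[["H"]] - ELECTRON_MASS

#' Parse a molecular formula string
#'
#' Parses a Hill-order elemental formula such as \code{"C21H20O10"} into a
#' named integer vector of element counts.  An element symbol without an
#' explicit count means a count of one.
#'
#' @param x Character vector of formula strings.
#' @return For a single string, a named integer vector of counts (class
#'   \code{"formula_counts"}); for a vector, a list of such vectors.
#' @examples
#' parse_formula("C21H20O10")
#' @export
parse_formula <- function(x) {
  if (length(x) > 1L) return(lapply(x, parse_formula))
  if (is.na(x) || !nzchar(x)) {
    stop(errorCondition("empty formula string", class = c("herbmarker_formula_error", "error", "condition")))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    stop(errorCondition(sprintf("cannot parse formula string: '%s'", x),
                        class = c("herbmarker_formula_error", "error", "condition")))
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]$", tokens), sub("^[A-Za-z]+", "", tokens), "1"))
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  validate_formula(out)
  class(out) <- "formula_counts"
  out
}

validate_formula <- function(counts) {
  if (any(counts < 0L)) stop("formula counts must be non-negative")
  if (sum(counts) == 0L) stop("formula must contain at least one atom")
  invisible(counts)
}

#' Format element counts as a Hill-order formula string
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string with carbon first, hydrogen second, and
#'   remaining elements alphabetical (Hill convention).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0L]
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

as_counts <- function(formula) {
  if (is.character(formula)) parse_formula(formula) else formula
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element count times monoisotopic atomic mass, in daltons.
#'
#' @param formula A formula string (e.g. \code{"C21H20O10"}) or a named
#'   count vector from \code{\link{parse_formula}}.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.0105646
#' monoisotopic_mass("C21H20O10")
#' @export
monoisotopic_mass <- function(formula) {
  counts <- as_counts(formula)
  unknown <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(unknown)) {
    stop(errorCondition(
      sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
      class = c("herbmarker_mass_error", "error", "condition")))
  }
  sum(ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

#' Registered adduct rules
#'
#' The adduct registry ships as a plain-text table
#' (\code{inst/extdata/adducts.csv}) with electron-corrected mass deltas:
#' a protonated ion adds the mass of a bare proton (1.00727645 Da), a
#' sodiated ion adds Na minus one electron.  All registered adducts are
#' singly charged positive ions.
#'
#' @param path Optional path to an alternative registry CSV with columns
#'   \code{name,mass_delta,charge}.
#' @return A data.frame with columns \code{name}, \code{mass_delta},
#'   \code{charge}.
#' @export
adduct_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adducts.csv", package = "herbmarker")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mass_delta", "charge") %in% names(reg)))
  reg
}

adduct_delta <- function(adduct, registry = adduct_registry()) {
  i <- match(adduct, registry$name)
  if (anyNA(i)) {
    stop(errorCondition(
      sprintf("unregistered adduct '%s'; registered: %s",
              adduct[which(is.na(i))[1]], paste(registry$name, collapse = ", ")),
      class = c("herbmarker_adduct_error", "error", "condition")))
  }
  registry$mass_delta[i]
}

#' Theoretical ion m/z under an adduct rule
#'
#' @param formula Neutral molecular formula (string or count vector).
#' @param adduct Registered adduct name, e.g. \code{"[M+H]+"}.
#' @param registry Adduct registry data.frame (see
#'   \code{\link{adduct_registry}}).
#' @return Theoretical m/z in Da: (monoisotopic mass + adduct delta) / |z|.
#' @examples
#' ion_mz("C21H20O10", "[M+H]+")   # 433.11292
#' ion_mz("C21H20O10", "[M+Na]+")  # 455.09487
#' @export
ion_mz <- function(formula, adduct, registry = adduct_registry()) {
  i <- match(adduct, registry$name)
  if (anyNA(i)) adduct_delta(adduct, registry)  # raises the informative error
  (monoisotopic_mass(formula) + registry$mass_delta[i]) / abs(registry$charge[i])
}

#' Signed mass error in parts per million
#'
#' @param experimental_mz Observed m/z (Da).
#' @param theoretical_mz Theoretical m/z (Da); must be positive.
#' @return \code{1e6 * (experimental - theoretical) / theoretical}.
#' @export
ppm_error <- function(experimental_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    stop(errorCondition("theoretical m/z must be positive",
                        class = c("herbmarker_mass_error", "error", "condition")))
  }
  1e6 * (experimental_mz - theoretical_mz) / theoretical_mz
}

#' Mass defect of an m/z value
#'
#' Fractional part of the m/z, in [0, 1).
#'
#' @param mz Positive m/z value(s).
#' @return \code{mz - floor(mz)}.
#' @export
mass_defect <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive")
  mz - floor(mz)
}

#' Ring-and-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 for a neutral CHNO molecule.
#'
#' @param formula Formula string or count vector.
#' @return RDBE value (multiple of 0.5 for valid CHNO compositions).
#' @export
rdbe <- function(formula) {
  counts <- as_counts(formula)
  g <- function(el) if (el %in% names(counts)) as.numeric(counts[[el]]) else 0
  g("C") - g("H") / 2 + g("N") / 2 + 1
}

#' Constraints for formula enumeration
#'
#' @param elements Allowed elements (default C, H, N, O).
#' @param max_counts Named upper bounds per element.
#' @param ppm_tol Mass tolerance in ppm (default 5, matching typical
#'   high-resolution feature detection).
#' @param rdbe_range Allowed RDBE interval.
#' @param hc_range Allowed H/C ratio interval.
#' @return A list of class \code{"formula_constraints"}.
#' @export
formula_constraints <- function(elements = c("C", "H", "N", "O"),
                                max_counts = c(C = 60, H = 120, N = 10, O = 30),
                                ppm_tol = 5,
                                rdbe_range = c(0, 40),
                                hc_range = c(0.2, 3.1)) {
  if (!length(elements)) {
    stop(errorCondition("element set must be non-empty",
                        class = c("herbmarker_mass_error", "error", "condition")))
  }
  stopifnot(ppm_tol > 0)
  structure(list(elements = elements, max_counts = max_counts,
                 ppm_tol = ppm_tol, rdbe_range = rdbe_range,
                 hc_range = hc_range),
            class = "formula_constraints")
}

constraints_ok <- function(nC, nH, nN, nO, constraints) {
  dbe <- nC - nH / 2 + nN / 2 + 1
  if (dbe < constraints$rdbe_range[1] || dbe > constraints$rdbe_range[2]) return(FALSE)
  if (abs(dbe * 2 - round(dbe * 2)) > 1e-9 || dbe < 0) return(FALSE)
  if (nC > 0 && nH > 0) {
    hc <- nH / nC
    if (hc < constraints$hc_range[1] || hc > constraints$hc_range[2]) return(FALSE)
  } else if (nH > 0) {
    return(FALSE)  # hydrogen without carbon is outside the constraint model
  }
  TRUE
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Exhaustive search over CHNO (or a configured subset) compositions whose
#' monoisotopic mass lies within the ppm tolerance of \code{neutral_mass},
#' subject to per-element count bounds, an RDBE window, and an H/C ratio
#' window.  The search iterates C, N, O and solves for the hydrogen count
#' analytically, so it is exhaustive over the constrained box.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param constraints A \code{\link{formula_constraints}} object.
#' @return A data.frame with columns \code{formula}, \code{mass},
#'   \code{error_ppm}, sorted by absolute ppm error; zero rows when nothing
#'   matches.
#' @examples
#' enumerate_formulas(432.10565)  # contains C21H20O10
#' @export
enumerate_formulas <- function(neutral_mass, constraints = formula_constraints()) {
  if (neutral_mass <= 0) stop("neutral mass must be positive")
  els <- constraints$elements
  if (!length(els)) stop("element set must be non-empty")
  maxc <- function(el) {
    if (!el %in% els) return(0L)
    v <- constraints$max_counts[[el]]
    if (is.null(v) || is.na(v)) 0L else as.integer(v)
  }
  tol_da <- neutral_mass * constraints$ppm_tol * 1e-6
  mC <- ATOMIC_MASS[["C"]]; mH <- ATOMIC_MASS[["H"]]
  mN <- ATOMIC_MASS[["N"]]; mO <- ATOMIC_MASS[["O"]]
  res_f <- character(); res_m <- numeric()
  cmax <- min(maxc("C"), floor((neutral_mass + tol_da) / mC))
  for (nC in 0:cmax) {
    remC <- neutral_mass - nC * mC
    nmax <- min(maxc("N"), floor((remC + tol_da) / mN))
    if (nmax < 0) next
    for (nN in 0:nmax) {
      remN <- remC - nN * mN
      omax <- min(maxc("O"), floor((remN + tol_da) / mO))
      if (omax < 0) next
      for (nO in 0:omax) {
        remO <- remN - nO * mO
        # hydrogen count solving |remO - nH*mH| <= tol_da
        hlo <- max(0L, ceiling((remO - tol_da) / mH))
        hhi <- min(maxc("H"), floor((remO + tol_da) / mH))
        if (hhi < hlo) next
        for (nH in hlo:hhi) {
          if (nC + nH + nN + nO == 0L) next
          if (!constraints_ok(nC, nH, nN, nO, constraints)) next
          mass <- nC * mC + nH * mH + nN * mN + nO * mO
          if (abs(mass - neutral_mass) > tol_da) next
          cnt <- c(C = nC, H = nH, N = nN, O = nO)
          res_f <- c(res_f, format_formula(cnt[cnt > 0L]))
          res_m <- c(res_m, mass)
        }
      }
    }
  }
  err <- if (length(res_m)) ppm_error(neutral_mass, res_m) else numeric()
  out <- data.frame(formula = res_f, mass = res_m, error_ppm = err,
                    stringsAsFactors = FALSE)
  out[order(abs(out$error_ppm)), , drop = FALSE]
}

#' Elements present in a formula
#'
#' @param formula Formula string or count vector.
#' @return Character vector of element symbols with positive counts.
#' @export
formula_elements <- function(formula) {
  counts <- as_counts(formula)
  names(counts)[counts > 0L]
}
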