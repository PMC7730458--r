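.ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

# Principal-isotope (monoisotopic) masses in Da, CODATA/IUPAC values.
.MONO_MASS <- c(
  H  = 1.0078250319, B = 11.0093054, C = 12.0, N = 14.0030740052,
  O  = 15.9949146221, F = 18.9984031627, Si = 27.9769265347,
  P  = 30.97376199, S = 31.97207069, Cl = 34.96885271,
  Br = 78.9183376, I = 126.904473
)

# Standard (average) atomic weights in amu.
.AVG_MASS <- c(
  H  = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F  = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  Br = 79.904, I = 126.904
)

#' Parse a Hill-notation molecular formula
#'
#' Converts a plain-text formula such as `"C23H21NO4"` into a named integer
#' vector of element counts.  Counts must be positive; an omitted count
#' means 1.  The result renders back to a canonical Hill-order string with
#' [format_formula()].
#'
#' @param text Formula string in element-count notation.
#' @param net_charge Integer net charge carried by the species (stored as
#'   an attribute; the mass functions operate on the neutral formula).
#' @return A `molecular_formula` object: named integer vector of counts
#'   with a `net_charge` attribute.
#' @examples
#' parse_formula("C23H21NO4")
#' @export
parse_formula <- function(text, net_charge = 0L) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  rest <- text
  counts <- integer(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("cannot parse formula at: '", rest, "'")
    el <- m[2]
    if (!el %in% .ELEMENTS)
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (n <= 0L)
      stop("element count must be a positive integer: '", el, m[3], "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  new_formula(counts, net_charge)
}

new_formula <- function(counts, net_charge = 0L) {
  counts <- counts[counts > 0L]
  structure(as.integer(counts), names = names(counts),
            net_charge = as.integer(net_charge),
            class = "molecular_formula")
}

#' Render a formula in canonical Hill order
#'
#' Carbon first, then hydrogen, then all other elements alphabetically;
#' when no carbon is present, all elements are alphabetical.
#'
#' @param formula A `molecular_formula`.
#' @return A single string.
#' @export
format_formula <- function(formula) {
  els <- names(formula)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    n <- formula[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format_formula(x))
  q <- attr(x, "net_charge")
  if (!is.null(q) && q != 0L) cat(sprintf(" (net charge %+d)", q))
  cat("\n")
  invisible(x)
}

#' Sum of two molecular formulas
#'
#' @param a,b `molecular_formula` objects.
#' @return Their elementwise sum (net charges add).
#' @export
formula_sum <- function(a, b) {
  els <- union(names(a), names(b))
  counts <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) +
      (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  names(counts) <- els
  new_formula(counts, (attr(a, "net_charge") %||% 0L) +
                (attr(b, "net_charge") %||% 0L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Monoisotopic mass of a neutral formula
#'
#' Sum of principal-isotope masses over the element counts.  The neutral
#' formula mass is reported as-is: no electron mass is subtracted even if
#' the formula carries a net charge, matching the convention used for
#' electron-ionization radical cations where the printed calculated mass
#' is that of the intact neutral.
#'
#' @param formula A `molecular_formula` (or string, parsed on the fly).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C23H21NO4")  # 375.1471
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  els <- names(formula)
  miss <- setdiff(els, names(.MONO_MASS))
  if (length(miss))
    stop("no principal-isotope mass tabulated for: ",
         paste(miss, collapse = ", "))
  sum(.MONO_MASS[els] * as.numeric(formula))
}

#' Average molecular weight of a formula
#'
#' @param formula A `molecular_formula` (or string).
#' @return Molecular weight in amu from standard atomic weights.
#' @export
molecular_weight <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  els <- names(formula)
  miss <- setdiff(els, names(.AVG_MASS))
  if (length(miss))
    stop("no atomic weight tabulated for: ", paste(miss, collapse = ", "))
  sum(.AVG_MASS[els] * as.numeric(formula))
}
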