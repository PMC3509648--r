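# Atomic property tables and carbon-scaled weighting schemes.

the <- new.env(parent = emptyenv())

#' Atomic property table
#'
#' Returns the reference table of atomic properties used to weight
#' descriptors: atomic mass (u), van der Waals volume (cubic Angstrom,
#' sphere at the Bondi radius), Sanderson electronegativity and atomic
#' polarizability (cubic Angstrom). Weighting schemes divide each property
#' by its carbon value, so descriptors depend only on ratios.
#'
#' @return A data frame with one row per supported element and columns
#'   `element`, `mass`, `vdw_volume`, `sanderson_en`, `polarizability`.
#' @export
#' @examples
#' atomic_properties()[atomic_properties()$element == "O", ]
atomic_properties <- function() {
  if (is.null(the$props)) {
    path <- system.file("extdata", "atomic_properties.tsv", package = "qsrr",
                        mustWork = TRUE)
    the$props <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  the$props
}

.scheme_columns <- c(u = NA, m = "mass", v = "vdw_volume",
                     e = "sanderson_en", p = "polarizability")

#' Carbon-scaled atomic weighting scheme
#'
#' Builds a weighting scheme for descriptor computation. Codes follow the
#' usual descriptor nomenclature: `"u"` unweighted, `"m"` atomic mass,
#' `"v"` van der Waals volume, `"e"` Sanderson electronegativity, `"p"`
#' polarizability. All weights are scaled so that carbon has weight 1.
#'
#' @param code One of `"u"`, `"m"`, `"v"`, `"e"`, `"p"`.
#' @return An object of class `weight_scheme`: a list with `code` and
#'   `values` (named per-element weights, carbon = 1).
#' @export
#' @examples
#' weight_scheme("p")$values[["O"]]  # alpha_O / alpha_C
weight_scheme <- function(code = c("u", "m", "v", "e", "p")) {
  code <- match.arg(code)
  props <- atomic_properties()
  if (code == "u") {
    values <- setNames(rep(1, nrow(props)), props$element)
  } else {
    col <- props[[.scheme_columns[[code]]]]
    values <- setNames(col / col[props$element == "C"], props$element)
  }
  stopifnot(all(values > 0), values[["C"]] == 1)
  structure(list(code = code, values = values), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  label <- c(u = "unweighted", m = "atomic mass", v = "van der Waals volume",
             e = "Sanderson electronegativity", p = "polarizability")[x$code]
  cat("Weighting scheme '", x$code, "' (", label, "), carbon-scaled\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Per-atom weights for a molecule
#'
#' Looks up the carbon-scaled weight of every atom of a molecule under a
#' weighting scheme, in atom order.
#'
#' @param mol A [molecule()].
#' @param scheme A [weight_scheme()] or a scheme code.
#' @param include_h Keep hydrogen atoms? Graph descriptors use the
#'   hydrogen-depleted molecule; constitutional and 3D descriptors use all
#'   atoms.
#' @return Numeric vector of weights (named by element).
#' @export
weight_vector <- function(mol, scheme, include_h = TRUE) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  if (is.character(scheme)) scheme <- weight_scheme(scheme)
  elements <- mol$atoms$element
  if (!include_h) elements <- elements[!mol$atoms$is_hydrogen]
  missing <- setdiff(unique(elements), names(scheme$values))
  if (length(missing))
    stop("element(s) not in the atomic property table: ",
         paste(missing, collapse = ", "))
  scheme$values[elements]
}
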