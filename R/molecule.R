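# Molecular data model: atoms, bonds, construction and checks.

#' Construct a molecule
#'
#' The central container for descriptor computation: an ordered atom list
#' (element, optional 3D position in Angstrom), a bond list (atom index
#' pairs with bond order) and a compound name. Molecules parsed from
#' SMILES have no reliable 3D coordinates and are flagged as requiring an
#' embedding step ([embed_structures()]) before 3D descriptors are allowed.
#'
#' @param elements Character vector of element symbols, one per atom, in
#'   atom order. Every element must appear in [atomic_properties()].
#' @param bonds Two- or three-column matrix/data frame of 1-based atom
#'   index pairs, third column the bond order (defaults to 1).
#' @param coords Numeric matrix (n x 3) of coordinates in Angstrom, or
#'   `NULL` for an un-embedded molecule.
#' @param name Compound label.
#' @return An object of class `qsrr_molecule`: list with `atoms` (data
#'   frame: element, x, y, z, is_hydrogen), `bonds` (data frame: from, to,
#'   order), `name`, `has_3d`.
#' @export
#' @examples
#' water <- molecule(c("O", "H", "H"), bonds = rbind(c(1, 2), c(1, 3)),
#'                   coords = rbind(c(0, 0, 0), c(0.96, 0, 0),
#'                                  c(-0.24, 0.93, 0)), name = "water")
#' water
molecule <- function(elements, bonds, coords = NULL, name = "") {
  elements <- as.character(elements)
  n <- length(elements)
  known <- atomic_properties()$element
  bad <- setdiff(unique(elements), known)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  has_3d <- !is.null(coords)
  if (has_3d) {
    coords <- as.matrix(coords)
    if (!is.numeric(coords) || nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an n x 3 numeric matrix")
    if (!all(is.finite(coords)))
      stop("coordinates must be finite")
  } else {
    coords <- matrix(NA_real_, n, 3)
  }
  if (is.null(bonds)) bonds <- matrix(numeric(0), 0, 3)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0 && ncol(bonds) == 2) bonds <- cbind(bonds, 1)
  if (nrow(bonds) > 0) {
    idx <- bonds[, 1:2]
    if (any(idx < 1 | idx > n | idx != round(idx)))
      stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  }
  is_h <- elements == "H"
  if (sum(!is_h) < 1) stop("molecule must contain at least one heavy atom")
  structure(list(
    atoms = data.frame(element = elements, x = coords[, 1], y = coords[, 2],
                       z = coords[, 3], is_hydrogen = is_h,
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = as.integer(bonds[, 1]),
                       to = as.integer(bonds[, 2]),
                       order = as.numeric(if (nrow(bonds)) bonds[, 3] else numeric(0))),
    name = name, has_3d = has_3d
  ), class = "qsrr_molecule")
}

#' @export
print.qsrr_molecule <- function(x, ...) {
  nh <- sum(!x$atoms$is_hydrogen)
  cat("<molecule", if (nzchar(x$name)) paste0(" '", x$name, "'"), "> ",
      nrow(x$atoms), " atoms (", nh, " heavy), ", nrow(x$bonds), " bonds, ",
      if (x$has_3d) "3D coordinates" else "no 3D coordinates (embed first)",
      "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)
n_heavy <- function(mol) sum(!mol$atoms$is_hydrogen)

# Guard used by 3D descriptors.
require_3d <- function(mol) {
  if (!mol$has_3d)
    stop("molecule '", mol$name, "' has no 3D coordinates; ",
         "run embed_structures() (or supply an SDF with coordinates) ",
         "before computing 3D descriptors")
  invisible(mol)
}

#' Molecular formula of a molecule
#'
#' Hill-order formula (C, H, then alphabetical) counting all atoms.
#'
#' @param mol A [molecule()].
#' @return A character scalar such as `"C7H6O5"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}
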