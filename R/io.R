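# Structure file I/O: MDL MOL/SDF V2000 and SMILES, plus 3D embedding.

# Standard valences used to add implicit hydrogens to SMILES-parsed
# molecules (neutral organics; S and P get the smallest common valence
# that accommodates the existing bond-order sum).
.default_valences <- list(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                          P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

.implicit_h <- function(element, bond_order_sum) {
  v <- .default_valences[[element]]
  if (is.null(v)) return(0L)
  v <- v[v >= bond_order_sum]
  if (!length(v)) return(0L)
  as.integer(v[1] - bond_order_sum)
}

# Convert one ChemmineR SDF object to a qsrr_molecule.
.sdf_to_molecule <- function(sdf, name = NULL, has_3d = TRUE, add_h = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  if (add_h) {
    n0 <- length(elements)
    bos <- rep(0, n0)
    if (!is.null(bonds)) for (k in seq_len(nrow(bonds))) {
      bos[bonds[k, 1]] <- bos[bonds[k, 1]] + bonds[k, 3]
      bos[bonds[k, 2]] <- bos[bonds[k, 2]] + bonds[k, 3]
    }
    for (i in seq_len(n0)) {
      if (elements[i] == "H") next
      nh <- .implicit_h(elements[i], bos[i])
      if (nh > 0) {
        new_idx <- length(elements) + seq_len(nh)
        elements <- c(elements, rep("H", nh))
        bonds <- rbind(bonds, cbind(i, new_idx, 1))
      }
    }
    coords <- NULL  # implicit hydrogens have no placed coordinates
  }
  if (is.null(name)) name <- ChemmineR::sdfid(sdf)
  molecule(elements, bonds = bonds,
           coords = if (has_3d && !add_h) coords else NULL, name = name)
}

#' Read molecular structures
#'
#' Reads molecules from an MDL MOL/SDF V2000 file or a SMILES file (one
#' SMILES per line, optionally followed by whitespace and a name).
#' SDF/MOL input keeps the coordinates in the file; SMILES input produces
#' molecules with explicit hydrogens (standard-valence filling) but no 3D
#' coordinates, so 3D descriptors refuse them until [embed_structures()]
#' has been applied.
#'
#' @param path File path.
#' @param format `"sdf"`, `"mol"` or `"smiles"`; inferred from the file
#'   extension by default.
#' @return A list of [molecule()] objects in file order.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "mol",
                     smi = "smiles", smiles = "smiles",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format %in% c("sdf", "mol")) {
    lines <- readLines(path, warn = FALSE)
    if (any(grepl("^M  CHG", lines)))
      warning("charge (M  CHG) lines present; charges are ignored")
    sdfset <- ChemmineR::read.SDFset(path)
    ok <- ChemmineR::validSDF(sdfset)
    if (any(!ok))
      stop("malformed SDF record(s) at index: ",
           paste(which(!ok), collapse = ", "))
    lapply(seq_along(sdfset), function(i) {
      tryCatch(.sdf_to_molecule(sdfset[[i]]),
               error = function(e) stop("record ", i, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      nm <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
      tryCatch(parse_smiles(parts[1], name = nm),
               error = function(e) stop("record ", i, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
  }
}

#' Parse a single SMILES string
#'
#' Parses a SMILES into a [molecule()] with explicit hydrogens added by
#' standard valence rules. The result has no 3D coordinates and is flagged
#' so that 3D descriptors refuse it until embedded.
#'
#' @param smiles SMILES string.
#' @param name Compound label.
#' @return A [molecule()].
#' @export
#' @examples
#' \dontrun{
#' phenol <- parse_smiles("c1ccccc1O", "phenol")
#' }
parse_smiles <- function(smiles, name = "") {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing requires the ChemmineOB package")
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  mol <- .sdf_to_molecule(sdf, name = name, has_3d = FALSE, add_h = TRUE)
  attr(mol, "smiles") <- smiles
  mol
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "qsrr_molecule")) mols <- list(mols)
  out <- unlist(lapply(mols, function(m) {
    a <- m$atoms; b <- m$bonds
    xyz <- as.matrix(a[, c("x", "y", "z")])
    xyz[!is.finite(xyz)] <- 0
    c(m$name, "  qsrr", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], a$element),
      if (nrow(b)) sprintf("%3d%3d%3d  0", b$from, b$to, as.integer(b$order)),
      "M  END", "$$$$")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Generate 3D coordinates for un-embedded molecules
#'
#' Shells out to Open Babel (`obabel --gen3d`) to embed molecules parsed
#' from SMILES, returning molecules with explicit hydrogens and 3D
#' coordinates. Requires the `obabel` executable on the PATH.
#'
#' @param mols A [molecule()] or list of molecules carrying a `smiles`
#'   attribute (as produced by [parse_smiles()]).
#' @return List of embedded molecules.
#' @export
embed_structures <- function(mols) {
  if (inherits(mols, "qsrr_molecule")) mols <- list(mols)
  if (Sys.which("obabel") == "")
    stop("obabel not found on PATH; cannot embed structures")
  lapply(mols, function(m) {
    if (m$has_3d) return(m)
    smi <- attr(m, "smiles")
    if (is.null(smi))
      stop("molecule '", m$name, "' has no SMILES to embed from")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    status <- system2("obabel", c(paste0("-:", shQuote(smi)), "-osdf",
                                  "--gen3d", "-h", "-O", tmp),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0 || !file.exists(tmp) || file.size(tmp) == 0)
      stop("obabel failed to embed '", m$name, "'")
    out <- read_structures(tmp, "sdf")[[1]]
    out$name <- m$name
    out
  })
}
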