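# Descriptor matrix assembly and pretreatment.

#' Descriptor set used by the retention models
#'
#' The nine descriptor codes appearing in the published phenolic retention
#' models: HNar, IDM, Mp, GATS2v, DISPe, DISPm and 3D-MoRSE signals 22
#' (volume), 28 and 32 (electronegativity).
#'
#' @return Character vector of descriptor codes.
#' @export
paper_descriptor_set <- function() {
  c("HNar", "IDM", "Mp", "GATS2v", "DISPe", "DISPm",
    "Mor22v", "Mor28e", "Mor32e")
}

# Parse a descriptor code into an evaluator function.
.descriptor_fun <- function(code) {
  if (code == "HNar") return(hnar)
  if (code == "IDM") return(idm)
  if (code == "Mp") return(mp)
  m <- regmatches(code, regexec("^GATS([0-9]+)([umvep])$", code))[[1]]
  if (length(m)) {
    lag <- as.integer(m[2]); sch <- m[3]
    return(function(mol) gats(mol, lag, sch))
  }
  m <- regmatches(code, regexec("^DISP([umvep])$", code))[[1]]
  if (length(m)) {
    sch <- m[2]
    return(function(mol) disp(mol, sch))
  }
  m <- regmatches(code, regexec("^Mor([0-9]+)([umvep])$", code))[[1]]
  if (length(m)) {
    sig <- as.integer(m[2]); sch <- m[3]
    return(function(mol) morse(mol, sig, sch))
  }
  stop("unknown descriptor code: ", code)
}

#' Compute a descriptor matrix
#'
#' Evaluates a set of descriptors for a list of molecules, producing a
#' compounds x descriptors matrix in request order. Duplicate descriptor
#' requests are collapsed to a single column with a warning; a failure on
#' any single cell aborts with the compound and descriptor named.
#'
#' @param mols List of [molecule()] objects.
#' @param descriptors Character vector of descriptor codes (default: the
#'   model set from [paper_descriptor_set()]).
#' @return An object of class `descriptor_matrix`: a numeric matrix with
#'   compound rownames and descriptor colnames, with a `pretreatment`
#'   attribute (empty until [pretreat()] is applied).
#' @export
compute_matrix <- function(mols, descriptors = paper_descriptor_set()) {
  if (inherits(mols, "qsrr_molecule")) mols <- list(mols)
  if (length(mols) == 0) stop("empty molecule list")
  if (anyDuplicated(descriptors)) {
    warning("duplicate descriptor request(s) collapsed: ",
            paste(unique(descriptors[duplicated(descriptors)]), collapse = ", "))
    descriptors <- unique(descriptors)
  }
  funs <- lapply(descriptors, .descriptor_fun)
  names <- vapply(seq_along(mols), function(i) {
    nm <- mols[[i]]$name
    if (nzchar(nm)) nm else paste0("compound_", i)
  }, character(1))
  out <- matrix(NA_real_, length(mols), length(descriptors),
                dimnames = list(names, descriptors))
  for (i in seq_along(mols)) for (j in seq_along(descriptors)) {
    out[i, j] <- tryCatch(
      withCallingHandlers(funs[[j]](mols[[i]]),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) stop("descriptor '", descriptors[j],
                               "' failed for compound '", names[i], "': ",
                               conditionMessage(e), call. = FALSE))
  }
  structure(out, pretreatment = data.frame(descriptor = character(0),
                                           reason = character(0)),
            class = c("descriptor_matrix", "matrix", "array"))
}

#' Pretreat a descriptor matrix
#'
#' Removes uninformative descriptor columns before model building:
#' all-zero columns, columns where a single value occupies at least
#' `constant_fraction` of the rows, and columns with sample variance below
#' `min_variance` (computed on raw, unstandardized values). Removal
#' reasons are recorded in the `pretreatment` attribute.
#'
#' @param x A `descriptor_matrix` or numeric matrix.
#' @param constant_fraction Fraction of rows a single value must occupy
#'   for the column to be dropped as near-constant.
#' @param min_variance Minimum sample variance to keep a column.
#' @return The filtered `descriptor_matrix`; the `pretreatment` attribute
#'   is a data frame of (descriptor, reason) for removed columns.
#' @export
pretreat <- function(x, constant_fraction = 0.5, min_variance = 5e-4) {
  if (is.null(colnames(x))) stop("descriptor matrix must have column names")
  if (ncol(x) == 0 || nrow(x) == 0) stop("empty descriptor matrix")
  reasons <- character(0); dropped <- character(0)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    reason <- NULL
    if (all(col == 0)) {
      reason <- "zero"
    } else if (max(table(col)) / length(col) >= constant_fraction) {
      reason <- "constant"
    } else if (var(col) < min_variance) {
      reason <- "low_variance"
    }
    if (!is.null(reason)) {
      dropped <- c(dropped, colnames(x)[j])
      reasons <- c(reasons, reason)
    }
  }
  keep <- setdiff(colnames(x), dropped)
  if (length(keep) == 0) stop("pretreatment removed every descriptor column")
  out <- x[, keep, drop = FALSE]
  structure(out,
            pretreatment = data.frame(descriptor = dropped, reason = reasons,
                                      stringsAsFactors = FALSE),
            class = c("descriptor_matrix", "matrix", "array"))
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor matrix> ", nrow(x), " compounds x ", ncol(x),
      " descriptors\n", sep = "")
  pt <- attr(x, "pretreatment")
  if (!is.null(pt) && nrow(pt))
    cat("pretreatment removed ", nrow(pt), " column(s): ",
        paste(pt$descriptor, collapse = ", "), "\n", sep = "")
  print(unclass(structure(x, pretreatment = NULL)))
  invisible(x)
}

#' Write a descriptor matrix (and its pretreatment report) to CSV
#'
#' @param x A `descriptor_matrix`.
#' @param path Output CSV path; a compound-name column is included.
#' @param report_path Optional path for the pretreatment report CSV.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(x, path, report_path = NULL) {
  df <- data.frame(compound = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(report_path))
    write.csv(attr(x, "pretreatment"), report_path, row.names = FALSE)
  invisible(path)
}
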