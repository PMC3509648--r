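# Embedded phenolics retention dataset and published model summaries.

.fixture_files <- c("phenolics_rt.csv", "phenolics_structures.csv",
                    "published_models.json")

#' Load the embedded phenolics retention fixture
#'
#' Returns the curated 39-compound phenolic retention dataset (experimental
#' RT in minutes, the four published models' predicted RT, and the
#' train/test/validation split) together with the published model
#' summaries (the five stepwise-regression coefficient sets, the two
#' optimal network architectures, the 22 descriptors retained by
#' unsupervised forward selection, and printed mean-polarizability
#' values). Compound structures are shipped as curated SMILES: they are
#' assembled from the compounds' standard nomenclature, not printed in
#' the original data source.
#'
#' File integrity is verified against stored MD5 checksums.
#'
#' @return An object of class `phenolics_fixture`: list with `dataset`
#'   (data frame: compound, rt_exp, rt_smlr, rt_ufs_smlr, rt_smlr_ann,
#'   rt_ufs_smlr_ann, split, formula, smiles) and `models` (list parsed
#'   from the published-model summaries).
#' @export
#' @examples
#' fx <- load_fixture()
#' nrow(fx$dataset)  # 39
load_fixture <- function() {
  dir <- system.file("extdata", package = "qsrr", mustWork = TRUE)
  paths <- file.path(dir, .fixture_files)
  sums <- tools::md5sum(paths)
  expected <- read.delim(file.path(dir, "checksums.tsv"),
                         stringsAsFactors = FALSE)
  for (f in .fixture_files) {
    want <- expected$md5[expected$file == f]
    if (!identical(unname(sums[[file.path(dir, f)]]), want))
      stop("fixture checksum mismatch for ", f)
  }
  ds <- read.csv(paths[1], stringsAsFactors = FALSE, check.names = FALSE)
  st <- read.csv(paths[2], stringsAsFactors = FALSE, check.names = FALSE)
  ds <- merge(ds, st, by = "compound", sort = FALSE)
  models <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  stopifnot(nrow(ds) == 39,
            sum(ds$split == "train") == 25,
            sum(ds$split == "test") == 5,
            sum(ds$split == "validation") == 9,
            all(ds$rt_exp > 1 & ds$rt_exp < 7))
  structure(list(dataset = ds, models = models),
            class = "phenolics_fixture")
}

#' @export
print.phenolics_fixture <- function(x, ...) {
  cat("Phenolics retention fixture: 39 compounds ",
      "(25 train / 5 test / 9 validation)\n",
      "experimental RT range: ",
      paste(range(x$dataset$rt_exp), collapse = " - "), " min\n", sep = "")
  invisible(x)
}

#' Molecules for the fixture compounds
#'
#' Parses the curated SMILES of the fixture compounds into [molecule()]
#' objects (explicit hydrogens, no 3D coordinates until
#' [embed_structures()]).
#'
#' @param compounds Optional character vector of compound names
#'   (default: all 39).
#' @return Named list of molecules.
#' @export
fixture_molecules <- function(compounds = NULL) {
  fx <- load_fixture()
  ds <- fx$dataset
  if (!is.null(compounds)) {
    missing <- setdiff(compounds, ds$compound)
    if (length(missing))
      stop("unknown compound(s): ", paste(missing, collapse = ", "))
    ds <- ds[match(compounds, ds$compound), , drop = FALSE]
  }
  mols <- Map(parse_smiles, ds$smiles, ds$compound)
  names(mols) <- ds$compound
  mols
}

#' Export the fixture dataset
#'
#' Writes the retention table as CSV and, optionally, the curated
#' structures as an SDF (2D connectivity with explicit hydrogens; embed
#' for 3D work).
#'
#' @param out CSV output path.
#' @param sdf_out Optional SDF output path.
#' @return `out`, invisibly.
#' @export
export_fixture <- function(out, sdf_out = NULL) {
  fx <- load_fixture()
  write.csv(fx$dataset, out, row.names = FALSE)
  if (!is.null(sdf_out)) write_sdf(fixture_molecules(), sdf_out)
  invisible(out)
}

#' Recompute the published model statistics from the fixture
#'
#' From the printed per-compound predictions alone, recomputes the
#' training-set R-squared (30 training compounds; the early-stopping
#' test subset is part of the training set) and the external PRESS and
#' Q-squared (9 validation compounds, training-mean reference) for all
#' four models, and compares them with the printed values at the
#' rounding-driven tolerances (+-0.01 on PRESS, +-0.005 on R2/Q2; the
#' printed predictions carry two decimals).
#'
#' @return Data frame with columns model, statistic, recomputed, printed,
#'   tolerance, within_tolerance.
#' @export
reproduce_paper_statistics <- function() {
  fx <- load_fixture()
  ds <- fx$dataset
  tr <- ds$split != "validation"
  printed <- list(
    smlr = fx$models$equations$smlr$stats,
    ufs_smlr = fx$models$equations$ufs_smlr$stats,
    smlr_ann = fx$models$ann$smlr_ann$stats,
    ufs_smlr_ann = fx$models$ann$ufs_smlr_ann$stats)
  cols <- c(smlr = "rt_smlr", ufs_smlr = "rt_ufs_smlr",
            smlr_ann = "rt_smlr_ann", ufs_smlr_ann = "rt_ufs_smlr_ann")
  out <- NULL
  for (m in names(cols)) {
    pred <- ds[[cols[m]]]
    ev <- external_validate(pred, ds$split, ds$rt_exp)
    rec <- c(R2 = 1 - sum((ds$rt_exp[tr] - pred[tr])^2) /
               sum((ds$rt_exp[tr] - mean(ds$rt_exp[tr]))^2),
             PRESS_ext = ev$press_ext, Q2_ext = ev$q2_ext)
    for (s in names(rec)) {
      prt <- printed[[m]][[s]]
      if (is.null(prt)) next
      tol <- if (s == "PRESS_ext") 0.01 else 0.005
      out <- rbind(out, data.frame(
        model = m, statistic = s, recomputed = unname(rec[s]),
        printed = prt, tolerance = tol,
        within_tolerance = abs(rec[[s]] - prt) <= tol,
        stringsAsFactors = FALSE))
    }
  }
  out
}
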