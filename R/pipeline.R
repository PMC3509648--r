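# End-to-end pipeline: pretreatment -> (UFS) -> SMLR -> OLS/ANN ->
# validation and reporting.

#' Pipeline configuration
#'
#' Collects every tunable of the modelling pipeline. The defaults are the
#' study settings: variance filter 0.0005, constant-value fraction 0.5,
#' UFS R2max 0.90, F-to-enter 6, F-to-remove 3, 500 networks, 500
#' scrambling permutations.
#'
#' @param min_variance,constant_fraction Pretreatment thresholds, see
#'   [pretreat()].
#' @param use_ufs Run unsupervised forward selection before SMLR?
#' @param r2max UFS threshold, see [ufs()].
#' @param f_enter,f_remove SMLR partial-F thresholds, see [smlr()].
#' @param fit_ann Train a neural-network ensemble on the SMLR-selected
#'   descriptors?
#' @param n_networks Ensemble size, see [train_ann_ensemble()].
#' @param ann_select_on `"test"` or `"validation"`.
#' @param n_scrambles y-scrambling permutations, see [y_scramble()].
#' @param reference Q2 reference-mean convention (both are always
#'   reported; this picks the headline one).
#' @param seed Master seed for ANN training and scrambling.
#' @return A list of class `qsrr_config`.
#' @export
qsrr_config <- function(min_variance = 5e-4, constant_fraction = 0.5,
                        use_ufs = TRUE, r2max = 0.90,
                        f_enter = 6, f_remove = 3,
                        fit_ann = FALSE, n_networks = 500,
                        ann_select_on = "test",
                        n_scrambles = 500,
                        reference = c("train", "validation"), seed = 1) {
  structure(list(min_variance = min_variance,
                 constant_fraction = constant_fraction,
                 use_ufs = use_ufs, r2max = r2max,
                 f_enter = f_enter, f_remove = f_remove,
                 fit_ann = fit_ann, n_networks = n_networks,
                 ann_select_on = ann_select_on,
                 n_scrambles = n_scrambles,
                 reference = match.arg(reference), seed = seed),
            class = "qsrr_config")
}

#' Run the full QSRR pipeline
#'
#' Executes pretreatment, optional unsupervised forward selection,
#' stepwise regression, optional neural-network ensemble training,
#' leave-one-out and external validation, and y-scrambling, then writes
#' CSV/JSON reports and a run manifest. Models are fit on the training
#' rows (train + early-stopping test subset); the validation rows are
#' used only for external statistics (and, if `ann_select_on =
#' "validation"`, for network selection).
#'
#' @param x Descriptor matrix with column names (or path to a CSV whose
#'   first column is the compound name).
#' @param y Response vector (or path to a one-column CSV).
#' @param split Character labels per row (`"train"`, `"test"`,
#'   `"validation"`); if `NULL`, all rows are training rows and external
#'   validation is skipped.
#' @param config A [qsrr_config()].
#' @param out_dir Output directory for reports; `NULL` writes nothing.
#' @return A list (invisibly) with elements `pretreated`, `ufs`, `smlr`,
#'   `model`, `ann`, `loo`, `external`, `external_valref`, `scrambling`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(x, y, split = NULL, config = qsrr_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "qsrr_config"))
  if (is.character(x)) {
    df <- read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- df[[1]]
  }
  if (is.character(y)) y <- read.csv(y)[[1]]
  if (is.null(split)) split <- rep("train", nrow(x))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- character(0)
  note <- function(s) manifest <<- c(manifest, s)

  xp <- stage("pretreat", pretreat(x, config$constant_fraction,
                                   config$min_variance))
  p_pretreat <- ncol(xp)
  note("pretreat")
  ufs_res <- NULL
  if (config$use_ufs) {
    ufs_res <- stage("ufs", ufs(xp, config$r2max))
    xp <- xp[, ufs_res$selected, drop = FALSE]
    note("ufs")
  }
  fitrows <- split != "validation"
  sm <- stage("smlr", smlr(xp[fitrows, , drop = FALSE], y[fitrows],
                           config$f_enter, config$f_remove))
  note("smlr")
  if (!length(sm$selected))
    stop("pipeline stage 'smlr' failed: no descriptor entered the model")
  model <- sm$model
  xsel_all <- xp[, sm$selected, drop = FALSE]

  ann_res <- NULL
  if (config$fit_ann) {
    ann_res <- stage("ann", train_ann_ensemble(
      xsel_all, y, split, n_networks = config$n_networks,
      select_on = config$ann_select_on, seed = config$seed))
    note("ann")
  }
  loo <- stage("loo_cv", loo_cv(xsel_all[fitrows, , drop = FALSE],
                                y[fitrows]))
  note("loo_cv")
  ext <- ext_valref <- NULL
  if (any(split == "validation")) {
    pred_all <- if (is.null(ann_res)) predict(model, xsel_all) else
      predict(ann_res$best, xsel_all)
    ext <- stage("external", external_validate(pred_all, split, y, "train"))
    ext_valref <- external_validate(pred_all, split, y, "validation")
    note("external")
  }
  scr <- stage("scramble", y_scramble(xsel_all[fitrows, , drop = FALSE],
                                      y[fitrows],
                                      n_permutations = config$n_scrambles,
                                      seed = config$seed))
  note("scramble")

  summary <- list(
    n = nrow(x), p_input = ncol(x), p_after_pretreat = p_pretreat,
    ufs_selected = if (is.null(ufs_res)) NULL else ufs_res$selected,
    smlr_selected = sm$selected,
    r_squared = model$r_squared,
    press_int = loo$press_int, q2_int = loo$q2_int,
    press_ext = if (is.null(ext)) NULL else ext$press_ext,
    q2_ext_train_ref = if (is.null(ext)) NULL else ext$q2_ext,
    q2_ext_validation_ref = if (is.null(ext_valref)) NULL else
      ext_valref$q2_ext,
    scrambling_mean_r2 = scr$mean_r2,
    scrambling_intercept = scr$intercept,
    ann_selected = if (is.null(ann_res)) NULL else
      ann_res$leaderboard[which.min(ann_res$leaderboard$test_error), ],
    seed = config$seed)
  result <- list(pretreated = xp, ufs = ufs_res, smlr = sm, model = model,
                 ann = ann_res, loo = loo, external = ext,
                 external_valref = ext_valref, scrambling = scr,
                 summary = summary, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(stages = manifest, seed = config$seed,
                              package_version =
                                as.character(utils::packageVersion("qsrr"))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write.csv(data.frame(observed = y, split = split,
                         predicted_lm = predict(model, xp)),
              file.path(out_dir, "predictions.csv"), row.names = FALSE)
    write.csv(scr$table, file.path(out_dir, "scrambling.csv"),
              row.names = FALSE)
  }
  invisible(result)
}
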