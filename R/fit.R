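#' Fit a polystyrene-binding peptide classifier
#'
#' Runs the full identification pipeline on a labeled two-class peptide
#' dataset: curation ([curate_peptides()]), 420-dimensional weighted
#' AAC+DPC encoding ([encode_dataset()]), ANOVA F-score ranking
#' ([rank_features()]), incremental feature selection with
#' cross-validated accuracy ([ifs_select()]), grid-search tuning of the
#' final RBF-SVM ([grid_search()]), training on the full dataset
#' ([svm_train()]), and cross-validated evaluation ([cross_validate()]).
#'
#' @param pos,neg positive / negative peptides (data frames from
#'   [read_fasta()]/[peptides()], or character vectors of sequences).
#' @param curation a [curation_config()].
#' @param k_max largest ranked-feature prefix evaluated during
#'   incremental selection (default: all 420).
#' @param inner_grid hyperparameter grid searched at every prefix size
#'   inside incremental selection (default [grid_coarse()]).
#' @param final_grid grid searched once, on the selected feature set, for
#'   the final model (default [grid_default()]; pass [grid_published()] for
#'   the published search range).
#' @param folds cross-validation fold count (default 5).
#' @param seed integer seed controlling every fold assignment.
#' @param cv_mode `"published"` (selection fixed on the full dataset before
#'   cross-validation, reproducing the published protocol) or `"nested"`
#'   (selection redone inside each training fold; honest but slower). See
#'   [cross_validate()].
#' @return An object of class `psbind` with components `curation`
#'   (report), `ranking`, `ifs`, `tuning` (final grid-search result),
#'   `classifier` (a `psbind_svm`), `cv` (a `psbind_cv`), `config`, and
#'   `call`. Methods: `print`, `summary`, `coef` (selected features with
#'   their F-scores), `predict`, `plot` (selection accuracy curve).
#' @examples
#' \donttest{
#' bench <- synth_peptides(seed = 7)
#' fit <- psbind_fit(bench$pos, bench$neg, k_max = 20, seed = 7)
#' fit
#' predict(fit, c("WWFYWAGH", "GAVLSTNQ"))
#' }
#' @export
psbind_fit <- function(pos, neg, curation = curation_config(),
                       k_max = 420L, inner_grid = grid_coarse(),
                       final_grid = grid_default(), folds = 5L, seed = 1L,
                       cv_mode = c("published", "nested")) {
  cv_mode <- match.arg(cv_mode)
  cur <- curate_peptides(pos, neg, curation)
  ds <- encode_dataset(cur)
  ranking <- rank_features(ds$x, ds$y)
  ifs <- ifs_select(ds$x, ds$y, ranking = ranking,
                    k_max = min(k_max, ncol(ds$x)), grid = inner_grid,
                    folds = folds, seed = seed)
  sel <- ifs$optimal_indices
  tuning <- grid_search(ds$x[, sel, drop = FALSE], ds$y, grid = final_grid,
                        folds = folds, seed = seed)
  classifier <- svm_train(ds$x[, sel, drop = FALSE], ds$y,
                          cost = tuning$params$cost,
                          gamma = tuning$params$gamma,
                          feature_indices = sel, seed = seed)
  cv <- cross_validate(ds$x, ds$y, mode = cv_mode,
                       selected_indices = sel, params = tuning$params,
                       k_max = min(k_max, ncol(ds$x)),
                       inner_grid = inner_grid, folds = folds, seed = seed)
  structure(list(
    curation = cur$report,
    dataset = ds,
    ranking = ranking,
    ifs = ifs,
    tuning = tuning,
    classifier = classifier,
    cv = cv,
    config = list(k_max = k_max, folds = folds, seed = seed,
                  cv_mode = cv_mode, curation = curation,
                  inner_grid = inner_grid, final_grid = final_grid),
    call = match.call()
  ), class = "psbind")
}

#' @export
print.psbind <- function(x, ...) {
  cat("Polystyrene-binding peptide classifier (RBF-SVM)\n")
  cat(sprintf("  training data: %d positives, %d negatives (after curation)\n",
              x$curation$n_output_pos, x$curation$n_output_neg))
  cat(sprintf("  selected features: %d of 420 (chosen by IFS)\n",
              x$ifs$chosen_k))
  cat(sprintf("  hyperparameters: C = 2^%g, gamma = 2^%g\n",
              x$tuning$params$log2c, x$tuning$params$log2gamma))
  cat(sprintf("  %d-fold CV (%s mode): SN %.4f  SP %.4f  ACC %.4f  AUC %.4f\n",
              x$config$folds, x$cv$mode, x$cv$mean["sn"], x$cv$mean["sp"],
              x$cv$mean["acc"], x$cv$mean["auc"]))
  invisible(x)
}

#' @export
summary.psbind <- function(object, ...) {
  structure(list(
    fit = object,
    breakdown = composition_breakdown(object$ifs$optimal_indices),
    top_features = utils::head(object$ranking, 10)
  ), class = "summary.psbind")
}

#' @export
print.summary.psbind <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$breakdown)
  cat("\nTop-ranked features (ANOVA F):\n")
  print(data.frame(x$top_features[, c("rank", "name", "f_value")]),
        row.names = FALSE)
  cat("\nPer-fold cross-validation metrics:\n")
  print(round(x$fit$cv$per_fold, 4), row.names = FALSE)
  invisible(x)
}

#' Selected features and their ANOVA F-scores
#'
#' @param object a `psbind` fit.
#' @param ... unused.
#' @return Named numeric vector of F-scores for the selected features, in
#'   rank order.
#' @export
coef.psbind <- function(object, ...) {
  sel <- object$ranking[object$ranking$feature_index %in%
                          object$ifs$optimal_indices, ]
  stats::setNames(sel$f_value, sel$name)
}

#' Predict new peptides with a fitted classifier
#'
#' @param object a `psbind` fit.
#' @param newdata peptides: data frame, character vector of sequences, or
#'   a path to a FASTA file.
#' @param ... unused.
#' @return See [predict.psbind_svm()].
#' @export
predict.psbind <- function(object, newdata, ...) {
  if (is.character(newdata) && length(newdata) == 1 &&
      file.exists(newdata)) {
    newdata <- read_fasta(newdata)
  }
  predict(object$classifier, newdata)
}

#' @export
plot.psbind <- function(x, ...) {
  plot(x$ifs, ...)
  invisible(x)
}
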