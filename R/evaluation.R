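#' Stratified cross-validation folds
#'
#' Partitions samples into `k` folds, stratified by class: within each
#' class, shuffled members are spread as evenly as possible, and each
#' class's remainder goes to the folds with the smallest running totals,
#' so per-fold class counts differ from perfect proportion by at most 1
#' and overall fold sizes are as balanced as the two classes allow (e.g.
#' 104 + 104 samples in 5 folds give sizes 42, 42, 42, 41, 41).
#' Reproducible from `seed`.
#'
#' @param y class labels (any two-level coding; used only for
#'   stratification).
#' @param k number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed integer seed.
#' @param stratified set `FALSE` for a plain random partition.
#' @return Integer vector of fold indices in `1..k`, with attribute
#'   `seed`.
#' @export
make_folds <- function(y, k = 5L, seed = 1L, stratified = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  n <- length(y)
  fold_id <- integer(n)
  .with_seed(seed, {
    if (!stratified) {
      fold_id <- sample(rep_len(seq_len(k), n))
    } else {
      totals <- integer(k)
      for (cl in unique(y)) {
        idx <- which(y == cl)
        if (length(idx) < k) {
          stop("class '", cl, "' has fewer members (", length(idx),
               ") than folds (", k, ")")
        }
        base <- length(idx) %/% k
        extra <- length(idx) %% k
        sizes <- rep(base, k)
        if (extra > 0) {
          recipients <- order(totals, seq_len(k))[seq_len(extra)]
          sizes[recipients] <- sizes[recipients] + 1L
        }
        fold_id[sample(idx)] <- rep(seq_len(k), times = sizes)
        totals <- totals + sizes
      }
    }
  })
  attr(fold_id, "seed") <- seed
  fold_id
}

# evaluate `expr` (lazily, in the caller's frame) under a temporary RNG
# state seeded with `seed`, restoring the global RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred binary vectors (1 = positive / PSBP, 0 = negative)
#'   of equal length.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sn = tp/(tp+fn)`, `sp = tn/(tn+fp)`, `acc = (tp+tn)/total`. Both
#' classes must be represented among the true labels; an empty class makes
#' sensitivity or specificity undefined and is an error rather than a
#' silent zero.
#'
#' @param counts a [confusion_counts()] result (or a list with the same
#'   fields).
#' @return Named numeric vector `c(sn, sp, acc)`, all in \[0, 1\].
#' @export
sn_sp_acc <- function(counts) {
  with(counts, {
    if (tp + fn == 0) stop("no positive samples: sensitivity undefined")
    if (tn + fp == 0) stop("no negative samples: specificity undefined")
    c(sn = tp / (tp + fn), sp = tn / (tn + fp),
      acc = (tp + tn) / (tp + tn + fp + fn))
  })
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs where the positive scores higher, with ties
#' counted 1/2 -- identical to the trapezoidal area under the ROC curve.
#'
#' @param y_true binary labels (1 = positive).
#' @param scores finite numeric decision scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1))  # 0.875
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(is.finite(scores)))
  np <- sum(y_true == 1L)
  nn <- sum(y_true == 0L)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y_true == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Five-fold (by default) stratified cross-validation reporting per-fold
#' and mean sensitivity, specificity, accuracy and AUC.
#'
#' Two protocols are available. In `"published"` mode, feature selection and
#' hyperparameters are fixed in advance (selected on the full dataset, as
#' the original protocol does) and each fold only refits the SVM on its
#' training 4/5 -- this reproduces the published protocol but lets
#' selection see the test folds, so its estimates are optimistic. In
#' `"nested"` mode, ANOVA ranking, incremental feature selection (with
#' `inner_folds`-fold inner CV) and the hyperparameter choice are redone
#' inside each training fold, giving an honest generalization estimate.
#'
#' @param x,y feature matrix (420 columns for nested mode) and binary
#'   labels.
#' @param mode `"published"` or `"nested"`.
#' @param selected_indices,params fixed feature indices and list with
#'   `cost`/`gamma` (published-protocol mode; required there).
#' @param k_max,inner_grid,inner_folds incremental-selection settings for
#'   nested mode.
#' @param folds,seed outer fold count and seed.
#' @return A list of class `psbind_cv`: `per_fold` (data frame of fold,
#'   sn, sp, acc, auc), `mean` (named vector averaging the folds), `mode`,
#'   `seed`.
#' @export
cross_validate <- function(x, y, mode = c("published", "nested"),
                           selected_indices = NULL, params = NULL,
                           k_max = 30L, inner_grid = grid_coarse(),
                           inner_folds = 3L, folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  fold_id <- make_folds(y, k = folds, seed = seed)
  per <- data.frame(fold = seq_len(folds), sn = NA_real_, sp = NA_real_,
                    acc = NA_real_, auc = NA_real_)
  if (mode == "published" && (is.null(selected_indices) || is.null(params))) {
    stop("published-protocol mode needs 'selected_indices' and 'params'")
  }
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
      stop("fold ", f, " is missing a class")
    }
    if (mode == "published") {
      idx <- selected_indices
      pp <- params
    } else {
      rk <- rank_features(x[tr, , drop = FALSE], y[tr])
      sel <- ifs_select(x[tr, , drop = FALSE], y[tr], ranking = rk,
                        k_max = min(k_max, ncol(x)), grid = inner_grid,
                        folds = inner_folds, seed = seed + f)
      idx <- sel$optimal_indices
      pp <- sel$best_params
    }
    pl <- .svm_fit(x[tr, idx, drop = FALSE], y[tr], pp$cost, pp$gamma)
    sc <- .svm_decision(pl, x[!tr, idx, drop = FALSE])
    pred <- as.integer(sc > 0)
    m <- sn_sp_acc(confusion_counts(y[!tr], pred))
    per$sn[f] <- m["sn"]
    per$sp[f] <- m["sp"]
    per$acc[f] <- m["acc"]
    per$auc[f] <- roc_auc(y[!tr], sc)
  }
  structure(list(per_fold = per,
                 mean = c(sn = mean(per$sn), sp = mean(per$sp),
                          acc = mean(per$acc), auc = mean(per$auc)),
                 mode = mode, seed = seed),
            class = "psbind_cv")
}

#' @export
print.psbind_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s mode, seed %d)\n",
              nrow(x$per_fold), x$mode, x$seed))
  print(cbind(round(x$per_fold, 4)), row.names = FALSE)
  cat(sprintf("mean: SN %.4f  SP %.4f  ACC %.4f  AUC %.4f\n",
              x$mean["sn"], x$mean["sp"], x$mean["acc"], x$mean["auc"]))
  invisible(x)
}
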