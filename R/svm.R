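#' Hyperparameter grids for the RBF-SVM
#'
#' A grid is the Cartesian product of log2(C) and log2(gamma) values,
#' enumerated inclusively from `min` to `max` in steps of `step`.
#' [grid_search()] scans it exhaustively.
#'
#' Three presets are provided. `grid_published()` is the published search
#' range for this identifier family: log2(C) in \[-10, 20\] and
#' log2(gamma) in \[6, 20\], both in steps of 0.5 (1769 points) -- gamma
#' is large because the 20/420- and 400/420-weighted composition features
#' make squared distances between peptides very small. `grid_default()`
#' is a wide conventional grid (log2(C) in \[-5, 15\], log2(gamma) in
#' \[-3, 13\], steps of 2; 99 points) used for final-model tuning.
#' `grid_coarse()` is a 4x4 grid (log2(C) in \{-3, 1, 5, 9\},
#' log2(gamma) in \{1, 5, 9, 13\}) used inside incremental feature
#' selection where the search runs at every prefix size.
#'
#' @param log2c_min,log2c_max,log2c_step range and step of log2(C).
#' @param log2gamma_min,log2gamma_max,log2gamma_step range and step of
#'   log2(gamma).
#' @return A list of class `grid_spec` with numeric vectors `log2c` and
#'   `log2gamma`.
#' @export
grid_spec <- function(log2c_min = -5, log2c_max = 15, log2c_step = 2,
                      log2gamma_min = -3, log2gamma_max = 13,
                      log2gamma_step = 2) {
  stopifnot(log2c_min <= log2c_max, log2c_step > 0,
            log2gamma_min <= log2gamma_max, log2gamma_step > 0)
  structure(list(log2c = seq(log2c_min, log2c_max, by = log2c_step),
                 log2gamma = seq(log2gamma_min, log2gamma_max,
                                 by = log2gamma_step)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
grid_default <- function() grid_spec()

#' @rdname grid_spec
#' @export
grid_published <- function() grid_spec(-10, 20, 0.5, 6, 20, 0.5)

#' @rdname grid_spec
#' @export
grid_coarse <- function() grid_spec(-3, 9, 4, 1, 13, 4)

# internal single svm fit; y is integer 0/1. Returns the extracted kernel
# payload so prediction never needs e1071 objects or training data.
.svm_fit <- function(x, y, cost, gamma) {
  if (nrow(x) < 2 || length(unique(y)) < 2) {
    stop("training needs at least two samples and both classes")
  }
  if (all(apply(x, 2, function(v) max(v) == min(v)))) {
    stop("degenerate training input: all rows identical")
  }
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  # libsvm's decision value is positive for the class named first in the
  # "A/B" colname of the decision-value matrix; normalize so that positive
  # scores mean class 1
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  sign <- if (identical(first, "1")) 1 else -1
  list(sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
       rho = as.numeric(fit$rho), gamma = gamma, cost = cost, sign = sign)
}

# decision values of a payload on rows of x (positive score = class 1)
.svm_decision <- function(payload, x) {
  sv <- payload$sv
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
  d2[d2 < 0] <- 0
  k <- exp(-payload$gamma * d2)
  payload$sign * (drop(k %*% payload$coefs) - payload$rho)
}

# grid search with a fixed fold assignment (shared across grid points)
.grid_search_folds <- function(x, y, grid, fold_id) {
  pts <- expand.grid(log2gamma = grid$log2gamma, log2c = grid$log2c)
  # row order gives the tie-break: ascending log2c, then ascending log2gamma
  pts <- pts[order(pts$log2c, pts$log2gamma), , drop = FALSE]
  accs <- numeric(nrow(pts))
  folds <- sort(unique(fold_id))
  for (i in seq_len(nrow(pts))) {
    cost <- 2^pts$log2c[i]
    gamma <- 2^pts$log2gamma[i]
    correct <- 0L
    for (f in folds) {
      tr <- fold_id != f
      pl <- .svm_fit(x[tr, , drop = FALSE], y[tr], cost, gamma)
      sc <- .svm_decision(pl, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.integer(sc > 0) == y[!tr])
    }
    accs[i] <- correct / length(y)
  }
  best <- which.max(accs)  # first maximum = smallest log2c, then log2gamma
  list(params = list(cost = 2^pts$log2c[best], gamma = 2^pts$log2gamma[best],
                     log2c = pts$log2c[best], log2gamma = pts$log2gamma[best]),
       cv_accuracy = accs[best],
       table = data.frame(log2c = pts$log2c, log2gamma = pts$log2gamma,
                          cv_accuracy = accs))
}

#' Exhaustive grid search for RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair of `grid` by mean cross-validated
#' accuracy with a single stratified fold assignment shared across all
#' grid points (a paired comparison, drawn once from `seed`). Ties are
#' broken toward the smaller log2(C), then the smaller log2(gamma), so the
#' result is independent of grid enumeration order.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (1 = positive, 0 = negative).
#' @param grid a [grid_spec()].
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return A list with `params` (`cost`, `gamma`, `log2c`, `log2gamma`),
#'   `cv_accuracy` (the winner's mean CV accuracy), and `table` (accuracy
#'   at every grid point).
#' @export
grid_search <- function(x, y, grid = grid_default(), folds = 5L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  fold_id <- make_folds(y, k = folds, seed = seed)
  .grid_search_folds(x, y, grid, fold_id)
}

#' Train an RBF-SVM peptide classifier
#'
#' Fits a soft-margin support vector machine with kernel
#' `k(u, v) = exp(-gamma * ||u - v||^2)` and penalty `cost` (via libsvm,
#' through e1071) on already-encoded features, and extracts a
#' self-contained kernel payload (support vectors, coefficients, bias) so
#' that prediction and persistence need neither the training data nor the
#' fitting library's objects. Deterministic for fixed input.
#'
#' @param x numeric feature matrix whose columns are the *selected*
#'   features, in [feature_names()] units.
#' @param y binary labels (1 = positive, 0 = negative).
#' @param cost,gamma hyperparameters (both > 0).
#' @param feature_indices 1-based indices of the columns of `x` within the
#'   full 420-feature vector; defaults to matching `colnames(x)` against
#'   [feature_names()], or `1:ncol(x)`.
#' @param seed integer recorded as training metadata.
#' @return An object of class `psbind_svm` bundling hyperparameters,
#'   selected feature indices, the kernel payload and training metadata.
#' @export
svm_train <- function(x, y, cost, gamma, feature_indices = NULL, seed = NA) {
  stopifnot(is.matrix(x), nrow(x) == length(y), cost > 0, gamma > 0,
            is.finite(cost), is.finite(gamma))
  y <- as.integer(y)
  if (is.null(feature_indices)) {
    feature_indices <- if (!is.null(colnames(x)) &&
                           all(colnames(x) %in% feature_names())) {
      match(colnames(x), feature_names())
    } else {
      seq_len(ncol(x))
    }
  }
  stopifnot(length(feature_indices) == ncol(x),
            !anyDuplicated(feature_indices),
            all(feature_indices >= 1), all(feature_indices <= 420))
  payload <- .svm_fit(x, y, cost, gamma)
  structure(list(
    format = "psbind_svm",
    version = 1L,
    hyperparams = list(cost = as.numeric(cost), gamma = as.numeric(gamma)),
    feature_indices = as.integer(feature_indices),
    feature_names = feature_names()[feature_indices],
    payload = payload,
    metadata = list(seed = as.numeric(seed), n_train = nrow(x),
                    fingerprint = .fingerprint(x, y))
  ), class = "psbind_svm")
}

# cheap deterministic dataset fingerprint (not cryptographic)
.fingerprint <- function(x, y) {
  sprintf("%dx%d/%d/%.10e", nrow(x), ncol(x), sum(y), sum(x) + sum(x^2))
}

#' @export
print.psbind_svm <- function(x, ...) {
  cat(sprintf(paste0("RBF-SVM peptide classifier: %d features, ",
                     "C = 2^%g, gamma = 2^%g, %d support vectors\n"),
              length(x$feature_indices), log2(x$hyperparams$cost),
              log2(x$hyperparams$gamma), nrow(x$payload$sv)))
  invisible(x)
}

#' Predict with a trained classifier
#'
#' Encodes each peptide ([encode_peptide()]), restricts the vector to the
#' model's selected features, and computes the RBF decision value from the
#' stored kernel payload. Positive decision values map to the positive
#' (polystyrene-binding) class; the continuous score is suitable for ROC
#' analysis. Invalid peptides (non-canonical residues, too short) are
#' reported per record and do not abort the batch.
#'
#' @param object a `psbind_svm`.
#' @param peptides peptide data frame, character vector of sequences, or
#'   path handled by the caller; an already-encoded numeric matrix with
#'   420 columns (or exactly the selected columns) is also accepted.
#' @param ... unused.
#' @return A data frame with one row per input: `id`, `label`
#'   (`"positive"`/`"negative"`, `NA` on failure), `score` (decision
#'   value), `ok`, `reason`.
#' @export
predict.psbind_svm <- function(object, peptides, ...) {
  if (is.matrix(peptides)) {
    m <- peptides
    if (ncol(m) == 420L) m <- m[, object$feature_indices, drop = FALSE]
    stopifnot(ncol(m) == length(object$feature_indices))
    sc <- .svm_decision(object$payload, m)
    ids <- rownames(m)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(m)))
    return(data.frame(id = ids,
                      label = ifelse(sc > 0, "positive", "negative"),
                      score = sc, ok = TRUE, reason = NA_character_,
                      stringsAsFactors = FALSE))
  }
  pep <- .as_peptides(peptides)
  n <- nrow(pep)
  out <- data.frame(id = pep$id, label = rep_len(NA_character_, n),
                    score = rep_len(NA_real_, n), ok = rep_len(FALSE, n),
                    reason = rep_len(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pep))) {
    v <- tryCatch(encode_peptide(pep$sequence[[i]]), error = function(e) e)
    if (inherits(v, "error")) {
      out$reason[i] <- conditionMessage(v)
      next
    }
    sc <- .svm_decision(object$payload,
                        matrix(v[object$feature_indices], nrow = 1))
    out$score[i] <- sc
    out$label[i] <- if (sc > 0) "positive" else "negative"
    out$ok[i] <- TRUE
  }
  out
}

#' Save / load a trained classifier
#'
#' The model is persisted as a single plain-text JSON archive: a header
#' (format tag, version, hyperparameters, selected feature indices,
#' training metadata) plus the kernel payload (support vectors,
#' coefficients, bias) at full numeric precision. The round trip is
#' lossless: the reloaded model produces identical predictions.
#'
#' @param object a `psbind_svm`.
#' @param path file path.
#' @return `save_classifier`: `path`, invisibly. `load_classifier`: the
#'   restored `psbind_svm`.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "psbind_svm"))
  obj <- unclass(object)
  obj$payload$sv <- as.data.frame(obj$payload$sv)  # rectangular in JSON
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = FALSE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("not a readable classifier archive: ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(obj$format, "psbind_svm")) {
    stop("format error: file is not a psbind_svm archive")
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop("format error: unsupported psbind_svm archive version ", obj$version)
  }
  need <- c("hyperparams", "feature_indices", "payload")
  if (!all(need %in% names(obj)) ||
      !all(c("sv", "coefs", "rho", "gamma", "sign") %in% names(obj$payload))) {
    stop("format error: truncated or corrupt classifier archive")
  }
  obj$payload$sv <- as.matrix(obj$payload$sv)
  dimnames(obj$payload$sv) <- NULL
  # JSON renders whole doubles without a decimal point; restore the types
  # the trainer produced so the round trip is identical, not just equal
  obj$payload[c("coefs", "rho", "gamma", "cost", "sign")] <-
    lapply(obj$payload[c("coefs", "rho", "gamma", "cost", "sign")],
           as.numeric)
  storage.mode(obj$payload$sv) <- "double"
  obj$hyperparams <- lapply(obj$hyperparams, as.numeric)
  obj$feature_indices <- as.integer(obj$feature_indices)
  obj$version <- as.integer(obj$version)
  if (!is.null(obj$metadata$seed)) {
    obj$metadata$seed <- as.numeric(obj$metadata$seed)
  }
  if (!is.null(obj$metadata$n_train)) {
    obj$metadata$n_train <- as.integer(obj$metadata$n_train)
  }
  structure(obj, class = "psbind_svm")
}
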