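#' One-way two-group ANOVA F-score of a single feature
#'
#' Measures how well one feature separates the positive from the negative
#' group: the between-group sum of squares (`ssb`, 1 degree of freedom)
#' over the within-group sum of squares (`ssw`, `m1 + m2 - 2` degrees of
#' freedom), `F = (ssb/1) / (ssw/(m1+m2-2))`. Identical to the classical
#' one-way ANOVA F statistic for two groups. Degenerate cases follow a
#' fixed convention: `F = 0` when `ssb = 0` (equal group means, including
#' features constant everywhere) and `F = Inf` when `ssb > 0` with
#' `ssw = 0` (perfect separation by a within-group-constant feature).
#'
#' @param values_pos,values_neg numeric observations of the feature in each
#'   group; each group needs at least 2 observations.
#' @return A list with `ssb`, `ssw` and `f_value`.
#' @examples
#' anova_f(c(3, 1), c(0, 2))  # f_value 0.5
#' @export
anova_f <- function(values_pos, values_neg) {
  m1 <- length(values_pos)
  m2 <- length(values_neg)
  if (m1 < 2 || m2 < 2) stop("each group needs at least 2 observations")
  g <- (sum(values_pos) + sum(values_neg)) / (m1 + m2)
  c1 <- mean(values_pos)
  c2 <- mean(values_neg)
  ssb <- m1 * (c1 - g)^2 + m2 * (c2 - g)^2
  ssw <- sum((values_pos - c1)^2) + sum((values_neg - c2)^2)
  f <- if (ssw > 0) (ssb / 1) / (ssw / (m1 + m2 - 2)) else
    if (ssb > 0) Inf else 0
  list(ssb = ssb, ssw = ssw, f_value = f)
}

# vectorized column-wise version over a matrix; same conventions as anova_f
.column_anova <- function(x, y) {
  pos <- y == 1L
  m1 <- sum(pos)
  m2 <- sum(!pos)
  if (m1 < 2 || m2 < 2) stop("each class needs at least 2 members")
  c1 <- colMeans(x[pos, , drop = FALSE])
  c2 <- colMeans(x[!pos, , drop = FALSE])
  g <- (m1 * c1 + m2 * c2) / (m1 + m2)
  ssb <- m1 * (c1 - g)^2 + m2 * (c2 - g)^2
  ssw <- colSums((x[pos, , drop = FALSE] - rep(c1, each = m1))^2) +
    colSums((x[!pos, , drop = FALSE] - rep(c2, each = m2))^2)
  # a column constant across all samples has equal means by construction;
  # guard against ssb picking up pure rounding noise when ssw is exactly 0
  const <- apply(x, 2, function(v) max(v) == min(v))
  ssb[const] <- 0
  f <- ifelse(ssw > 0, ssb / (ssw / (m1 + m2 - 2)),
              ifelse(ssb > 0, Inf, 0))
  list(ssb = ssb, ssw = ssw, f_value = f)
}

#' Rank features by ANOVA F-score
#'
#' Scores every column of the feature matrix with the two-group ANOVA F
#' statistic ([anova_f()]) and sorts in descending order; infinite scores
#' come first, and ties are broken by ascending column index, so the
#' ranking is fully deterministic.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (1 = positive, 0 = negative), both classes with
#'   at least 2 members.
#' @return A data frame of class `feature_ranking`, one row per feature in
#'   rank order, with columns `rank`, `feature_index` (1-based column
#'   index), `name` (from column names, if any), `ssb`, `ssw`, `f_value`.
#' @export
rank_features <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  sc <- .column_anova(x, as.integer(y))
  ord <- order(-sc$f_value, seq_along(sc$f_value))
  out <- data.frame(
    rank = seq_along(ord),
    feature_index = ord,
    name = if (!is.null(colnames(x))) colnames(x)[ord] else NA_character_,
    ssb = sc$ssb[ord],
    ssw = sc$ssw[ord],
    f_value = sc$f_value[ord],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Incremental feature selection along an ANOVA ranking
#'
#' For each prefix size `k = 1, ..., k_max` of the ranked feature list,
#' tunes an RBF-SVM over `grid` by stratified cross-validated accuracy
#' (one fold assignment, drawn once from `seed`, shared by every `k` and
#' every grid point) and records the best accuracy. The chosen prefix is
#' the smallest `k` attaining the maximum of the curve (preferring fewer
#' features when tied).
#'
#' @param x,y feature matrix and binary labels.
#' @param ranking a [rank_features()] result (computed from `x`/`y` if
#'   omitted).
#' @param k_max largest prefix size to evaluate (defaults to all features).
#' @param grid a [grid_spec()] searched at every prefix size; the default
#'   coarse grid keeps the search tractable (see [grid_coarse()]).
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return A list of class `ifs_result`: `curve` (data frame `k`,
#'   `cv_accuracy`), `chosen_k`, `optimal_indices` (the first `chosen_k`
#'   ranked feature indices), `best_params` (grid winner at `chosen_k`),
#'   `cv_seed`, `folds`.
#' @export
ifs_select <- function(x, y, ranking = NULL, k_max = ncol(x),
                       grid = grid_coarse(), folds = 5L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (k_max < 1) stop("k_max must be at least 1")
  if (k_max > ncol(x)) stop("k_max exceeds the number of features")
  if (is.null(ranking)) ranking <- rank_features(x, y)
  y <- as.integer(y)
  fold_id <- make_folds(y, k = folds, seed = seed)
  order_idx <- ranking$feature_index
  acc <- numeric(k_max)
  params <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    xk <- x[, order_idx[seq_len(k)], drop = FALSE]
    gs <- .grid_search_folds(xk, y, grid, fold_id)
    acc[k] <- gs$cv_accuracy
    params[[k]] <- gs$params
  }
  chosen_k <- which.max(acc)  # which.max takes the first (smallest k) on ties
  structure(list(
    curve = data.frame(k = seq_len(k_max), cv_accuracy = acc),
    chosen_k = chosen_k,
    optimal_indices = order_idx[seq_len(chosen_k)],
    best_params = params[[chosen_k]],
    cv_seed = seed,
    folds = folds
  ), class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf(paste0("Incremental feature selection: k = 1..%d, ",
                     "chosen k = %d (CV accuracy %.4f)\n"),
              nrow(x$curve), x$chosen_k, x$curve$cv_accuracy[x$chosen_k]))
  invisible(x)
}

#' Write a feature ranking as a TSV table
#'
#' @param ranking a `feature_ranking`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, file) {
  utils::write.table(as.data.frame(ranking), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
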