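#' Composition breakdown of a selected feature set
#'
#' Splits a set of selected feature indices into its single-residue (AAC,
#' indices 1--20) and dipeptide (DPC, indices 21--420) parts and tallies
#' residue participation: for each of the 20 residues, how many selected
#' AAC features name it and how many residue slots of selected dipeptides
#' it fills (each residue of a dipeptide counts once per position, so a
#' selected "WW" contributes 2 to W's DPC count), plus how many selected
#' dipeptides *start* with each residue.
#'
#' @param indices unique 1-based feature indices in `1..420`.
#' @return A list of class `feature_breakdown`: `n_aac`, `n_dpc`,
#'   `aac_fraction_of_block` (`n_aac/20`), `dpc_fraction_of_block`
#'   (`n_dpc/400`), `residue_occurrence` (20 x 2 matrix, columns `aac` and
#'   `dpc`), `dipeptide_initial_counts` (named vector of 20).
#' @export
composition_breakdown <- function(indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("feature indices must be unique")
  if (any(indices < 1L | indices > 420L)) {
    stop("feature index out of range 1..420")
  }
  nm <- feature_names()[indices]
  aac <- nm[nchar(nm) == 1L]
  dpc <- nm[nchar(nm) == 2L]
  aa <- amino_acids()
  occ_aac <- vapply(aa, function(r) sum(aac == r), integer(1))
  dpc_chars <- unlist(strsplit(dpc, "", fixed = TRUE))
  occ_dpc <- vapply(aa, function(r) sum(dpc_chars == r), integer(1))
  initials <- vapply(aa, function(r) sum(substr(dpc, 1, 1) == r), integer(1))
  structure(list(
    n_aac = length(aac),
    n_dpc = length(dpc),
    aac_fraction_of_block = length(aac) / 20,
    dpc_fraction_of_block = length(dpc) / 400,
    residue_occurrence = cbind(aac = occ_aac, dpc = occ_dpc),
    dipeptide_initial_counts = initials
  ), class = "feature_breakdown")
}

#' @export
print.feature_breakdown <- function(x, ...) {
  cat(sprintf(paste0("Selected feature set: %d AAC + %d DPC features ",
                     "(%.1f%% and %.2f%% of their blocks)\n"),
              x$n_aac, x$n_dpc, 100 * x$aac_fraction_of_block,
              100 * x$dpc_fraction_of_block))
  top <- sort(rowSums(x$residue_occurrence), decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  top residues by occurrence:",
        paste(sprintf("%s=%d", names(utils::head(top, 6)),
                      utils::head(top, 6)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Accuracy-versus-prefix-size table of an IFS run
#'
#' @param ifs an [ifs_select()] result.
#' @return A data frame sorted by `k` with columns `k`, `cv_accuracy`,
#'   `optimal` (`TRUE` on the chosen row: the smallest `k` attaining the
#'   maximum accuracy).
#' @export
accuracy_curve_table <- function(ifs) {
  stopifnot(inherits(ifs, "ifs_result"))
  if (nrow(ifs$curve) == 0) stop("empty accuracy curve")
  out <- ifs$curve[order(ifs$curve$k), , drop = FALSE]
  out$optimal <- out$k == ifs$chosen_k
  rownames(out) <- NULL
  out
}

#' Plot the incremental-feature-selection accuracy curve
#'
#' @param x an `ifs_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ifs_result <- function(x, ...) {
  tab <- accuracy_curve_table(x)
  graphics::plot(tab$k, tab$cv_accuracy, type = "l",
                 xlab = "number of top-ranked features (k)",
                 ylab = "cross-validated accuracy", ...)
  best <- tab[tab$optimal, ]
  graphics::points(best$k, best$cv_accuracy, pch = 19, col = "red3")
  graphics::text(best$k, best$cv_accuracy,
                 labels = sprintf("k = %d", best$k), pos = 4, col = "red3")
  invisible(x)
}

#' Bar plot of residue participation in a selected feature set
#'
#' @param x a `feature_breakdown`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.feature_breakdown <- function(x, ...) {
  graphics::barplot(t(x$residue_occurrence), beside = TRUE,
                    legend.text = c("AAC", "DPC"),
                    xlab = "residue", ylab = "occurrences in selected set",
                    ...)
  invisible(x)
}
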