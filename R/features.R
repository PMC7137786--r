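#' Names of the 420 composition features
#'
#' Positions 1--20 are the single residues in the canonical order
#' ([amino_acids()]); positions 21--420 are the 400 ordered dipeptides in
#' row-major order over that same residue order (GG, GA, ..., GH, AG, ...,
#' HH). This ordering is fixed and part of the on-disk contract.
#'
#' @return Character vector of length 420.
#' @export
feature_names <- function() {
  aa <- amino_acids()
  c(aa, as.vector(t(outer(aa, aa, paste0))))
}

.check_sequence <- function(sequence, min_length = 1L, what = "peptide") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < min_length) {
    stop(what, " sequence shorter than ", min_length, " residues")
  }
  bad <- setdiff(chars, amino_acids())
  if (length(bad)) {
    stop(what, " contains non-canonical residues: ",
         paste(bad, collapse = ", "))
  }
  chars
}

#' Weighted amino-acid composition (AAC) of one peptide
#'
#' The entry for residue `r` is `(20/420) * count(r) / L`, where `L` is the
#' peptide length, so the 20 entries sum to 20/420. The block weight makes
#' the concatenated AAC+DPC vector of [encode_peptide()] sum to 1.
#'
#' @param sequence peptide sequence (string) or single-row peptide data
#'   frame.
#' @return Named numeric vector of length 20 in canonical residue order.
#' @export
encode_aac <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  chars <- .check_sequence(sequence, 1L)
  counts <- tabulate(match(chars, amino_acids()), 20L)
  stats::setNames((20 / 420) * counts / length(chars), amino_acids())
}

#' Weighted dipeptide composition (DPC) of one peptide
#'
#' The entry for the ordered pair `rs` is `(400/420) * count(rs) / (L - 1)`
#' with overlapping adjacent windows (so "GGG" contains GG twice); the 400
#' entries sum to 400/420.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (dipeptides in row-major
#'   canonical order).
#' @export
encode_dpc <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  chars <- .check_sequence(sequence, 2L)
  L <- length(chars)
  pairs <- paste0(chars[-L], chars[-1])
  dinames <- feature_names()[21:420]
  counts <- tabulate(match(pairs, dinames), 400L)
  stats::setNames((400 / 420) * counts / (L - 1), dinames)
}

#' Full 420-dimensional weighted composition vector
#'
#' Concatenates [encode_aac()] (20 entries, summing to 20/420) and
#' [encode_dpc()] (400 entries, summing to 400/420); the whole vector sums
#' to 1 and behaves like a probability vector over composition features.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 420 in [feature_names()] order.
#' @export
encode_peptide <- function(sequence) {
  c(encode_aac(sequence), encode_dpc(sequence))
}

#' Encode a labeled peptide set as a feature matrix
#'
#' @param x peptide data frame with labels `"positive"` / `"negative"`
#'   (see [peptides()]), or the result of [curate_peptides()] (positives
#'   then negatives, in order).
#' @return A list with `x` (numeric matrix, one row per peptide, 420
#'   columns named by [feature_names()], rownames = peptide ids) and `y`
#'   (integer vector; positive = 1, negative = 0), rows in input order.
#' @export
encode_dataset <- function(x) {
  if (inherits(x, "curation_result")) x <- rbind(x$pos, x$neg)
  x <- .as_peptides(x)
  if (nrow(x) == 0L) stop("no peptides to encode")
  if (any(x$label == "unlabeled")) {
    stop("unlabeled peptides cannot be encoded as a dataset: ",
         paste(utils::head(x$id[x$label == "unlabeled"], 5), collapse = ", "))
  }
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    rows[[i]] <- tryCatch(encode_peptide(x$sequence[[i]]), error = function(e) {
      stop("cannot encode peptide '", x$id[[i]], "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- x$id
  list(x = mat, y = as.integer(x$label == "positive"))
}

#' Write / read an encoded feature matrix as TSV
#'
#' The header row carries the feature names; the first two columns are the
#' peptide id and the 0/1 label. Feature-name order is part of the format.
#'
#' @param dataset a list with `x` and `y` as returned by [encode_dataset()].
#' @param file path.
#' @return `write_dataset_tsv`: `file`, invisibly. `read_dataset_tsv`: a
#'   list with `x` and `y`.
#' @export
write_dataset_tsv <- function(dataset, file) {
  df <- data.frame(id = rownames(dataset$x), label = dataset$y,
                   dataset$x, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[-(1:2)], feature_names())) {
    stop("feature columns do not match the canonical 420-feature order")
  }
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$id
  list(x = x, y = as.integer(df$label))
}
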