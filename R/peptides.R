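#' Canonical residue order
#'
#' The 20 canonical amino acids in the fixed order used by all feature
#' indices in this package: G, A, V, L, I, P, F, Y, W, S, T, C, M, N, Q, D,
#' E, K, R, H. This ordering (biochemical grouping, not alphabetical) is
#' part of the on-disk contract for encoded matrices and reports.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("G", "A", "V", "L", "I", "P", "F", "Y", "W", "S",
    "T", "C", "M", "N", "Q", "D", "E", "K", "R", "H")
}

# Ambiguity codes that disqualify a sequence during curation.
.AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' Build a peptide table
#'
#' Peptides are represented throughout the package as a data frame with
#' columns `id`, `sequence` and `label` (one of `"positive"`, `"negative"`,
#' `"unlabeled"`). Sequences are uppercased; no validation beyond type
#' checks is performed here (see [screen_sequence()] and
#' [curate_peptides()]).
#'
#' @param sequence character vector of peptide sequences.
#' @param id identifiers; defaults to `pep1`, `pep2`, ...
#' @param label a single label or one per peptide.
#' @return A `data.frame` with columns `id`, `sequence`, `label`.
#' @export
peptides <- function(sequence, id = NULL,
                     label = c("unlabeled", "positive", "negative")) {
  stopifnot(is.character(sequence))
  if (is.null(id)) {
    id <- if (length(sequence)) paste0("pep", seq_along(sequence))
          else character(0)
  }
  if (length(label) > 1 && length(label) != length(sequence) &&
      !all(label %in% c("unlabeled", "positive", "negative"))) {
    stop("invalid label")
  }
  label <- if (length(label) == length(sequence)) label else match.arg(label)
  stopifnot(all(label %in% c("unlabeled", "positive", "negative")))
  data.frame(id = as.character(id), sequence = toupper(sequence),
             label = rep_len(label, length(sequence)),
             stringsAsFactors = FALSE)
}

.as_peptides <- function(x, label = "unlabeled") {
  if (is.character(x)) return(peptides(x, label = label))
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x))) {
      stop("peptide data frame needs 'id' and 'sequence' columns")
    }
    if (is.null(x$label)) x$label <- label
    x$sequence <- toupper(x$sequence)
    return(x[, c("id", "sequence", "label")])
  }
  stop("cannot interpret input as peptides")
}

#' Read peptides from FASTA
#'
#' Minimal FASTA reader for short peptide sequences. Multi-line records are
#' concatenated, whitespace is stripped, and sequences are uppercased.
#' Record order is preserved and labels are set to `"unlabeled"` (use the
#' `label` argument when reading one-class files).
#'
#' @param file path to a FASTA file. Ignored if `text` is given.
#' @param text FASTA content as a character scalar or vector of lines.
#' @param label label assigned to all records.
#' @return A peptide data frame (see [peptides()]); zero rows for empty
#'   input.
#' @examples
#' read_fasta(text = ">p1\nGAVL\n>p2\nwfy")
#' @export
read_fasta <- function(file = NULL, text = NULL, label = "unlabeled") {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    if (!file.exists(file)) stop("FASTA file not found: ", file)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      ids <- c(ids, sub("^>\\s*", "", ln))
      seqs <- c(seqs, "")
      cur <- length(ids)
    } else {
      if (is.null(cur)) {
        stop("malformed FASTA: sequence data before any '>' header at line ", i)
      }
      seqs[cur] <- paste0(seqs[cur], toupper(gsub("\\s", "", ln)))
    }
  }
  # keep only the first whitespace-delimited token of the header as id
  ids <- sub("\\s.*$", "", ids)
  peptides(seqs, id = ids, label = label)
}

#' Write peptides to FASTA
#'
#' @param x peptide data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file) {
  x <- .as_peptides(x)
  writeLines(paste0(">", x$id, "\n", x$sequence), file)
  invisible(file)
}

#' Curation configuration
#'
#' Settings for [screen_sequence()] and [curate_peptides()].
#'
#' @param forbidden_residues ambiguity codes that cause rejection
#'   (default B, J, O, U, X, Z).
#' @param similarity_threshold generalized Jaccard similarity at or above
#'   which a negative peptide is considered redundant with a positive one
#'   and removed; in (0, 1], default 0.90 ("below 90%" survives).
#' @param drop_cysteine_peptides reject peptides containing cysteine.
#'   Off by default: C is informative downstream, and circular phage-display
#'   peptides (whose flanking cysteines motivate the option) are the only
#'   case where dropping makes sense.
#' @param min_length minimum residue count (>= 2, so that dipeptide
#'   composition is defined).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(forbidden_residues = .AMBIGUOUS,
                            similarity_threshold = 0.90,
                            drop_cysteine_peptides = FALSE,
                            min_length = 2L) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            min_length >= 2)
  structure(list(forbidden_residues = toupper(forbidden_residues),
                 similarity_threshold = similarity_threshold,
                 drop_cysteine_peptides = isTRUE(drop_cysteine_peptides),
                 min_length = as.integer(min_length)),
            class = "curation_config")
}

#' Screen one raw sequence
#'
#' Applies the character-level acceptance rules, in order: ambiguous
#' residue codes, non-alphabetic characters, minimum length, and
#' (optionally) cysteine content. The first matching rule determines the
#' rejection reason.
#'
#' @param raw a non-empty string (uppercased internally).
#' @param config a [curation_config()].
#' @return A list with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise one of `"ambiguous_residue"`, `"non_alphabetic"`,
#'   `"too_short"`, `"cysteine"`).
#' @examples
#' screen_sequence("GAXVL")  # rejected: X is ambiguous
#' screen_sequence("GA-VL")  # rejected: non-alphabetic
#' @export
screen_sequence <- function(raw, config = curation_config()) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  s <- toupper(raw)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  reason <- NA_character_
  if (any(chars %in% config$forbidden_residues)) {
    reason <- "ambiguous_residue"
  } else if (any(!chars %in% LETTERS)) {
    reason <- "non_alphabetic"
  } else if (length(chars) < config$min_length) {
    reason <- "too_short"
  } else if (config$drop_cysteine_peptides && any(chars == "C")) {
    reason <- "cysteine"
  }
  list(accept = is.na(reason), reason = reason)
}

# residue count matrix over a common alphabet, rows = sequences
.residue_counts <- function(seqs, alphabet) {
  t(vapply(strsplit(seqs, "", fixed = TRUE),
           function(a) tabulate(match(a, alphabet), length(alphabet)),
           integer(length(alphabet))))
}

#' Generalized Jaccard similarity of two peptides
#'
#' Treats each sequence as a residue multiset: with `c_x(r)` the count of
#' residue `r` in sequence `x`, the similarity is
#' `sum_r min(c_a(r), c_b(r)) / sum_r max(c_a(r), c_b(r))`. Symmetric, in
#' \[0, 1\], and equal to 1 exactly when the two sequences are permutations
#' of the same multiset.
#'
#' @param a,b peptide sequences (strings) or single-row peptide data frames.
#' @return Similarity in \[0, 1\].
#' @examples
#' generalized_jaccard("AAG", "AGG")  # 0.5
#' @export
generalized_jaccard <- function(a, b) {
  a <- if (is.data.frame(a)) a$sequence[[1]] else a
  b <- if (is.data.frame(b)) b$sequence[[1]] else b
  stopifnot(is.character(a), is.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("generalized_jaccard: empty sequence")
  ab <- sort(unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]]))
  cc <- .residue_counts(c(a, b), ab)
  sum(pmin(cc[1, ], cc[2, ])) / sum(pmax(cc[1, ], cc[2, ]))
}

#' Curate a two-class peptide dataset
#'
#' Applies, in order: (1) per-sequence screening ([screen_sequence()]);
#' (2) removal of exact duplicate sequences within each class (first
#' occurrence kept); (3) removal from the negative class of any sequence
#' also present among the positives; (4) removal of every negative whose
#' generalized Jaccard similarity to any positive is at or above
#' `similarity_threshold`. Every removal is accounted for in the returned
#' report.
#'
#' @param pos,neg positive / negative peptides (data frame or character
#'   vector of sequences).
#' @param config a [curation_config()].
#' @return A list of class `curation_result` with elements `pos`, `neg`
#'   (curated peptide data frames, labels set) and `report` (class
#'   `curation_report`).
#' @export
curate_peptides <- function(pos, neg, config = curation_config()) {
  pos <- .as_peptides(pos, label = "positive")
  neg <- .as_peptides(neg, label = "negative")
  pos$label <- rep_len("positive", nrow(pos))
  neg$label <- rep_len("negative", nrow(neg))

  reasons <- c("ambiguous_residue", "non_alphabetic", "too_short",
               "cysteine", "duplicate")
  tally <- function() stats::setNames(integer(length(reasons)), reasons)
  rej_pos <- tally()
  rej_neg <- tally()

  screen_class <- function(df, rej) {
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      v <- if (nzchar(df$sequence[[i]])) screen_sequence(df$sequence[[i]], config)
           else list(accept = FALSE, reason = "too_short")
      keep[i] <- v$accept
      if (!v$accept) rej[v$reason] <- rej[v$reason] + 1L
    }
    list(df = df[keep, , drop = FALSE], rej = rej)
  }
  sp <- screen_class(pos, rej_pos); pos <- sp$df; rej_pos <- sp$rej
  sn <- screen_class(neg, rej_neg); neg <- sn$df; rej_neg <- sn$rej

  dup_p <- duplicated(pos$sequence)
  rej_pos["duplicate"] <- sum(dup_p)
  pos <- pos[!dup_p, , drop = FALSE]
  dup_n <- duplicated(neg$sequence)
  rej_neg["duplicate"] <- sum(dup_n)
  neg <- neg[!dup_n, , drop = FALSE]

  cross <- neg$sequence %in% pos$sequence
  n_cross <- sum(cross)
  neg <- neg[!cross, , drop = FALSE]

  n_sim <- 0L
  if (nrow(neg) > 0 && nrow(pos) > 0) {
    alphabet <- sort(unique(unlist(strsplit(c(pos$sequence, neg$sequence),
                                            "", fixed = TRUE))))
    cp <- .residue_counts(pos$sequence, alphabet)
    cn <- .residue_counts(neg$sequence, alphabet)
    drop_sim <- vapply(seq_len(nrow(cn)), function(j) {
      mins <- pmin(cp, rep(cn[j, ], each = nrow(cp)))
      maxs <- pmax(cp, rep(cn[j, ], each = nrow(cp)))
      any(rowSums(mins) / rowSums(maxs) >= config$similarity_threshold)
    }, logical(1))
    n_sim <- sum(drop_sim)
    neg <- neg[!drop_sim, , drop = FALSE]
  }

  if (nrow(pos) == 0L) stop("empty class after curation: no positives remain")
  if (nrow(neg) == 0L) stop("empty class after curation: no negatives remain")

  report <- structure(list(
    n_input_pos = nrow(pos) + sum(rej_pos),
    n_input_neg = nrow(neg) + sum(rej_neg) + n_cross + n_sim,
    n_rejected_by_reason = list(positive = rej_pos, negative = rej_neg),
    n_cross_set_duplicates_removed = n_cross,
    n_similarity_removed = n_sim,
    n_output_pos = nrow(pos),
    n_output_neg = nrow(neg)
  ), class = "curation_report")

  rownames(pos) <- NULL
  rownames(neg) <- NULL
  structure(list(pos = pos, neg = neg, report = report),
            class = "curation_result")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input:  %d positive, %d negative\n",
              x$n_input_pos, x$n_input_neg))
  for (cl in c("positive", "negative")) {
    r <- x$n_rejected_by_reason[[cl]]
    r <- r[r > 0]
    if (length(r)) {
      cat(sprintf("  rejected (%s): %s\n", cl,
                  paste(sprintf("%s=%d", names(r), r), collapse = ", ")))
    }
  }
  cat(sprintf("  cross-set duplicates removed (from negatives): %d\n",
              x$n_cross_set_duplicates_removed))
  cat(sprintf("  similarity-redundant negatives removed: %d\n",
              x$n_similarity_removed))
  cat(sprintf("  output: %d positive, %d negative\n",
              x$n_output_pos, x$n_output_neg))
  invisible(x)
}

#' Write a curation report as tab-separated key/value text
#'
#' @param report a `curation_report`.
#' @param file output path or connection.
#' @return `file`, invisibly.
#' @export
write_curation_report <- function(report, file) {
  stopifnot(inherits(report, "curation_report"))
  kv <- c(
    n_input_pos = report$n_input_pos,
    n_input_neg = report$n_input_neg,
    stats::setNames(report$n_rejected_by_reason$positive,
                    paste0("rejected_pos_",
                           names(report$n_rejected_by_reason$positive))),
    stats::setNames(report$n_rejected_by_reason$negative,
                    paste0("rejected_neg_",
                           names(report$n_rejected_by_reason$negative))),
    n_cross_set_duplicates_removed = report$n_cross_set_duplicates_removed,
    n_similarity_removed = report$n_similarity_removed,
    n_output_pos = report$n_output_pos,
    n_output_neg = report$n_output_neg
  )
  writeLines(paste(names(kv), kv, sep = "\t"), file)
  invisible(file)
}
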