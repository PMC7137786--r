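#' Generate a synthetic two-class peptide benchmark
#'
#' Emulates the statistical shape of a phage-display-derived
#' polystyrene-binding benchmark: two balanced classes of short peptides
#' over the 20-residue alphabet. Negatives are drawn i.i.d. uniformly over
#' the residues; positives use sampling weights in which each residue of
#' `enriched_residues` is multiplied by `enrichment_factor` before
#' renormalization (`enrichment_factor = 1` gives exchangeable classes --
#' a null dataset). Lengths are uniform over `length_range`. Optionally a
#' fixed dipeptide motif is inserted into positives with probability
#' `motif_prob`, placing signal in dipeptide rather than single-residue
#' composition. All outputs pass [screen_sequence()] and the result is
#' byte-reproducible from `seed`.
#'
#' @param n_pos,n_neg class sizes (both >= 4; defaults 104 each, matching
#'   the published benchmark's shape).
#' @param length_range integer range of peptide lengths (min >= 2;
#'   default 7--12, phage-display-insert-like).
#' @param enriched_residues residues over-represented in positives
#'   (default W, F, Y).
#' @param enrichment_factor multiplicative sampling weight (>= 1) on the
#'   enriched residues in positives.
#' @param motif optional 2-residue string inserted into positives.
#' @param motif_prob per-positive probability of a motif insertion.
#' @param seed integer seed.
#' @return A list with labeled peptide data frames `pos` and `neg` and a
#'   `manifest` list recording every setting.
#' @export
synth_peptides <- function(n_pos = 104L, n_neg = 104L,
                           length_range = c(7L, 12L),
                           enriched_residues = c("W", "F", "Y"),
                           enrichment_factor = 8, motif = NULL,
                           motif_prob = 0, seed = 1L) {
  stopifnot(n_pos >= 4, n_neg >= 4, length(length_range) == 2,
            length_range[1] >= 2, length_range[1] <= length_range[2],
            enrichment_factor >= 1,
            all(enriched_residues %in% amino_acids()))
  if (!is.null(motif)) stopifnot(nchar(motif) == 2,
                                 all(strsplit(motif, "")[[1]] %in% amino_acids()))
  aa <- amino_acids()
  w_pos <- rep(1, 20)
  w_pos[aa %in% enriched_residues] <- enrichment_factor
  w_pos <- w_pos / sum(w_pos)
  lens <- length_range[1]:length_range[2]
  draw <- function(n, w) {
    vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(lens, 1), replace = TRUE, prob = w),
            collapse = "")
    }, character(1))
  }
  pos_seq <- neg_seq <- NULL
  .with_seed(seed, {
    pos_seq <- draw(n_pos, w_pos)
    if (!is.null(motif) && motif_prob > 0) {
      hit <- stats::runif(n_pos) < motif_prob
      for (i in which(hit)) {
        s <- pos_seq[[i]]
        at <- sample(nchar(s) - 1L, 1)
        substr(pos_seq[i], at, at + 1L) <- motif
      }
    }
    neg_seq <- draw(n_neg, rep(1 / 20, 20))
  })
  list(
    pos = peptides(pos_seq, id = sprintf("pos_%03d", seq_len(n_pos)),
                   label = "positive"),
    neg = peptides(neg_seq, id = sprintf("neg_%03d", seq_len(n_neg)),
                   label = "negative"),
    manifest = list(n_pos = n_pos, n_neg = n_neg,
                    length_range = as.integer(length_range),
                    enriched_residues = enriched_residues,
                    enrichment_factor = enrichment_factor,
                    motif = motif, motif_prob = motif_prob, seed = seed)
  )
}

#' Generate a separable (or pure-noise) Gaussian feature dataset
#'
#' Two Gaussian blobs (unit standard deviation) whose centers are
#' `separation` apart along each of `informative_dims` dimensions, plus
#' `noise_dims` standard-normal nuisance dimensions. With the default
#' `separation = 6` over 2 informative dimensions the class centers are
#' ~8.5 standard deviations apart, so an RBF or linear SVM separates the
#' classes perfectly; with `informative_dims = 0` the two classes are
#' identically distributed (a null dataset).
#'
#' @param n_per_class samples per class (>= 2).
#' @param informative_dims number of dimensions carrying the class shift
#'   (0 allowed).
#' @param noise_dims number of uninformative dimensions.
#' @param separation center shift per informative dimension, in standard
#'   deviations.
#' @param seed integer seed.
#' @return A list with `x` (matrix, positives first) and `y` (1/0 labels).
#' @export
synth_separable <- function(n_per_class = 50L, informative_dims = 2L,
                            noise_dims = 2L, separation = 6, seed = 1L) {
  stopifnot(n_per_class >= 2, informative_dims >= 0, noise_dims >= 0,
            informative_dims + noise_dims >= 1)
  n <- 2L * n_per_class
  d <- informative_dims + noise_dims
  x <- NULL
  .with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    if (informative_dims > 0) {
      x[seq_len(n_per_class), seq_len(informative_dims)] <-
        x[seq_len(n_per_class), seq_len(informative_dims)] + separation
    }
  })
  colnames(x) <- paste0("dim", seq_len(d))
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}

#' Write a synthetic benchmark to FASTA plus manifest
#'
#' One FASTA file per class plus a JSON manifest recording the generator
#' settings and seed.
#'
#' @param dataset a [synth_peptides()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synth <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pos = file.path(dir, "positives.fasta"),
             neg = file.path(dir, "negatives.fasta"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta(dataset$pos, paths["pos"])
  write_fasta(dataset$neg, paths["neg"])
  jsonlite::write_json(dataset$manifest, paths["manifest"],
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(paths)
}
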