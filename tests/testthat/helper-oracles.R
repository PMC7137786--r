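# Independent oracles and fixture builders shared across test files.
# Everything here deliberately uses naive arithmetic (per-element loops,
# brute-force enumeration) so the package code is checked against an
# implementation that shares no code path with it.

random_peptides <- function(n, len_range = c(2L, 30L), seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(amino_acids(), sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# naive counting encoder: integer counts via explicit loops, then the
# block weights (exact equality with the package encoder is expected,
# since both scale integer counts the same way)
oracle_encode <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  nm <- feature_names()
  counts <- stats::setNames(integer(420), nm)
  for (ch in chars) counts[ch] <- counts[ch] + 1L
  for (i in seq_len(L - 1)) {
    di <- paste0(chars[i], chars[i + 1])
    counts[di] <- counts[di] + 1L
  }
  v <- numeric(420)
  v[1:20] <- (20 / 420) * counts[1:20] / L
  v[21:420] <- (400 / 420) * counts[21:420] / (L - 1)
  stats::setNames(v, nm)
}

# textbook one-way two-group ANOVA F via the group-means formulas
oracle_anova_f <- function(a, b) {
  n <- length(a) + length(b)
  grand <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - grand)^2 + length(b) * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  (ssb / 1) / (ssw / (n - 2))
}

# brute-force pairwise Mann-Whitney AUC, ties counted 1/2
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# multiset generalized Jaccard by explicit per-letter min/max counting
oracle_jaccard <- function(a, b) {
  la <- strsplit(a, "")[[1]]
  lb <- strsplit(b, "")[[1]]
  letters_all <- union(la, lb)
  mins <- maxs <- 0
  for (ch in letters_all) {
    ca <- sum(la == ch)
    cb <- sum(lb == ch)
    mins <- mins + min(ca, cb)
    maxs <- maxs + max(ca, cb)
  }
  mins / maxs
}
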