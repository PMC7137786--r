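test_that("FASTA parsing normalizes records and preserves order", {
  pep <- read_fasta(text = ">p1\nGAVL")
  expect_equal(pep$id, "p1")
  expect_equal(pep$sequence, "GAVL")
  expect_equal(pep$label, "unlabeled")

  expect_equal(nrow(read_fasta(text = "")), 0L)

  pep <- read_fasta(text = ">p1\ngavl\nwfy")
  expect_equal(pep$sequence, "GAVLWFY")

  pep <- read_fasta(text = ">a desc here\nGA VL\n\n>b\nWF\nYH")
  expect_equal(pep$id, c("a", "b"))
  expect_equal(pep$sequence, c("GAVL", "WFYH"))

  expect_error(read_fasta(text = "GAVL\n>p1\nWFY"), "line 1")
})

test_that("FASTA writing round-trips through reading", {
  pep <- peptides(c("GAVL", "WWFY"), id = c("x", "y"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pep, f)
  back <- read_fasta(f)
  expect_equal(back$id, pep$id)
  expect_equal(back$sequence, pep$sequence)
})

test_that("screening applies the rejection rules in order", {
  expect_equal(screen_sequence("GAXVL")$reason, "ambiguous_residue")
  expect_equal(screen_sequence("GA-VL")$reason, "non_alphabetic")
  expect_true(screen_sequence("GAVL")$accept)
  expect_equal(screen_sequence("G")$reason, "too_short")
  # ambiguity outranks non-alphabetic when both are present
  expect_equal(screen_sequence("GX-VL")$reason, "ambiguous_residue")
  # cysteine only rejected when asked for
  expect_true(screen_sequence("GACL")$accept)
  cfg <- curation_config(drop_cysteine_peptides = TRUE)
  expect_equal(screen_sequence("GACL", cfg)$reason, "cysteine")
  # lowercase input is normalized, not rejected
  expect_true(screen_sequence("gavl")$accept)
})

test_that("generalized Jaccard matches hand and oracle computations", {
  expect_equal(generalized_jaccard("WFY", "WFY"), 1.0)
  expect_equal(generalized_jaccard("AAA", "GGG"), 0.0)
  expect_equal(generalized_jaccard("AAG", "AGG"), 0.5)
  expect_equal(generalized_jaccard("WWWW", "WWWV"), 3 / 5)

  set.seed(42)
  for (i in 1:50) {
    a <- paste(sample(amino_acids(), sample(2:15, 1), TRUE), collapse = "")
    b <- paste(sample(amino_acids(), sample(2:15, 1), TRUE), collapse = "")
    expect_equal(generalized_jaccard(a, b), oracle_jaccard(a, b))
    # symmetry and range
    expect_equal(generalized_jaccard(a, b), generalized_jaccard(b, a))
    expect_gte(generalized_jaccard(a, b), 0)
    expect_lte(generalized_jaccard(a, b), 1)
    # permutation of the same multiset scores exactly 1
    perm <- paste(sample(strsplit(a, "")[[1]]), collapse = "")
    expect_identical(generalized_jaccard(a, perm), 1)
  }
  expect_error(generalized_jaccard("", "AA"), "empty")
})

test_that("curation removes duplicates and similar negatives with exact bookkeeping", {
  res <- curate_peptides(c("WWFY"), c("WWFY", "GAVL"))
  expect_equal(res$pos$sequence, "WWFY")
  expect_equal(res$neg$sequence, "GAVL")
  expect_equal(res$report$n_cross_set_duplicates_removed, 1L)

  # similarity 3/5 = 0.6: kept at threshold 0.9, removed at 0.5
  res <- curate_peptides(c("WWWW", "AAGG"), c("WWWV", "GAVL"))
  expect_equal(res$neg$sequence, c("WWWV", "GAVL"))
  expect_error(
    curate_peptides(c("WWWW"), c("WWWV"),
                    curation_config(similarity_threshold = 0.5)),
    "empty class")

  expect_error(curate_peptides(character(0), c("GAVL")), "empty class")
})

test_that("curation report balances per class and curation is idempotent", {
  pos <- c("WWFY", "WWFY", "GAXL", "WFYH", "AC")
  neg <- c("WWFY", "GAVL", "GA-L", "G", "WFHY", "GAVL")
  res <- curate_peptides(pos, neg)
  rep <- res$report
  expect_equal(rep$n_output_pos + sum(rep$n_rejected_by_reason$positive),
               rep$n_input_pos)
  expect_equal(rep$n_output_neg + sum(rep$n_rejected_by_reason$negative) +
                 rep$n_cross_set_duplicates_removed +
                 rep$n_similarity_removed,
               rep$n_input_neg)
  expect_equal(rep$n_input_pos, length(pos))
  expect_equal(rep$n_input_neg, length(neg))
  # WFYH (pos) vs WFHY (neg) share a residue multiset: similarity 1 >= 0.9
  expect_equal(rep$n_similarity_removed, 1L)

  # curating the curated output removes nothing
  res2 <- curate_peptides(res$pos, res$neg)
  expect_equal(res2$pos$sequence, res$pos$sequence)
  expect_equal(res2$neg$sequence, res$neg$sequence)
  expect_equal(sum(res2$report$n_rejected_by_reason$positive), 0L)
  expect_equal(sum(res2$report$n_rejected_by_reason$negative), 0L)
  expect_equal(res2$report$n_cross_set_duplicates_removed, 0L)
  expect_equal(res2$report$n_similarity_removed, 0L)

  # report serializes as key/value TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curation_report(rep, f)
  kv <- read.delim(f, header = FALSE)
  expect_true("n_output_pos" %in% kv$V1)
})
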