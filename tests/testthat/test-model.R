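test_that("grid specs enumerate inclusively and validate their ranges", {
  g <- grid_spec(-2, 2, 1, 0, 4, 2)
  expect_equal(g$log2c, -2:2)
  expect_equal(g$log2gamma, c(0, 2, 4))
  expect_error(grid_spec(2, -2, 1), "log2c_min <= log2c_max")
  expect_equal(length(grid_published()$log2c), 61L)
  expect_equal(length(grid_published()$log2gamma), 29L)
})

test_that("grid search is exhaustive, deterministic, and tie-breaks on smaller C", {
  sp <- synth_separable(n_per_class = 20, seed = 6)

  # degenerate 1x1 grid returns that point
  g1 <- grid_spec(3, 3, 1, -1, -1, 1)
  res <- grid_search(sp$x, sp$y, g1, folds = 3, seed = 6)
  expect_equal(res$params$log2c, 3)
  expect_equal(res$params$log2gamma, -1)
  expect_equal(nrow(res$table), 1L)

  # separable blobs: some grid point reaches perfect CV accuracy
  res <- grid_search(sp$x, sp$y, grid_default(), folds = 5, seed = 6)
  expect_equal(res$cv_accuracy, 1.0)

  # many points tie at accuracy 1; the winner is the smallest log2c, then
  # the smallest log2gamma among the tied set
  tied <- res$table[res$table$cv_accuracy == res$cv_accuracy, ]
  best <- tied[order(tied$log2c, tied$log2gamma), ][1, ]
  expect_equal(res$params$log2c, best$log2c)
  expect_equal(res$params$log2gamma, best$log2gamma)

  # deterministic given the seed
  res2 <- grid_search(sp$x, sp$y, grid_default(), folds = 5, seed = 6)
  expect_identical(res$table, res2$table)

  expect_error(grid_search(sp$x, rep(1, length(sp$y)), grid_default()),
               "both classes")
})

test_that("training is deterministic and separates a separable pair", {
  x <- rbind(c(0, 0), c(1, 1))
  colnames(x) <- c("d1", "d2")
  m <- svm_train(x, c(0L, 1L), cost = 10, gamma = 1)
  pr <- predict(m, x)
  expect_equal(pr$label, c("negative", "positive"))

  sp <- synth_separable(n_per_class = 25, seed = 9)
  m1 <- svm_train(sp$x, sp$y, cost = 4, gamma = 0.5)
  m2 <- svm_train(sp$x, sp$y, cost = 4, gamma = 0.5)
  probe <- synth_separable(n_per_class = 10, seed = 10)$x
  expect_identical(predict(m1, probe)$score, predict(m2, probe)$score)

  # degenerate input is an error, not a silent fit
  xdeg <- matrix(1, 4, 3)
  expect_error(svm_train(xdeg, c(1, 1, 0, 0), 1, 1), "degenerate")
})

test_that("in-package decision values equal the fitting library's", {
  sp <- synth_separable(n_per_class = 20, noise_dims = 3, seed = 12)
  yf <- factor(sp$y, levels = c(0L, 1L))
  fit <- e1071::svm(sp$x, yf, type = "C-classification", kernel = "radial",
                    cost = 3, gamma = 0.7, scale = FALSE)
  dv <- attr(predict(fit, sp$x, decision.values = TRUE), "decision.values")
  sign <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") 1 else -1
  m <- svm_train(sp$x, sp$y, cost = 3, gamma = 0.7)
  expect_equal(predict(m, sp$x)$score, sign * as.numeric(dv),
               tolerance = 1e-10)
})

test_that("prediction encodes peptides, skips bad records, and is stateless", {
  bench <- synth_peptides(n_pos = 30, n_neg = 30, seed = 14)
  ds <- encode_dataset(rbind(bench$pos, bench$neg))
  m <- svm_train(ds$x[, 1:20], ds$y, cost = 32, gamma = 512,
                 feature_indices = 1:20)

  pep <- rbind(bench$pos[1:3, ], peptides("GAXVL", id = "bad"),
               bench$neg[1:3, ])
  pr <- predict(m, pep)
  expect_equal(nrow(pr), 7L)
  expect_false(pr$ok[4])
  expect_match(pr$reason[4], "non-canonical")
  expect_true(all(pr$ok[-4]))
  expect_true(all(is.finite(pr$score[-4])))

  # batch order does not affect scores
  pr_rev <- predict(m, pep[7:1, ])
  expect_equal(pr_rev$score[7:1], pr$score)
})

test_that("save/load round-trips the classifier losslessly", {
  bench <- synth_peptides(n_pos = 20, n_neg = 20, seed = 15)
  ds <- encode_dataset(rbind(bench$pos, bench$neg))
  sel <- rank_features(ds$x, ds$y)$feature_index[1:10]
  m <- svm_train(ds$x[, sel], ds$y, cost = 8, gamma = 256,
                 feature_indices = sel, seed = 15)
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, f)
  m2 <- load_classifier(f)

  expect_identical(m2$hyperparams$cost, m$hyperparams$cost)
  expect_identical(m2$hyperparams$gamma, m$hyperparams$gamma)
  expect_identical(m2$feature_indices, m$feature_indices)
  expect_identical(m2$metadata$seed, m$metadata$seed)
  expect_identical(m2$metadata$fingerprint, m$metadata$fingerprint)

  probe <- synth_peptides(n_pos = 10, n_neg = 10, seed = 16)
  probe <- rbind(probe$pos, probe$neg)
  expect_identical(predict(m2, probe)$score, predict(m, probe)$score)
  expect_identical(predict(m2, probe)$label, predict(m, probe)$label)

  # corrupt / truncated archives raise format errors
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 50), f)
  expect_error(load_classifier(f), "archive")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), f2, auto_unbox = TRUE)
  expect_error(load_classifier(f2), "format error")
})
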