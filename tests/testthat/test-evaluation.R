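test_that("stratified folds balance classes and reproduce from seed", {
  y <- rep(c(1L, 0L), each = 104)
  f <- make_folds(y, k = 5, seed = 21)
  expect_setequal(unique(f), 1:5)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(42L, 42L, 42L, 41L, 41L))
  per_fold_pos <- table(f[y == 1])
  expect_true(all(per_fold_pos %in% c(20L, 21L)))

  expect_identical(make_folds(y, 5, seed = 21), make_folds(y, 5, seed = 21))
  expect_false(identical(make_folds(y, 5, seed = 21),
                         make_folds(y, 5, seed = 22)))

  f2 <- make_folds(c(1, 1, 0, 0), k = 2, seed = 1)
  expect_equal(as.vector(table(f2)), c(2L, 2L))
  expect_equal(as.vector(table(f2[c(1, 2)])), c(1L, 1L))  # 1 pos per fold

  expect_error(make_folds(c(1, 1, 1, 0), k = 2), "fewer members")
})

test_that("confusion counts tally the four cells", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(cc$fp + cc$fn, 0L)
  cc <- confusion_counts(rep(c(1, 0), each = 10), rep(1, 20))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 10L, fp = 10L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "length mismatch")
})

test_that("sensitivity/specificity/accuracy follow their definitions", {
  m <- sn_sp_acc(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(unname(m), c(0.90, 0.80, 0.85))
  expect_equal(unname(sn_sp_acc(list(tp = 5, fn = 0, tn = 5, fp = 0))),
               c(1, 1, 1))
  expect_equal(unname(sn_sp_acc(list(tp = 0, fn = 10, tn = 10, fp = 0))),
               c(0, 1, 0.5))
  expect_error(sn_sp_acc(list(tp = 0, fn = 0, tn = 5, fp = 5)), "undefined")

  # acc = (sn*P + sp*N)/(P+N) algebraically, on random confusions
  set.seed(31)
  for (i in 1:50) {
    cc <- list(tp = sample(0:30, 1), fn = sample(1:30, 1),
               tn = sample(0:30, 1), fp = sample(1:30, 1))
    m <- sn_sp_acc(cc)
    P <- cc$tp + cc$fn
    N <- cc$tn + cc$fp
    expect_equal(unname(m["acc"]), (m[["sn"]] * P + m[["sp"]] * N) / (P + N))
  }
})

test_that("roc_auc equals the brute-force pairwise statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.3, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)

  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # frequent ties
    expect_equal(roc_auc(y, s), oracle_auc(y, s))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc_auc agrees with pROC and flips under score negation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  for (i in 1:10) {
    y <- rep(c(1, 0), each = 15)
    s <- rnorm(30) + y
    expect_equal(roc_auc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)  # tie-free scores
  }
})

test_that("cross-validation is deterministic and perfect on separable data", {
  sp <- synth_separable(n_per_class = 30, seed = 61)
  cv <- cross_validate(sp$x, sp$y, mode = "published",
                       selected_indices = seq_len(ncol(sp$x)),
                       params = list(cost = 4, gamma = 0.25),
                       folds = 5, seed = 61)
  expect_equal(unname(cv$mean["acc"]), 1.0)
  expect_equal(unname(cv$mean["auc"]), 1.0)
  # mean of per-fold accuracies is the headline accuracy
  expect_equal(mean(cv$per_fold$acc), unname(cv$mean["acc"]))

  cv2 <- cross_validate(sp$x, sp$y, mode = "published",
                        selected_indices = seq_len(ncol(sp$x)),
                        params = list(cost = 4, gamma = 0.25),
                        folds = 5, seed = 61)
  expect_identical(cv$per_fold, cv2$per_fold)
})
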