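test_that("t-test selection finds a planted feature and matches t.test ranking", {
  withr::with_seed(42, {
    cls <- rep(c("case", "control"), each = 10)
    x <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(sprintf("S%02d", 1:20), paste0("f", 1:10)))
    x[cls == "case", 1] <- x[cls == "case", 1] + 5
  })
  expect_identical(select_features_ttest(x, cls, 1), "f1")

  # full ranking agrees with per-column stats::t.test (Welch)
  tstats <- vapply(seq_len(ncol(x)), function(j) {
    abs(stats::t.test(x[cls == "case", j], x[cls == "control", j])$statistic)
  }, numeric(1))
  expect_identical(select_features_ttest(x, cls, 10),
                   colnames(x)[order(-tstats)])
})

test_that("selection clips the count and breaks ties by feature order", {
  withr::with_seed(1, {
    cls <- rep(c("case", "control"), each = 5)
    x <- matrix(rnorm(10 * 3), 10, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  })
  expect_length(select_features_ttest(x, cls, 100), 3)
  dup <- cbind(x, x[, 1, drop = FALSE])
  colnames(dup) <- c("a", "b", "c", "z_copy_of_a")
  picked <- select_features_ttest(dup, cls, 4)
  expect_true(which(picked == "a") < which(picked == "z_copy_of_a"))
})

test_that("DLDA estimates match closed-form means and pooled variances", {
  # trivial 1-D case with floored variance
  m1 <- matrix(c(0, 0, 10, 10), 4, 1, dimnames = list(NULL, "f1"))
  fit <- fit_dlda(m1, c("a", "a", "b", "b"))
  expect_equal(unname(fit$means[, 1]), c(0, 10))
  expect_equal(fit$priors, c(0.5, 0.5))

  withr::with_seed(7, {
    cls <- rep(c("case", "control"), c(12, 8))
    x <- matrix(rnorm(20 * 2, 0, 2), 20, 2,
                dimnames = list(NULL, c("f1", "f2")))
  })
  fit <- fit_dlda(x, cls)
  for (j in 1:2) {
    ss <- sum((x[cls == "case", j] - mean(x[cls == "case", j]))^2) +
      sum((x[cls == "control", j] - mean(x[cls == "control", j]))^2)
    expect_equal(fit$variance[j], ss / 18)
    expect_equal(unname(fit$means[1, j]), mean(x[cls == "case", j]))
  }
  expect_equal(fit$priors, c(0.6, 0.4))

  # duplicating every sample changes neither means nor pooled variances much
  fit2 <- fit_dlda(rbind(x, x), c(cls, cls))
  expect_equal(fit2$means, fit$means)
  expect_equal(fit2$variance, fit$variance * 18 / 19)  # df 18 -> 38 of 2*ss
})

test_that("DLDA predictions agree with a brute-force density oracle", {
  tr <- make_separable_assay(n = 30, m = 5, n_informative = 2, delta = 2,
                             seed = 11)
  fit <- fit_dlda(tr$assay$matrix, tr$labels)
  withr::with_seed(12, {
    test_x <- matrix(rnorm(50 * 5), 50, 5,
                     dimnames = list(NULL, colnames(tr$assay$matrix)))
  })
  expect_identical(predict_dlda(fit, test_x), unname(dlda_oracle(fit, test_x)))

  # a point at a class mean is assigned that class; an exact midpoint with
  # equal priors goes to the first-listed class
  sym <- fit_dlda(matrix(c(-1, -1, 1, 1), 4, 1, dimnames = list(NULL, "f1")),
                  c("a", "a", "b", "b"))
  expect_identical(predict_dlda(sym, matrix(-1, 1, 1,
                                            dimnames = list(NULL, "f1"))), "a")
  expect_identical(predict_dlda(sym, matrix(0, 1, 1,
                                            dimnames = list(NULL, "f1"))), "a")
  expect_error(predict_dlda(fit, test_x[, 1:2]), "missing model feature")
})

test_that("feature-count tuning prefers informative counts and small ties", {
  expect_identical(tune_feature_count(matrix(rnorm(40), 10, 4,
                                             dimnames = list(NULL, paste0("f", 1:4))),
                                      rep(c("a", "b"), 5), 30), 30L)

  # 10 planted features among 90 noise: a small candidate beats 100
  sep <- make_separable_assay(n = 60, m = 100, n_informative = 10,
                              delta = 3, seed = 21)
  picked <- tune_feature_count(sep$assay$matrix, sep$labels,
                               c(10, 100), seed = 3)
  expect_identical(picked, 10L)

  # identical columns and balanced classes: every count gives the same
  # predictions, so the tie goes to the smallest candidate
  base <- withr::with_seed(22, rnorm(16))
  x <- cbind(base, base, base, base)
  colnames(x) <- paste0("f", 1:4)
  cls <- rep(c("a", "b"), length.out = 16)
  for (s in 1:5) {
    expect_identical(tune_feature_count(x, cls, c(2, 3, 4), seed = s), 2L)
  }
})

test_that("repeated CV gives every patient exactly r out-of-sample votes", {
  sep <- make_separable_assay(n = 8, m = 6, seed = 5)
  preds <- run_repeated_cv(sep$assay, sep$labels,
                           small_config(repeats = 3, feature_counts = 3))
  expect_equal(nrow(preds), 8)
  expect_true(all(preds$n_votes == 3))
  expect_true(all(lengths(preds$votes) == 3))
})

test_that("perfect separation yields unanimous confidence and accuracy", {
  sep <- make_separable_assay(n = 30, m = 10, n_informative = 3, delta = 20,
                              sd = 0.1, seed = 6)
  preds <- run_repeated_cv(sep$assay, sep$labels, small_config())
  expect_true(all(preds$confidence == 1))
  expect_true(all(preds$accuracy == 1))
  expect_identical(preds$majority, unname(sep$labels[preds$sample]))
})

test_that("label permutation drives mean patient accuracy to chance", {
  sep <- make_separable_assay(n = 24, m = 10, seed = 8)
  accs <- vapply(1:20, function(s) {
    perm <- withr::with_seed(100 + s,
                             setNames(sample(unname(sep$labels)),
                                      names(sep$labels)))
    mean(run_repeated_cv(sep$assay, perm,
                         small_config(repeats = 3, seed = s))$accuracy)
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("runs are reproducible from the seed and vary across seeds", {
  sep <- make_separable_assay(n = 20, m = 8, delta = 1, seed = 9)
  a <- run_repeated_cv(sep$assay, sep$labels, small_config(seed = 4))
  b <- run_repeated_cv(sep$assay, sep$labels, small_config(seed = 4))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- run_repeated_cv(sep$assay, sep$labels, small_config(seed = 5))
  expect_true(all(c$n_votes == 5))
  expect_false(identical(a$votes, c$votes))
})

test_that("confidence is order- and relabel-invariant with the exact grid", {
  withr::with_seed(31, {
    for (r in c(5, 10, 50)) {
      votes <- sample(c("case", "control"), r, replace = TRUE)
      cc <- compute_confidence(votes, seed = 1)
      expect_identical(compute_confidence(rev(votes), seed = 1)$confidence,
                       cc$confidence)
      flipped <- ifelse(votes == "case", "control", "case")
      expect_identical(compute_confidence(flipped, seed = 1)$confidence,
                       cc$confidence)
      grid <- sort(unique(2 * abs(0:r / r - 0.5)))
      expect_true(cc$confidence %in% grid)
    }
  })
})

test_that("confidence is materially lower on permuted labels than separable data", {
  sep <- make_separable_assay(n = 24, m = 10, delta = 6, seed = 13)
  strong <- run_repeated_cv(sep$assay, sep$labels, small_config())
  perm <- withr::with_seed(14, setNames(sample(unname(sep$labels)),
                                        names(sep$labels)))
  weak <- run_repeated_cv(sep$assay, perm, small_config())
  expect_gt(mean(strong$confidence), mean(weak$confidence) + 0.1)
})

test_that("patient accuracy is the fraction of correct votes", {
  expect_equal(patient_accuracy(rep("a", 10), "a"), 1)
  expect_equal(patient_accuracy(c(rep("a", 30), rep("b", 20)), "a"), 0.6)
  expect_equal(patient_accuracy(rep("b", 4), "a"), 0)
})

test_that("the frozen ensemble stores r*k models reproducing the CV votes", {
  sep <- make_separable_assay(n = 16, m = 8, delta = 2, seed = 15)
  cfg <- small_config(repeats = 4, folds = 2)
  ens <- train_full_ensemble(sep$assay, sep$labels, cfg)
  expect_length(ens$models, 8)
  expect_length(train_full_ensemble(sep$assay, sep$labels,
                                    small_config(repeats = 1))$models, 2)

  cv <- run_repeated_cv(sep$assay, sep$labels, cfg)
  for (m in ens$models) {
    held <- m$heldout
    pred <- predict_dlda(m$model,
                         sep$assay$matrix[held, m$model$features,
                                          drop = FALSE])
    for (i in seq_along(held)) {
      votes <- cv$votes[[match(held[i], cv$sample)]]
      expect_identical(pred[i], votes[m$repeat_index])
    }
  }
})

test_that("applying a frozen ensemble to its own cohort recovers the majorities", {
  sep <- make_separable_assay(n = 20, m = 8, delta = 6, seed = 16)
  cfg <- small_config(repeats = 4)
  ens <- train_full_ensemble(sep$assay, sep$labels, cfg)
  ext <- apply_ensemble(ens, sep$assay, truth = sep$labels)
  expect_true(all(ext$n_votes == 8))
  cv <- run_repeated_cv(sep$assay, sep$labels, cfg)
  expect_identical(ext$majority, cv$majority[match(ext$sample, cv$sample)])

  one <- sep$assay$matrix[1, , drop = FALSE]
  expect_equal(nrow(apply_ensemble(ens, one)), 1)
  expect_true(all(apply_ensemble(ens, one)$n_votes == 8))

  needed <- unique(unlist(lapply(ens$models, function(m) m$model$features)))
  dropped <- setdiff(colnames(sep$assay$matrix), needed)[1]
  crippled <- sep$assay$matrix[, setdiff(colnames(sep$assay$matrix),
                                         needed[1])]
  expect_error(apply_ensemble(ens, crippled), needed[1])
})
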