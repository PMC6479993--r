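test_that("Kennard-Stone picks the extreme pair first, then maximin", {
  ks <- kennard_stone(matrix(c(0, 1, 10)), 2)
  expect_equal(sort(ks$selection_order[1:2]), c(1, 3))
  expect_equal(ks$calibration_indices, c(1, 3))
  expect_equal(ks$validation_indices, 2)

  # full selection covers everything, disjoint and exhaustive
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  ks2 <- kennard_stone(X, 20)
  expect_equal(sort(ks2$selection_order), 1:20)
  expect_length(ks2$validation_indices, 0)

  ks3 <- kennard_stone(X, 12)
  expect_length(intersect(ks3$calibration_indices,
                          ks3$validation_indices), 0)
  expect_equal(sort(c(ks3$calibration_indices, ks3$validation_indices)),
               1:20)
  expect_error(kennard_stone(X, 21), "between 2 and")
})

test_that("Kennard-Stone is deterministic and storage-order independent", {
  set.seed(8)
  X <- matrix(rnorm(60 * 4), 60, 4)  # continuous data: ties have measure 0
  ks <- kennard_stone(X, 40)
  expect_identical(kennard_stone(X, 40), ks)
  perm <- sample(60)
  ksp <- kennard_stone(X[perm, ], 40)
  expect_equal(sort(perm[ksp$calibration_indices]),
               ks$calibration_indices)
})

test_that("the 78-sample split yields 52 calibration and 26 validation", {
  set.seed(5)
  X <- matrix(rnorm(78 * 10), 78, 10)
  ks <- kennard_stone(X, 52)
  expect_length(ks$calibration_indices, 52)
  expect_length(ks$validation_indices, 26)
})

test_that("confusion matrices count, order and validate labels", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), classes = 1:2)
  expect_equal(as.vector(cm), c(1L, 0L, 1L, 2L))
  expect_equal(sum(cm), 4)
  expect_error(confusion_matrix(1:2, c(1, 9), classes = 1:2), "outside")

  # 8-class design with perfect predictions: diagonal of class sizes
  y <- rep(1:8, times = c(10, 10, 10, 10, 10, 10, 10, 8))
  cmp <- confusion_matrix(y, y, classes = 1:8)
  expect_equal(diag(cmp), c(`1` = 10L, `2` = 10L, `3` = 10L, `4` = 10L,
                            `5` = 10L, `6` = 10L, `7` = 10L, `8` = 8L))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)

  # everything predicted as class 1: one nonzero column
  cm1 <- confusion_matrix(y, rep(1, length(y)), classes = 1:8)
  expect_true(all(cm1[, -1] == 0))
})

test_that("per-class metrics match hand counts and identities", {
  cm <- matrix(c(3, 0, 1, 4), 2, 2,
               dimnames = list(true = 1:2, predicted = 1:2))
  met <- class_metrics(cm)
  r1 <- met$per_class[1, ]
  expect_equal(c(r1$TP, r1$FN, r1$TN, r1$FP), c(3, 1, 4, 0))
  expect_equal(r1$sensitivity, 0.75)
  expect_equal(r1$specificity, 1.0)
  expect_equal(r1$efficiency, 0.75)
  expect_equal(met$accuracy, 7 / 8)

  # geometric-mean variant
  met_g <- class_metrics(cm, efficiency = "geometric")
  expect_equal(met_g$per_class$efficiency[1], sqrt(0.75))

  # accuracy percentage convention: 24/26 prints as 92.31
  expect_equal(fusefinger:::accuracy_pct(24, 26), 92.31)

  # integer identities on a random confusion matrix
  set.seed(13)
  y <- sample(1:8, 78, replace = TRUE)
  yh <- ifelse(runif(78) < 0.7, y, sample(1:8, 78, replace = TRUE))
  cmr <- confusion_matrix(y, yh, classes = 1:8)
  mr <- class_metrics(cmr)$per_class
  n <- sum(cmr)
  expect_equal(mr$TP + mr$FN, unname(rowSums(cmr)))
  expect_true(all(mr$TP + mr$FP + mr$TN + mr$FN == n))
  # sensitivity * (TP + FN) = TP exactly
  expect_equal(mr$sensitivity * (mr$TP + mr$FN), mr$TP)
  # accuracy equals the class-size weighted mean sensitivity
  expect_equal(class_metrics(cmr)$accuracy,
               sum(mr$sensitivity * (mr$TP + mr$FN)) / n)
  expect_true(all(stats::na.omit(c(mr$sensitivity, mr$specificity,
                                   mr$efficiency)) >= 0))
  expect_true(all(stats::na.omit(c(mr$sensitivity, mr$specificity,
                                   mr$efficiency)) <= 1))
})

test_that("empty classes give NA metrics, not zero", {
  cm <- matrix(c(0, 0, 0, 5), 2, 2, dimnames = list(1:2, 1:2))
  met <- class_metrics(cm)
  expect_true(is.na(met$per_class$sensitivity[1]))
})

test_that("model comparison ranks and flags as specified", {
  reports <- data.frame(
    name = c("a", "b", "c", "d"),
    level = c("single", "single", "low", "mid"),
    part = c("inner", "epidermis", "inner", "inner"),
    val_acc = c(92.31, 92.31, 100, 96.15),
    Q2cum = c(0.70, 0.55, 0.79, 0.57))
  ranked <- compare_models(reports)
  expect_equal(ranked$name, c("c", "d", "a", "b"))
  # equal accuracy: higher Q2 ranks first
  expect_true(ranked$Q2cum[3] > ranked$Q2cum[4])
  flags <- attr(ranked, "flags")
  expect_true(flags[["fused_ge_single"]])
  expect_true(flags[["low_ge_mid"]])
  expect_true(flags[["inner_ge_epidermis"]])
  expect_error(compare_models(NULL), "empty comparison set")
})
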