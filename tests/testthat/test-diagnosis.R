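# two-stage grading, bespoke metrics, cross-validation drivers

grade_cohort <- function(seed, n_per = 12, p = 20, sep = 2.5) {
  set.seed(seed)
  n <- 5 * n_per
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  y <- rep(c("LR1", "LR2", "LR3", "LR4", "LR5"), each = n_per)
  X[, 1] <- X[, 1] + sep * (as.integer(grade_to_group(y)) - 2)  # group axis
  X[, 2] <- X[, 2] + sep * (y %in% c("LR2", "LR4"))             # within-group
  list(X = X, y = y)
}

test_that("two-stage training validates labels and routes predictions", {
  d <- grade_cohort(1)
  m <- train_two_stage(d$X, d$y, seed = 3)
  pr <- predict(m, d$X)
  # routing contract: the grade-group correspondence is structural
  expect_true(all((pr$final == "LR3") == (pr$stage1 == "intermediate")))
  expect_true(all((pr$final %in% c("LR1", "LR2")) == (pr$stage1 == "benign")))
  expect_true(all((pr$final %in% c("LR4", "LR5")) == (pr$stage1 == "malignant")))
  # deep forest on separable data: perfect resubstitution
  expect_equal(mean(pr$final == d$y), 1)

  m2 <- train_two_stage(d$X, d$y, seed = 3)
  expect_identical(predict(m2, d$X)$final, pr$final)

  yy <- d$y
  yy[3] <- NA
  expect_error(train_two_stage(d$X, yy), "unlabeled subject")
  sel <- d$y != "LR4"
  expect_error(train_two_stage(d$X[sel, ], d$y[sel]),
               "class missing for stage2_malignant")
  expect_error(predict(m, d$X[, 1:5]), "marker schema mismatch")
})

test_that("metrics implement the bespoke three-group definitions", {
  y <- rep(c("LR1", "LR3", "LR5"), c(38, 19, 38))
  cm <- compute_metrics(y, rep("LR5", 95))
  expect_equal(unname(cm$counts), c(38, 0, 57, 0))  # TP TN FP FN
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  expect_equal(cm$f1, 76 / 133)

  # one intermediate predicted malignant counts as a false positive
  pred <- y
  pred[39] <- "LR5"
  cm2 <- compute_metrics(y, pred)
  expect_equal(unname(cm2$counts["FP"]), 1)
  expect_equal(cm2$specificity, 38 / 39)

  cm3 <- compute_metrics(y, y)
  expect_equal(c(cm3$sensitivity, cm3$specificity, cm3$f1), c(1, 1, 1))
  expect_equal(unname(cm3$per_grade_accuracy[c("LR1", "LR3", "LR5")]), c(1, 1, 1))
  expect_true(all(rowSums(cm3$matrix) == c(38, 0, 19, 0, 38)))
  expect_error(compute_metrics(character(0), character(0)), "no subjects")
})

test_that("LOSO runs one fit set per subject and a perfect oracle scores 1", {
  d <- grade_cohort(2, n_per = 6)
  n <- nrow(d$X)
  # count stage-1 fits through a custom family; the oracle reads the grade
  # it smuggles in through a marker column
  fits <- 0L
  oracle <- list(
    fit = function(X, y, seed) { fits <<- fits + 1L; NULL },
    predict = function(model, X) {
      code <- round(X[, "f20"])
      c("LR1", "LR2", "LR3", "LR4", "LR5", "benign", "intermediate",
        "malignant")[code]
    })
  Xo <- d$X
  Xo[, "f20"] <- as.integer(factor(d$y, levels = c("LR1", "LR2", "LR3",
                                                   "LR4", "LR5")))
  rpt1 <- cross_validate(Xo, d$y, "loso", repeats = 1, family = oracle,
                         seed = 5, stages = 1L)
  expect_equal(fits, n)  # one 5-class fit per left-out subject
  expect_equal(rpt1$metrics$mean[rpt1$metrics$metric == "overall_accuracy"], 1)

  # perfect predictor: every metric 1 with zero spread over repeats
  rpt <- cross_validate(Xo, d$y, "loso", repeats = 3, family = oracle,
                        seed = 5, stages = 1L)
  expect_true(all(rpt$metrics$mean[1:4] == 1))
  expect_true(all(rpt$metrics$sd[1:4] == 0))
})

test_that("stratified folds preserve group proportions", {
  y <- rep(c("LR1", "LR2", "LR3", "LR4", "LR5"), each = 19)
  grp <- grade_to_group(y)
  for (sd in 1:20) {
    set.seed(sd)
    fold <- hepatocad:::stratified_folds(grp, 5)
    expect_equal(sort(unique(fold)), 1:5)
    for (f in 1:5) {
      # per-stratum assignment is balanced to +/-1, so every fold holds
      # 3 or 4 intermediate subjects and close to n/k subjects in total
      expect_gte(sum(grp[fold == f] == "intermediate"), 3)
      expect_true(abs(sum(grp[fold == f] == "benign") - 38 / 5) <= 1)
      expect_true(abs(sum(fold == f) - 19) <= 2)
    }
  }
  expect_error(hepatocad:::stratified_folds(grp[1:3], 10), "too many folds")
})

test_that("k-fold reports vary across repeats but are seed-deterministic", {
  d <- grade_cohort(3, n_per = 8)
  r1 <- cross_validate(d$X, d$y, "k5", repeats = 3, seed = 17)
  r2 <- cross_validate(d$X, d$y, "k5", repeats = 3, seed = 17)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$confusion, r2$confusion)
  # repeats use different partitions: per-repeat rows are not all equal
  expect_gt(nrow(unique(r1$per_repeat)), 1L)
})

test_that("test-fold labels never leak into training or selection", {
  d <- grade_cohort(4, n_per = 8)
  n <- nrow(d$X)
  test_idx <- c(1, 9, 17, 25, 33)
  train_idx <- setdiff(seq_len(n), test_idx)

  m <- train_two_stage(d$X[train_idx, ], d$y[train_idx], seed = 2)
  y_shuffled <- d$y
  y_shuffled[test_idx] <- sample(d$y[test_idx])
  m2 <- train_two_stage(d$X[train_idx, ], y_shuffled[train_idx], seed = 2)
  expect_identical(predict(m, d$X[test_idx, ])$final,
                   predict(m2, d$X[test_idx, ])$final)

  sel1 <- hepatocad:::apply_selection(d$X[train_idx, ], d$y[train_idx],
                                      list(method = "gini"), seed = 2)
  sel2 <- hepatocad:::apply_selection(d$X[train_idx, ], y_shuffled[train_idx],
                                      list(method = "gini"), seed = 2)
  expect_identical(sel1, sel2)
})

test_that("per-fold selection runs inside cross-validation", {
  d <- grade_cohort(5, n_per = 6)
  rpt <- cross_validate(d$X, d$y, "k5", repeats = 1,
                        selection = list(method = "forward", st = 0.05),
                        seed = 9)
  expect_s3_class(rpt, "eval_report")
  expect_true(all(rpt$metrics$mean[1:4] >= 0 & rpt$metrics$mean[1:4] <= 1))
})
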