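# Two-stage grading and its evaluation.
#
# Stage 1 separates benign (LR1-2) / intermediate (LR3) / malignant (LR4-5);
# stage 2 grades within the benign (LR1 vs LR2) and malignant (LR4 vs LR5)
# groups.  Stage-2 models are trained on the ground-truth subgroups and
# applied after stage-1 routing at inference.  Metrics follow the bespoke
# three-group definitions: TP are malignant subjects predicted malignant,
# TN benign predicted benign, FP benign-or-intermediate predicted
# malignant, FN malignant-or-intermediate predicted benign.

#' Train the two-stage grading model
#'
#' @param X numeric matrix, subjects x markers.
#' @param y grades (`"LR1"`..`"LR5"`), one per subject, no missing values.
#' @param family classifier family (see [fit_classifier()]).
#' @param hyper hyper-parameter overrides.
#' @param seed integer seed.
#' @param markers optional character vector restricting the marker subset
#'   (all three sub-models always share it).
#' @return object of class `two_stage_model`.
#' @export
train_two_stage <- function(X, y, family = "rf", hyper = list(), seed = 1L,
                            markers = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(y)) stop("unlabeled subject")
  if (!all(y %in% GRADES)) stop("unlabeled subject")
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  grp <- grade_to_group(y)
  if (!all(c("LR1", "LR2") %in% y))
    stop("unlabeled subject class missing for stage2_benign")
  if (!all(c("LR4", "LR5") %in% y))
    stop("unlabeled subject class missing for stage2_malignant")
  s1 <- fit_classifier(X, grp, family, hyper, seed)
  bsel <- y %in% c("LR1", "LR2")
  msel <- y %in% c("LR4", "LR5")
  s2b <- fit_classifier(X[bsel, , drop = FALSE],
                        factor(y[bsel], levels = c("LR1", "LR2")),
                        family, hyper, seed + 1L)
  s2m <- fit_classifier(X[msel, , drop = FALSE],
                        factor(y[msel], levels = c("LR4", "LR5")),
                        family, hyper, seed + 2L)
  structure(list(stage1 = s1, stage2_benign = s2b, stage2_malignant = s2m,
                 markers = colnames(X), family = if (is.list(family)) "custom" else family),
            class = "two_stage_model")
}

#' Predict grades with a two-stage model
#'
#' Stage 1 picks the group; intermediate maps directly to LR3, otherwise the
#' matching stage-2 model grades within the group.
#'
#' @param object a `two_stage_model`.
#' @param X marker matrix (or a single `marker_vector`).
#' @param ... unused.
#' @return data.frame of class `grade_prediction` with `study_id` (when
#'   available), `stage1` and `final`.
#' @export
predict.two_stage_model <- function(object, X, ...) {
  ids <- NULL
  if (inherits(X, "marker_vector")) {
    ids <- X$study_id
    X <- matrix(X$values, 1, dimnames = list(NULL, names(X$values)))
  }
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    if (!all(object$markers %in% colnames(X))) stop("marker schema mismatch")
    X <- X[, object$markers, drop = FALSE]
  } else if (ncol(X) != length(object$markers)) {
    stop("marker schema mismatch")
  }
  grp <- as.character(predict(object$stage1, X))
  final <- character(nrow(X))
  final[grp == "intermediate"] <- "LR3"
  if (any(grp == "benign"))
    final[grp == "benign"] <-
      as.character(predict(object$stage2_benign, X[grp == "benign", , drop = FALSE]))
  if (any(grp == "malignant"))
    final[grp == "malignant"] <-
      as.character(predict(object$stage2_malignant, X[grp == "malignant", , drop = FALSE]))
  out <- data.frame(stage1 = factor(grp, levels = GROUPS3),
                    final = factor(final, levels = GRADES),
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(study_id = ids, out)
  if (is.null(ids) && !is.null(rownames(X))) out$study_id <- rownames(X)
  class(out) <- c("grade_prediction", "data.frame")
  out
}

#' Confusion summary and diagnostic metrics
#'
#' Builds the 5x5 grade confusion matrix and the three-group sensitivity,
#' specificity and F1.  The three-group counts are: TP = malignant subjects
#' predicted malignant; TN = benign predicted benign; FP = benign and
#' intermediate subjects predicted malignant; FN = malignant and
#' intermediate subjects predicted benign.
#'
#' @param truth true grades (`"LR1"`..`"LR5"`).
#' @param pred predicted grades, or a `grade_prediction` frame.
#' @return object of class `confusion_summary`: `matrix` (5x5), `counts`
#'   (TP, TN, FP, FN), `sensitivity`, `specificity`, `f1`,
#'   `per_grade_accuracy`, `overall_accuracy`.
#' @export
compute_metrics <- function(truth, pred) {
  if (inherits(pred, "grade_prediction") || is.data.frame(pred))
    pred <- pred$final
  truth <- factor(as.character(truth), levels = GRADES)
  pred <- factor(as.character(pred), levels = GRADES)
  if (length(truth) == 0) stop("no subjects")
  stopifnot(length(truth) == length(pred))
  cm <- table(truth = truth, predicted = pred)
  tg <- grade_to_group(as.character(truth))
  pg <- grade_to_group(as.character(pred))
  TP <- sum(tg == "malignant" & pg == "malignant")
  TN <- sum(tg == "benign" & pg == "benign")
  FP <- sum(tg %in% c("benign", "intermediate") & pg == "malignant")
  FN <- sum(tg %in% c("malignant", "intermediate") & pg == "benign")
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  pga <- diag(cm) / pmax(rowSums(cm), 1)
  pga[rowSums(cm) == 0] <- NA_real_
  structure(list(matrix = cm,
                 counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
                 sensitivity = sens, specificity = spec, f1 = f1,
                 per_grade_accuracy = pga,
                 overall_accuracy = sum(diag(cm)) / length(truth)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  print(x$matrix)
  cat(sprintf("sensitivity %.3f  specificity %.3f  F1 %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$f1, x$overall_accuracy))
  invisible(x)
}

metric_row <- function(cs) {
  c(sensitivity = cs$sensitivity, specificity = cs$specificity, f1 = cs$f1,
    overall_accuracy = cs$overall_accuracy,
    setNames(as.vector(cs$per_grade_accuracy), paste0("acc_", GRADES)))
}

# stratified fold assignment by three-group label, proportions preserved
stratified_folds <- function(groups, k) {
  n <- length(groups)
  if (k > n) stop("too many folds")
  fold <- integer(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the two-stage model
#'
#' LOSO leaves one subject out per iteration (fold order fixed, classifier
#' seed varying across repeats); stratified k-fold draws random partitions
#' preserving the benign/intermediate/malignant proportions, re-randomized
#' each repeat.  Any marker selection is re-run inside each training fold,
#' so test subjects never influence the marker subset or the model.
#'
#' @param X marker matrix, subjects x markers.
#' @param y grades.
#' @param scheme `"loso"`, `"k10"` or `"k5"`.
#' @param repeats number of repetitions (default 10).
#' @param family classifier family.
#' @param hyper hyper-parameter overrides.
#' @param selection optional selection specification
#'   (`list(method = "forward"|"stepwise"|"gini", ...)`) re-run per fold,
#'   or a fixed `selection_result`.
#' @param seed master seed; fans out to fold assignment and classifier
#'   seeds.
#' @param stages 2 (default, the two-stage model) or 1 (single 5-class
#'   baseline).
#' @return object of class `eval_report`: `scheme`, `repeats`, `metrics`
#'   (mean and sd per metric), `per_repeat`, pooled `confusion`,
#'   `predictions` (last repeat), `seed`.
#' @export
cross_validate <- function(X, y, scheme = c("loso", "k10", "k5"),
                           repeats = 10L, family = "rf", hyper = list(),
                           selection = NULL, seed = 1L, stages = 2L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  grp <- grade_to_group(y)
  k <- switch(scheme, loso = n, k10 = 10L, k5 = 5L)
  if (k > n) stop("too many folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)

  per_repeat <- matrix(NA_real_, repeats, 9)
  pooled <- matrix(0L, 5, 5, dimnames = list(truth = GRADES, predicted = GRADES))
  last_pred <- NULL
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold <- if (scheme == "loso") seq_len(n) else stratified_folds(grp, k)
    pred <- character(n)
    for (f in sort(unique(fold))) {
      test <- which(fold == f)
      train <- which(fold != f)
      fseed <- (rep_seeds[r] + f) %% .Machine$integer.max
      sel <- apply_selection(X[train, , drop = FALSE], y[train], selection, fseed)
      pred[test] <- as.character(
        fit_and_predict(X[train, sel, drop = FALSE], y[train],
                        X[test, sel, drop = FALSE], family, hyper,
                        fseed, stages))
    }
    cs <- compute_metrics(y, pred)
    per_repeat[r, ] <- metric_row(cs)
    pooled <- pooled + unclass(cs$matrix)
    last_pred <- pred
  }
  colnames(per_repeat) <- names(metric_row(compute_metrics(y, y)))
  structure(list(scheme = scheme, repeats = repeats,
                 metrics = data.frame(
                   metric = colnames(per_repeat),
                   mean = colMeans(per_repeat),
                   sd = apply(per_repeat, 2, sd),
                   row.names = NULL),
                 per_repeat = per_repeat, confusion = pooled,
                 predictions = last_pred, seed = seed, family =
                   if (is.list(family)) "custom" else family,
                 stages = stages),
            class = "eval_report")
}

fit_and_predict <- function(Xtr, ytr, Xte, family, hyper, seed, stages) {
  if (stages == 2L) {
    m <- train_two_stage(Xtr, ytr, family, hyper, seed)
    predict(m, Xte)$final
  } else {
    m <- fit_classifier(Xtr, factor(ytr, levels = GRADES), family, hyper, seed)
    predict(m, Xte)
  }
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$scheme, ", ", x$repeats, " repeats, ",
      x$stages, "-stage ", x$family, "\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-16s %.4f +/- %.4f\n", m$metric[i], m$mean[i], m$sd[i]))
  invisible(x)
}

#' One-stage 5-class baseline
#'
#' The same evaluation with a single 5-class classifier, for the two-stage
#' versus one-stage comparison.
#'
#' @inheritParams cross_validate
#' @return an `eval_report`.
#' @export
one_stage_baseline <- function(X, y, scheme = "loso", repeats = 10L,
                               family = "rf", hyper = list(), seed = 1L) {
  cross_validate(X, y, scheme = scheme, repeats = repeats, family = family,
                 hyper = hyper, seed = seed, stages = 1L)
}

#' Side-by-side two-stage vs one-stage comparison
#'
#' @inheritParams cross_validate
#' @return list with `two_stage` and `one_stage` eval reports and their
#'   pooled confusion matrices.
#' @export
compare_stages <- function(X, y, scheme = "loso", repeats = 10L,
                           family = "rf", hyper = list(), seed = 1L) {
  two <- cross_validate(X, y, scheme, repeats, family, hyper, seed = seed,
                        stages = 2L)
  one <- cross_validate(X, y, scheme, repeats, family, hyper, seed = seed,
                        stages = 1L)
  list(two_stage = two, one_stage = one,
       confusion = list(two_stage = two$confusion, one_stage = one$confusion))
}
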