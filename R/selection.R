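# Marker-subset selection: greedy wrapper selection on an ordinal linear
# model (forward and bi-directional / stepwise variants, partial-F tests),
# and random-forest Gini-importance selection in combined and per-group
# modes.

selection_result <- function(selected, method, thresholds, trace, scores = NULL) {
  structure(list(selected = selected, method = method,
                 thresholds = thresholds, trace = trace, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$selected),
      " markers selected\n", sep = "")
  invisible(x)
}

# ordinal class code 0, 1, ... in level order
class_code <- function(y) {
  y <- if (is.factor(y)) y else factor(y)
  if (nlevels(y) < 2) stop("single class")
  as.double(as.integer(y) - 1L)
}

# Partial-F p-values for adding each candidate column to the model spanned
# by Q (orthonormal basis of [1, X_selected]).  Residualize candidates and
# the response against Q; the squared correlation of residuals gives the
# RSS drop.  Returns NA for (near-)constant or collinear candidates.
partial_f_pvalues <- function(Xc, Q, y, df2) {
  ry <- y - Q %*% crossprod(Q, y)
  R <- Xc - Q %*% crossprod(Q, Xc)
  ss <- colSums(R^2)
  rss0 <- sum(ry^2)
  num <- as.vector(crossprod(R, ry))^2 / ss
  rss1 <- rss0 - num
  Fst <- num / (rss1 / df2)
  p <- pf(Fst, 1, df2, lower.tail = FALSE)
  scale0 <- colSums(Xc^2) + 1e-30
  p[ss <= 1e-10 * scale0 | rss1 <= 0] <- NA
  p
}

#' Forward (greedy) marker selection
#'
#' Starting from the empty model, repeatedly adds the candidate marker with
#' the smallest partial-F p-value in an ordinary least-squares model of the
#' ordinal class code, stopping when no candidate reaches `st`.  Ties are
#' broken by schema (column) order; constant columns are skipped with a
#' warning.
#'
#' @param X numeric matrix, studies x markers (named columns).
#' @param y class labels (factor or character), at least 2 classes.
#' @param st significance threshold for entry (the conventional choices are
#'   0.05 and 0.10).
#' @return a `selection_result`; `selected` is ordered by entry.
#' @export
forward_select <- function(X, y, st = 0.05) {
  X <- as.matrix(X)
  yc <- class_code(y)
  n <- nrow(X)
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("skipping constant marker columns: ",
            paste(colnames(X)[const], collapse = ", "))
  avail <- which(!const)
  sel <- integer(0)
  trace <- list()
  Q <- matrix(1 / sqrt(n), n, 1)
  repeat {
    df2 <- n - length(sel) - 2L
    if (length(avail) == 0 || df2 < 1) break
    p <- partial_f_pvalues(X[, avail, drop = FALSE], Q, yc, df2)
    if (all(is.na(p)) || min(p, na.rm = TRUE) >= st) break
    k <- which.min(p)  # first minimum = schema order tie-break
    trace[[length(trace) + 1]] <- data.frame(
      step = length(sel) + 1L, marker = colnames(X)[avail[k]],
      p_value = p[k], action = "add", stringsAsFactors = FALSE)
    sel <- c(sel, avail[k])
    avail <- avail[-k]
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
  }
  selection_result(colnames(X)[sel], "forward", c(st = st),
                   do.call(rbind, trace))
}

#' Bi-directional (stepwise) marker selection
#'
#' Forward entry as in [forward_select()], followed after every entry by a
#' backward check: any included marker whose drop-one partial-F p-value in
#' the current model is at least `st_remove` is eliminated (worst first).
#' Iterates to a fixed point, with a cycle guard on repeated marker sets.
#'
#' @inheritParams forward_select
#' @param st_enter entry threshold.
#' @param st_remove removal threshold (default equal to `st_enter`).
#' @return a `selection_result`.
#' @export
stepwise_select <- function(X, y, st_enter = 0.05, st_remove = st_enter) {
  X <- as.matrix(X)
  yc <- class_code(y)
  n <- nrow(X)
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("skipping constant marker columns: ",
            paste(colnames(X)[const], collapse = ", "))
  sel <- integer(0)
  trace <- list()
  seen <- character(0)
  note <- function(marker, p, action) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1L, marker = marker, p_value = p,
      action = action, stringsAsFactors = FALSE)
  }
  repeat {
    avail <- setdiff(which(!const), sel)
    df2 <- n - length(sel) - 2L
    if (length(avail) == 0 || df2 < 1) break
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    p <- partial_f_pvalues(X[, avail, drop = FALSE], Q, yc, df2)
    if (all(is.na(p)) || min(p, na.rm = TRUE) >= st_enter) break
    k <- which.min(p)
    note(colnames(X)[avail[k]], p[k], "add")
    sel <- c(sel, avail[k])
    # backward sweep: drop included markers no longer significant
    repeat {
      if (length(sel) < 2) break
      df2b <- n - length(sel) - 1L
      if (df2b < 1) break
      pin <- vapply(seq_along(sel), function(j) {
        others <- sel[-j]
        Qo <- qr.Q(qr(cbind(1, X[, others, drop = FALSE])))
        partial_f_pvalues(X[, sel[j], drop = FALSE], Qo, yc, df2b)
      }, 0)
      worst <- which.max(pin)
      if (is.na(pin[worst]) || pin[worst] < st_remove) break
      note(colnames(X)[sel[worst]], pin[worst], "remove")
      sel <- sel[-worst]
    }
    state <- paste(sort(sel), collapse = ",")
    if (state %in% seen) break
    seen <- c(seen, state)
  }
  selection_result(colnames(X)[sel], "stepwise",
                   c(st_enter = st_enter, st_remove = st_remove),
                   do.call(rbind, trace))
}

#' Gini-importance marker selection
#'
#' Fits a random forest (the default classification hyper-parameters of this
#' package: 100 trees, balanced class weights, gini criterion, max depth 30,
#' min samples leaf 5, min samples split 2) and keeps every marker whose
#' normalized mean-decrease-in-impurity importance exceeds the mean
#' importance.  In `separate` mode the rule is applied within each marker
#' group and the survivors are pooled.
#'
#' @inheritParams forward_select
#' @param mode `"combined"` (rank all markers jointly) or `"separate"`
#'   (within each group of `groups`).
#' @param seed integer seed for the forest.
#' @param groups character vector mapping each column of `X` to a marker
#'   group; required for `mode = "separate"`.  Defaults to the standard
#'   schema groups when `X` has the full 249-marker schema.
#' @param hyper optional random-forest hyper-parameter overrides.
#' @return a `selection_result` with the normalized importances in `scores`
#'   (they sum to 1 in combined mode).
#' @export
gini_select <- function(X, y, mode = c("combined", "separate"), seed = 1L,
                        groups = NULL, hyper = list()) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) stop("single class")
  if (mode == "combined") {
    fit <- fit_classifier(X, y, family = "rf", hyper = hyper, seed = seed)
    imp <- setNames(fit$model$importance, colnames(X))
    keep <- imp > mean(imp)
    return(selection_result(colnames(X)[keep], "gini_combined",
                            c(cutoff = mean(imp)), trace = NULL, scores = imp))
  }
  if (is.null(groups)) {
    sc <- marker_schema()
    if (!all(colnames(X) %in% sc$name))
      stop("groups must be given for non-standard marker sets")
    groups <- sc$group[match(colnames(X), sc$name)]
  }
  stopifnot(length(groups) == ncol(X))
  keep <- character(0)
  scores <- numeric(0)
  for (gname in unique(groups)) {
    cols <- which(groups == gname)
    fit <- fit_classifier(X[, cols, drop = FALSE], y, family = "rf",
                          hyper = hyper, seed = seed)
    imp <- setNames(fit$model$importance, colnames(X)[cols])
    keep <- c(keep, names(imp)[imp > mean(imp)])
    scores <- c(scores, imp)
  }
  keep <- colnames(X)[colnames(X) %in% keep]  # schema order
  selection_result(keep, "gini_separate", c(cutoff = NA), trace = NULL,
                   scores = scores)
}

# selection specification used inside cross-validation folds
apply_selection <- function(X, y, spec, seed) {
  if (is.null(spec)) return(colnames(X))
  if (inherits(spec, "selection_result")) return(spec$selected)
  method <- spec$method
  res <- switch(method,
    forward = forward_select(X, y, st = spec$st %||% 0.05),
    stepwise = stepwise_select(X, y, st_enter = spec$st %||% 0.05,
                               st_remove = spec$st_remove %||% spec$st %||% 0.05),
    gini = gini_select(X, y, mode = spec$mode %||% "combined", seed = seed,
                       groups = spec$groups),
    stop("unknown selection method: ", method))
  res$selected
}

`%||%` <- function(a, b) if (is.null(a)) b else a
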