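# Classifier families behind one fit/predict interface.
#
# The default family is the random forest (implemented in src/forest.cpp):
# 100 gini trees, balanced class weights, max depth 30, min samples leaf 5,
# min samples split 2, mtry = floor(sqrt(p)).  Alternatives: fine kNN
# (5 neighbours, Euclidean, uniform weights), polynomial-kernel SVM solved
# as a dual QP (one-vs-one; cubic or quadratic kernel, C = 1,
# gamma = 0.001), Gaussian naive Bayes, and shrinkage LDA (pooled
# covariance shrunk toward its average eigenvalue, s = 0.52).  A custom
# family may be supplied as `list(fit = function(X, y, seed),
# predict = function(model, X))`.

rf_default_hyper <- function(p) {
  list(ntree = 100L, mtry = max(1L, floor(sqrt(p))), max_depth = 30L,
       min_split = 2L, min_leaf = 5L, class_weight = "balanced")
}

#' Fit a classifier
#'
#' @param X numeric matrix, subjects x markers.
#' @param y factor of class labels.
#' @param family one of `"rf"`, `"knn"`, `"svm_cubic"`, `"svm_quad"`,
#'   `"nb"`, `"lda"`, or a `list(fit=, predict=)` pair.
#' @param hyper named list of hyper-parameter overrides.
#' @param seed integer seed (used by the forest; other families are
#'   deterministic).
#' @return object of class `cad_classifier`.
#' @export
fit_classifier <- function(X, y, family = "rf", hyper = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  stopifnot(nrow(X) == length(y))
  lev <- levels(y)
  K <- length(lev)
  if (is.list(family)) {
    model <- family$fit(X, y, seed)
    return(structure(list(family = "custom", model = model, levels = lev,
                          predict_fun = family$predict, markers = colnames(X)),
                     class = "cad_classifier"))
  }
  model <- switch(family,
    rf = {
      h <- deep_merge(rf_default_hyper(ncol(X)), hyper)
      cw <- if (identical(h$class_weight, "balanced")) {
        cnt <- tabulate(as.integer(y), K)
        length(y) / (K * cnt)
      } else rep(1, K)
      rf_fit_cpp(X, as.integer(y) - 1L, K, as.integer(h$ntree),
                 as.integer(h$mtry), as.integer(h$max_depth),
                 as.integer(h$min_split), as.integer(h$min_leaf),
                 cw, as.integer(seed))
    },
    knn = list(X = X, y = as.integer(y), k = hyper$k %||% 5L),
    svm_cubic = svm_ovo_fit(X, y, degree = 3, C = hyper$C %||% 1,
                            gamma = hyper$gamma %||% 0.001),
    svm_quad = svm_ovo_fit(X, y, degree = 2, C = hyper$C %||% 1,
                           gamma = hyper$gamma %||% 0.001),
    nb = gnb_fit(X, y),
    lda = slda_fit(X, y, shrinkage = hyper$shrinkage %||% 0.52),
    stop("unknown classifier"))
  structure(list(family = family, model = model, levels = lev,
                 markers = colnames(X)),
            class = "cad_classifier")
}

#' Predict class labels
#'
#' @param object a fitted `cad_classifier`.
#' @param X numeric matrix with the same marker columns as at training.
#' @param ... unused.
#' @return factor of predicted labels (training levels).
#' @export
predict.cad_classifier <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(object$markers) && !is.null(colnames(X))) {
    if (!all(object$markers %in% colnames(X))) stop("marker schema mismatch")
    X <- X[, object$markers, drop = FALSE]
  } else if (!is.null(object$markers) && ncol(X) != length(object$markers)) {
    stop("marker schema mismatch")
  }
  lev <- object$levels
  cls <- switch(object$family,
    custom = return(factor(as.character(object$predict_fun(object$model, X)),
                           levels = lev)),
    rf = max.col(rf_predict_cpp(object$model, X), ties.method = "first"),
    knn = {
      m <- object$model
      idx <- FNN::get.knnx(m$X, X, k = min(m$k, nrow(m$X)))$nn.index
      apply(idx, 1, function(ii) {
        v <- tabulate(m$y[ii], nbins = length(lev))
        which.max(v)  # deterministic tie-break: lowest class index
      })
    },
    svm_cubic = svm_ovo_predict(object$model, X),
    svm_quad = svm_ovo_predict(object$model, X),
    nb = gnb_predict(object$model, X),
    lda = slda_predict(object$model, X))
  factor(lev[cls], levels = lev)
}

# ---- Gaussian naive Bayes -------------------------------------------------

gnb_fit <- function(X, y) {
  K <- nlevels(y)
  mu <- s2 <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    Xk <- X[as.integer(y) == k, , drop = FALSE]
    mu[k, ] <- colMeans(Xk)
    s2[k, ] <- apply(Xk, 2, function(v) mean((v - mean(v))^2))
  }
  eps <- 1e-9 * max(apply(X, 2, var), 1e-12)
  list(mu = mu, s2 = s2 + eps, logprior = log(tabulate(as.integer(y), K) / length(y)))
}

gnb_predict <- function(m, X) {
  K <- nrow(m$mu)
  ll <- sapply(seq_len(K), function(k) {
    -0.5 * rowSums(sweep(X, 2, m$mu[k, ])^2 / rep(m$s2[k, ], each = nrow(X)) +
                     rep(log(2 * pi * m$s2[k, ]), each = nrow(X))) + m$logprior[k]
  })
  max.col(matrix(ll, nrow(X), K), ties.method = "first")
}

# ---- shrinkage LDA --------------------------------------------------------

slda_fit <- function(X, y, shrinkage = 0.52) {
  K <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  mu <- matrix(0, K, p)
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    Xk <- X[as.integer(y) == k, , drop = FALSE]
    mu[k, ] <- colMeans(Xk)
    C <- sweep(Xk, 2, mu[k, ])
    S <- S + crossprod(C)
  }
  S <- S / n  # pooled empirical within-class covariance
  Ssh <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / p) * diag(p)
  W <- solve(Ssh, t(mu))                       # p x K
  b <- -0.5 * colSums(t(mu) * W) + log(tabulate(as.integer(y), K) / n)
  list(W = W, b = b)
}

slda_predict <- function(m, X) {
  sc <- X %*% m$W + rep(m$b, each = nrow(X))
  max.col(sc, ties.method = "first")
}

# ---- polynomial-kernel SVM (dual QP, one-vs-one) --------------------------

poly_kernel <- function(A, B, gamma, degree) (gamma * tcrossprod(A, B))^degree

svm_binary_fit <- function(X, ys, C, gamma, degree) {
  # ys in {-1, +1}; dual soft-margin QP solved with quadprog
  n <- length(ys)
  Km <- poly_kernel(X, X, gamma, degree)
  D <- (ys %o% ys) * Km
  D <- D + diag(1e-8 * max(diag(D), 1), n)
  A <- cbind(ys, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-8
  on_margin <- sv & alpha < C - 1e-8
  f0 <- as.vector(Km %*% (alpha * ys))
  rho <- if (any(on_margin)) mean(ys[on_margin] - f0[on_margin])
         else mean(ys[sv] - f0[sv])
  list(X = X[sv, , drop = FALSE], ay = (alpha * ys)[sv], rho = rho,
       gamma = gamma, degree = degree)
}

svm_binary_decision <- function(m, X) {
  as.vector(poly_kernel(X, m$X, m$gamma, m$degree) %*% m$ay) + m$rho
}

svm_ovo_fit <- function(X, y, degree, C, gamma) {
  K <- nlevels(y)
  fits <- list()
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    sel <- as.integer(y) %in% c(a, b)
    ys <- ifelse(as.integer(y)[sel] == a, 1, -1)
    fits[[length(fits) + 1]] <- c(svm_binary_fit(X[sel, , drop = FALSE], ys,
                                                 C, gamma, degree),
                                  list(pos = a, neg = b))
  }
  list(fits = fits, K = K)
}

svm_ovo_predict <- function(m, X) {
  votes <- matrix(0, nrow(X), m$K)
  for (f in m$fits) {
    d <- svm_binary_decision(f, X)
    votes[, f$pos] <- votes[, f$pos] + (d >= 0)
    votes[, f$neg] <- votes[, f$neg] + (d < 0)
  }
  max.col(votes, ties.method = "first")
}
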