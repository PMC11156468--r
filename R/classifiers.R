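# Minimal two-class classifiers used by the decoding module: shrinkage
# LDA, a linear SVM (Pegasos subgradient), and bagged CART trees. All take
# a numeric feature matrix and a two-level factor, and return objects with
# a predict() method yielding class labels.

#' Fit a two-class linear discriminant with diagonal shrinkage
#'
#' Pooled-covariance LDA. The pooled covariance is shrunk toward its
#' diagonal, `S' = (1 - lambda) S + lambda diag(S)`, with
#' `lambda = min(0.9, max(0.1, p/n))` so the estimator stays well
#' conditioned when units approach or exceed trials; a small ridge is added
#' for numerical safety.
#'
#' @param x Numeric matrix (trials x features).
#' @param y Two-level factor (or coercible).
#' @param lambda Optional shrinkage override in [0, 1].
#' @return An object of class `xm_lda`.
#' @export
fit_lda <- function(x, y, lambda = NULL) {
  y <- factor(y)
  if (nlevels(y) != 2L) structural_error("LDA requires exactly two classes")
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  lambda <- lambda %||% min(0.9, max(0.1, p / n))
  lv <- levels(y)
  m0 <- colMeans(x[y == lv[1], , drop = FALSE])
  m1 <- colMeans(x[y == lv[2], , drop = FALSE])
  xc <- x
  xc[y == lv[1], ] <- sweep(x[y == lv[1], , drop = FALSE], 2, m0)
  xc[y == lv[2], ] <- sweep(x[y == lv[2], , drop = FALSE], 2, m1)
  S <- crossprod(xc) / max(1L, n - 2L)
  S <- (1 - lambda) * S + lambda * diag(diag(S), p)
  diag(S) <- diag(S) + 1e-8 * mean(diag(S)) + 1e-12
  w <- solve(S, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2 + log(mean(y == lv[2]) / mean(y == lv[1]))
  structure(list(w = w, b = b, levels = lv), class = "xm_lda")
}

#' @export
predict.xm_lda <- function(object, newdata, type = "class", ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  if (type == "score") return(drop(s))
  factor(object$levels[(s > 0) + 1L], levels = object$levels)
}

#' Fit a linear support vector machine (Pegasos)
#'
#' Primal subgradient descent on the hinge loss with L2 regularization.
#' Features are standardized internally.
#'
#' @param x Numeric matrix (trials x features).
#' @param y Two-level factor.
#' @param lambda Regularization strength (default 0.01).
#' @param epochs Passes over the data (default 30).
#' @param seed Integer seed for the sampling order.
#' @return An object of class `xm_svm`.
#' @export
fit_svm <- function(x, y, lambda = 0.01, epochs = 30L, seed = NULL) {
  y <- factor(y)
  if (nlevels(y) != 2L) structural_error("SVM requires exactly two classes")
  x <- as.matrix(x)
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd); sd[sd == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  yy <- ifelse(y == levels(y)[2], 1, -1)
  n <- nrow(xs); p <- ncol(xs)
  w <- numeric(p); b <- 0; t <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t)
        marg <- yy[i] * (sum(w * xs[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (marg < 1) {
          w <- w + eta * yy[i] * xs[i, ]
          b <- b + eta * yy[i]
        }
      }
    }
  })
  structure(list(w = w, b = b, mu = mu, sd = sd, levels = levels(y)),
            class = "xm_svm")
}

#' @export
predict.xm_svm <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, "/")
  s <- xs %*% object$w + object$b
  factor(object$levels[(s > 0) + 1L], levels = object$levels)
}

# --- Bagged CART ("random forest" in the TreeBagger sense) ---------------

gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

grow_tree <- function(x, y, depth, mtry, min_n = 5L) {
  n <- length(y)
  tab <- tabulate(y, 2L)
  if (depth == 0L || n < min_n || any(tab == 0L))
    return(list(leaf = TRUE, class = which.max(tab)))
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_gain <- 1e-12
  parent <- gini(tab)
  for (f in feats) {
    v <- x[, f]
    cuts <- unique(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.2),
                                   names = FALSE))
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      g <- parent - (nl * gini(tabulate(y[left], 2L)) +
                       (n - nl) * gini(tabulate(y[!left], 2L))) / n
      if (g > best_gain) {
        best_gain <- g
        best <- list(f = f, cut = cut, left = left)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = which.max(tab)))
  list(leaf = FALSE, f = best$f, cut = best$cut,
       l = grow_tree(x[best$left, , drop = FALSE], y[best$left],
                     depth - 1L, mtry, min_n),
       r = grow_tree(x[!best$left, , drop = FALSE], y[!best$left],
                     depth - 1L, mtry, min_n))
}

predict_tree <- function(tree, x) {
  out <- integer(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- x[idx, node$f] <= node$cut
    rec(node$l, idx[left]); rec(node$r, idx[!left])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

#' Fit a bagged classification-tree ensemble
#'
#' Bootstrap-aggregated CART trees with `mtry = ceiling(sqrt(p))` features
#' per split, majority vote at prediction. The 500-tree default matches the
#' tree count used for the reference Random-Forests decoding.
#'
#' @param x Numeric matrix (trials x features).
#' @param y Two-level factor.
#' @param n_trees Number of trees (default 500).
#' @param max_depth Maximum tree depth (default 5).
#' @param seed Integer seed.
#' @return An object of class `xm_bagged_trees`.
#' @export
fit_bagged_trees <- function(x, y, n_trees = 500L, max_depth = 5L,
                             seed = NULL) {
  y <- factor(y)
  if (nlevels(y) != 2L)
    structural_error("bagged trees require exactly two classes")
  x <- as.matrix(x)
  yi <- as.integer(y)
  mtry <- ceiling(sqrt(ncol(x)))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], yi[idx], max_depth, mtry)
  }))
  structure(list(trees = trees, levels = levels(y)),
            class = "xm_bagged_trees")
}

#' @export
predict.xm_bagged_trees <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  votes <- matrix(0L, nrow(x), 2L)
  for (tr in object$trees) {
    p <- predict_tree(tr, x)
    votes[cbind(seq_len(nrow(x)), p)] <- votes[cbind(seq_len(nrow(x)), p)] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
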