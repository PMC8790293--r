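#' Train a linear maximum-margin (soft-margin) classifier
#'
#' Solves the soft-margin primal `min 1/2 ||w||^2 + C * sum(xi)` subject to
#' `y_i (w'x_i + b) >= 1 - xi_i` through its dual, using a deterministic
#' SMO (sequential minimal optimization) solver: at each step the maximal
#' KKT-violating pair is updated (ties broken by lowest index), and
#' iteration stops when the duality-gap surrogate `m(alpha) - M(alpha)`
#' falls below `tol`. On linearly separable data with large `C` the
#' hard-margin solution is recovered, with geometric margin `2 / ||w||`.
#'
#' Features are standardized (training mean/sd per feature) before fitting
#' by default; the standardization parameters are stored in the model and
#' applied to new data by [decision_values()].
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y labels in `{-1, +1}` (or a factor with `tumor` as positive).
#' @param C soft-margin penalty (> 0); large values approach hard margin.
#' @param standardize center/scale features using the training data.
#' @param tol KKT tolerance for convergence.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return Object of class `SVMModel`: `w`, `b` (on the standardized scale),
#'   `C`, `feature_names`, `center`, `scale`, `margin` (= `2 / ||w||`),
#'   `support` (indices with alpha > 0), `alpha`, `iterations`.
#' @export
train_svm <- function(x, y, C = 1, standardize = TRUE, tol = 1e-6,
                      max_iter = 200000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- as_pm1(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2) stop("need at least one sample per class")
  if (C <= 0) stop("'C' must be positive")

  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  fit <- smo_linear(xs, y, C, tol, max_iter)

  structure(
    list(w = setNames(fit$w, colnames(x)), b = fit$b, C = C,
         feature_names = colnames(x), center = setNames(ctr, colnames(x)),
         scale = setNames(scl, colnames(x)),
         margin = 2 / sqrt(sum(fit$w^2)),
         support = which(fit$alpha > 1e-8), alpha = fit$alpha,
         iterations = fit$iterations),
    class = "SVMModel"
  )
}

as_pm1 <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("tumor", "normal"))) {
      stop("labels must be numeric +/-1 or 'tumor'/'normal'")
    }
    return(ifelse(y == "tumor", 1, -1))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1 or +1")
  y
}

# Deterministic maximal-violating-pair SMO for the linear-kernel SVM dual:
#   min_alpha 1/2 a'Q a - sum(a),  0 <= a <= C,  sum(a * y) = 0,
# with Q_ij = y_i y_j x_i'x_j. The weight vector w = X' (alpha * y) is
# maintained incrementally so each iteration costs one n x d matvec.
smo_linear <- function(x, y, C, tol = 1e-6, max_iter = 200000L) {
  n <- nrow(x)
  alpha <- numeric(n)
  w <- numeric(ncol(x))
  xsq <- rowSums(x^2)
  it <- 0L
  repeat {
    f <- drop(x %*% w)            # w'x_i
    opt <- y - f                  # -y_i * grad_i  (= y_i - w'x_i)
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(opt[up])]
    j <- which(lo)[which.min(opt[lo])]
    gap <- opt[i] - opt[j]
    if (gap < tol) break
    it <- it + 1L
    if (it > max_iter) {
      stop("SMO failed to converge within ", max_iter,
           " iterations (KKT gap ", format(gap), ")")
    }
    quad <- xsq[i] + xsq[j] - 2 * sum(x[i, ] * x[j, ])
    if (quad <= 1e-12) quad <- 1e-12
    t_step <- gap / quad
    t_max_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] < 0) C - alpha[j] else alpha[j]
    t_step <- min(t_step, t_max_i, t_max_j)
    # d alpha_i = y_i t, d alpha_j = -y_j t keeps sum(alpha * y) fixed
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    alpha[i] <- min(max(alpha[i], 0), C)
    alpha[j] <- min(max(alpha[j], 0), C)
    w <- w + t_step * (x[i, ] - x[j, ])
  }
  f <- drop(x %*% w)
  opt <- y - f
  up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
  lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
  m_up <- if (any(up)) max(opt[up]) else -Inf
  m_lo <- if (any(lo)) min(opt[lo]) else Inf
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(opt[free]) else mean(c(m_up, m_lo)[is.finite(c(m_up, m_lo))])
  list(w = w, b = b, alpha = alpha, iterations = it)
}

#' Decision scores and class predictions from a fitted model
#'
#' `decision_values()` returns `w' x_std + b` for each row after applying the
#' model's stored standardization; `predict()` thresholds at zero, assigning
#' a score of exactly zero to the positive (tumor) class.
#'
#' @param model an `SVMModel`.
#' @param x numeric matrix with the model's features in columns (matched by
#'   name when available, else by position).
#' @return Numeric score vector, or a `+/-1` integer vector for `predict`.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "SVMModel"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$w)) {
    stop("feature count mismatch: model has ", length(model$w),
         ", data has ", ncol(x))
  }
  if (!is.null(colnames(x)) && !is.null(model$feature_names)) {
    if (!all(model$feature_names %in% colnames(x))) {
      stop("data is missing model features: ",
           paste(setdiff(model$feature_names, colnames(x)), collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(xs %*% model$w) + model$b
}

#' @rdname decision_values
#' @param object an `SVMModel` (predict method).
#' @param ... unused.
#' @export
predict.SVMModel <- function(object, x, ...) {
  s <- decision_values(object, x)
  ifelse(s >= 0, 1L, -1L)
}

#' @export
print.SVMModel <- function(x, ...) {
  cat(sprintf(
    "Linear SVM: %d features, C = %g, margin 2/||w|| = %.4g, %d support vectors\n",
    length(x$w), x$C, x$margin, length(x$support)
  ))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model an `SVMModel`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "SVMModel"))
  jsonlite::write_json(
    list(w = as.numeric(model$w), b = model$b, C = model$C,
         feature_names = model$feature_names,
         center = as.numeric(model$center), scale = as.numeric(model$scale),
         margin = model$margin),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
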