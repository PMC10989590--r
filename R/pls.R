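#' Cross-validation configuration for latent-variable selection
#'
#' @param folds Integer number of CV folds (>= 2).
#' @param lv_grid Integer vector of candidate latent-variable counts.
#'   Default 1 to 20. Candidates infeasible for a given training fold
#'   (`a > min(m_fold - 1, n)`) are dropped automatically.
#' @param seed Integer seed controlling the shuffled fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 5L, lv_grid = 1:20, seed = 1L) {
  folds <- as.integer(folds)
  lv_grid <- sort(unique(as.integer(lv_grid)))
  check(folds >= 2L, "folds must be >= 2")
  check(length(lv_grid) >= 1L && all(lv_grid >= 1L),
        "lv_grid must contain positive integers")
  structure(list(folds = folds, lv_grid = lv_grid, seed = as.integer(seed)),
            class = "cv_config")
}

# scaling vectors: center always; scale = sd (or 1 for zero-variance columns)
.x_scaling <- function(X, scaling) {
  ctr <- colMeans(X)
  if (scaling == "autoscale") {
    s <- apply(X, 2, stats::sd)
    s[!is.finite(s) | s < .Machine$double.eps^0.5] <- 1
  } else {
    s <- rep(1, ncol(X))
  }
  list(center = ctr, scale = s)
}

#' Fit a univariate-response PLS regression model (NIPALS)
#'
#' Extracts `a` latent variables sequentially: per component the weight
#' vector is `w = X'y / ||X'y||`, scores `t = Xw`, x-loading
#' `p = X't/(t't)`, y-loading `q = y't/(t't)`, followed by deflation of
#' both `X` and `y`. Columns are mean-centered and, under `autoscale`,
#' divided by their standard deviation; zero-variance columns (which the
#' transfer-learning design guarantees to exist) are centered but given
#' scale 1. The model stores its preprocessing vectors so prediction is
#' self-contained.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Numeric response vector.
#' @param a Number of latent variables; must satisfy
#'   `a <= min(nrow(X) - 1, ncol(X))`. If the response is fully deflated
#'   earlier, extraction stops and the model keeps fewer components (with a
#'   warning).
#' @param scaling `"autoscale"` (center + unit variance, the chemometrics
#'   default assumed by the VIP derivation) or `"center"`.
#' @return An object of class `pls_model` with elements `W`, `P`, `q`, `T`
#'   (training scores), `a`, and the centering/scaling vectors.
#' @export
fit_pls <- function(X, y, a, scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  n <- ncol(X)
  check(length(y) == m, "length(y) must equal nrow(X)")
  check(m >= 2L, "need at least 2 samples")
  a <- as.integer(a)
  check(a >= 1L && a <= min(m - 1L, n),
        "a must satisfy 1 <= a <= min(m - 1, n) = %d", min(m - 1L, n))

  xs <- .x_scaling(X, scaling)
  y_center <- mean(y)
  y_scale <- if (scaling == "autoscale") stats::sd(y) else 1
  if (scaling == "autoscale") {
    check(is.finite(y_scale) && y_scale > .Machine$double.eps^0.5,
          "y is constant; cannot autoscale")
  }
  Xd <- sweep(sweep(X, 2, xs$center), 2, xs$scale, "/")
  check(any(abs(Xd) > 0), "all-constant X")
  yd <- (y - y_center) / y_scale

  W <- matrix(0, n, a)
  P <- matrix(0, n, a)
  Tm <- matrix(0, m, a)
  q <- numeric(a)
  used <- 0L
  for (j in seq_len(a)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning(sprintf("response fully deflated after %d components", used))
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xd, t)) / tt
    qj <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - t * qj
    W[, j] <- w
    P[, j] <- p
    Tm[, j] <- t
    q[j] <- qj
    used <- j
  }
  if (used < a) {
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]
    q <- q[seq_len(used)]
  }
  structure(
    list(x_center = xs$center, x_scale = xs$scale,
         y_center = y_center, y_scale = y_scale,
         W = W, P = P, q = q, T = Tm, a = used, scaling = scaling),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d wavenumber columns (%s)\n",
              x$a, nrow(x$W), x$scaling))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Applies the stored centering/scaling, accumulates the score-times-
#' y-loading contributions of each latent variable via successive
#' deflation, and back-transforms to the response scale.
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with the same number of columns the model
#'   was trained on. Zero rows give an empty prediction.
#' @param ncomp Number of components to use, default all (`object$a`).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$a, ...) {
  X <- as.matrix(newdata)
  check(ncol(X) == nrow(object$W),
        "newdata has %d columns; model expects %d", ncol(X), nrow(object$W))
  check(ncomp >= 1L && ncomp <= object$a, "ncomp out of range")
  if (nrow(X) == 0L) return(numeric(0))
  Xd <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  yd <- numeric(nrow(X))
  for (j in seq_len(ncomp)) {
    t <- drop(Xd %*% object$W[, j])
    yd <- yd + t * object$q[j]
    Xd <- Xd - tcrossprod(t, object$P[, j])
  }
  yd * object$y_scale + object$y_center
}

#' @export
fitted.pls_model <- function(object, ...) {
  drop(object$T %*% object$q) * object$y_scale + object$y_center
}

#' Regression coefficients of a PLS model
#'
#' Collapses the latent-variable model to a single linear predictor
#' `y = b0 + X b` on the original (unscaled) variables, using
#' `b = W (P'W)^{-1} q`.
#'
#' @param object A `pls_model`.
#' @param ... Unused.
#' @return Named vector: intercept followed by one coefficient per column.
#' @export
coef.pls_model <- function(object, ...) {
  b_scaled <- object$W %*% solve(crossprod(object$P, object$W), object$q)
  b <- drop(b_scaled) * object$y_scale / object$x_scale
  b0 <- object$y_center - sum(b * object$x_center)
  c(intercept = b0, stats::setNames(b, rownames(object$W)))
}

# fold assignment: shuffled, sizes as equal as possible
.cv_folds <- function(m, folds, seed) {
  idx <- with_seed(seed, sample.int(m))
  split(idx, rep_len(seq_len(folds), m))
}

#' Choose the number of latent variables by cross-validation
#'
#' For each candidate component count `a` in the grid, computes the
#' cross-validated coefficient of determination
#' `r2_cv = 1 - sum((y - yhat_cv)^2) / sum((y - mean(y))^2)` with the
#' centering/scaling re-estimated inside every training fold, and returns
#' the candidate maximizing it (smallest `a` on ties). One model with the
#' maximal candidate count is fitted per fold; smaller counts are evaluated
#' from its leading components.
#'
#' @param X Numeric matrix.
#' @param y Numeric response.
#' @param cv A [cv_config()].
#' @param scaling Passed to [fit_pls()].
#' @return List with `a` (the selected count) and `r2cv` (named vector of
#'   the cross-validated r-squared per candidate).
#' @export
optimize_lv <- function(X, y, cv = cv_config(), scaling = "autoscale") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  check(inherits(cv, "cv_config"), "cv must be a cv_config")
  check(cv$folds <= m, "more folds than samples")
  folds <- .cv_folds(m, cv$folds, cv$seed)
  check(all(lengths(folds) >= 1L) && all(m - lengths(folds) >= 2L),
        "a training fold has fewer than 2 samples")

  a_max_feasible <- min(vapply(folds, function(f) m - length(f) - 1L,
                               integer(1)), ncol(X))
  grid <- cv$lv_grid[cv$lv_grid <= a_max_feasible]
  check(length(grid) >= 1L,
        "no feasible latent-variable count in lv_grid (max feasible %d)",
        a_max_feasible)
  a_top <- max(grid)

  press_by_a <- numeric(a_top)
  for (f in folds) {
    fit <- suppressWarnings(
      fit_pls(X[-f, , drop = FALSE], y[-f], a = a_top, scaling = scaling))
    Xd <- sweep(sweep(X[f, , drop = FALSE], 2, fit$x_center),
                2, fit$x_scale, "/")
    yd <- numeric(length(f))
    for (j in seq_len(fit$a)) {
      t <- drop(Xd %*% fit$W[, j])
      yd <- yd + t * fit$q[j]
      Xd <- Xd - tcrossprod(t, fit$P[, j])
      yhat <- yd * fit$y_scale + fit$y_center
      press_by_a[j] <- press_by_a[j] + sum((y[f] - yhat)^2)
    }
    if (fit$a < a_top) {
      # response exhausted early: later counts predict like the last one
      yhat <- yd * fit$y_scale + fit$y_center
      extra <- sum((y[f] - yhat)^2)
      press_by_a[(fit$a + 1L):a_top] <-
        press_by_a[(fit$a + 1L):a_top] + extra
    }
  }
  tss <- sum((y - mean(y))^2)
  r2cv <- 1 - press_by_a[grid] / tss
  names(r2cv) <- grid
  list(a = grid[which.max(r2cv)], r2cv = r2cv)
}

#' Variable importance in projection (VIP)
#'
#' Per-variable importance summarizing the weighted contribution of each
#' predictor across the latent variables:
#' `VIP_i = sqrt( n * sum_j SS_j (w_ij / ||w_j||)^2 / sum_j SS_j )` with
#' `SS_j = q_j^2 t_j't_j`, the response variance explained by component
#' `j`. Under this square-root convention `sum_i VIP_i^2 = n`, so values
#' above 1 mark predictors that are more important than average. Setting
#' `sqrt = FALSE` returns the squared variant; it orders variables
#' identically.
#'
#' @param model A fitted `pls_model`.
#' @param sqrt Logical; apply the square root (default `TRUE`).
#' @return Numeric vector of length `ncol(X)` of non-negative scores.
#' @export
vip <- function(model, sqrt = TRUE) {
  check(inherits(model, "pls_model"), "model must be a pls_model")
  ss <- model$q^2 * colSums(model$T^2)             # SS_j = q_j^2 t_j' t_j
  total <- sum(ss)
  check(total > 0, "no explained variance (constant response?)")
  n <- nrow(model$W)
  # ||w_j|| = 1 by construction, kept explicit for clarity
  wnorm2 <- colSums(model$W^2)
  v2 <- n * drop(model$W^2 %*% (ss / wnorm2)) / total
  if (sqrt) base::sqrt(v2) else v2
}

#' Prediction metrics: coefficient of determination and RMSE
#'
#' @param y_true Observed values (length >= 2, not constant).
#' @param y_pred Predicted values, same length.
#' @param r2_type `"cod"` (default): `1 - SSE/SST`, which can be negative
#'   for predictions worse than the mean; `"pearson"`: squared Pearson
#'   correlation.
#' @return List with `r2` and `rmse`.
#' @export
prediction_metrics <- function(y_true, y_pred, r2_type = c("cod", "pearson")) {
  r2_type <- match.arg(r2_type)
  check(length(y_true) == length(y_pred), "length mismatch")
  check(length(y_true) >= 2L, "need at least 2 values")
  check(stats::sd(y_true) > 0, "y_true is constant")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r2 <- if (r2_type == "cod") {
    1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  } else {
    stats::cor(y_true, y_pred)^2
  }
  list(r2 = r2, rmse = rmse)
}
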