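test_that("a single component fits an exact rank-1 relationship", {
  x <- matrix(c(-2, -1, 0, 1, 2), ncol = 1)
  y <- 2 * x[, 1]
  f <- fit_pls(x, y, a = 1)
  expect_equal(fitted(f), y, tolerance = 1e-10)
  expect_equal(predict(f, x), y, tolerance = 1e-10)
})

test_that("PLS with full rank matches ordinary least squares", {
  for (seed in 1:5) {
    with_seed_local(seed, {
      X <- matrix(rnorm(15), 5, 3)
      y <- rnorm(5)
    })
    f <- fit_pls(X, y, a = 3)
    ols <- unname(stats::lm.fit(cbind(1, X), y)$fitted.values)
    expect_equal(predict(f, X), ols, tolerance = 1e-8)
    # collapsed coefficients agree with the OLS solution too
    b <- coef(f)
    expect_equal(unname(b[1] + X %*% b[-1])[, 1], ols, tolerance = 1e-8)
  }
})

test_that("prediction at the column-mean point returns the mean response", {
  with_seed_local(2, {
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
  })
  f <- fit_pls(X, y, a = 2)
  expect_equal(predict(f, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
})

test_that("predict handles empty input and dimension mismatch", {
  f <- fit_pls(matrix(rnorm(20), 5, 4), rnorm(5), a = 2)
  expect_identical(predict(f, matrix(0, 0, 4)), numeric(0))
  expect_error(predict(f, matrix(0, 1, 3)), "columns")
})

test_that("duplicated columns leave predictions unchanged", {
  with_seed_local(3, {
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
    Xn <- matrix(rnorm(20), 4, 5)
  })
  a <- 3
  p_plain <- predict(fit_pls(X, y, a), Xn)
  p_dup <- predict(fit_pls(cbind(X, X), y, a), cbind(Xn, Xn))
  expect_equal(p_dup, p_plain, tolerance = 1e-8)
})

test_that("weights are unit norm and scores mutually orthogonal", {
  for (seed in 1:10) {
    with_seed_local(seed, {
      m <- sample(8:25, 1); n <- sample(3:30, 1)
      X <- matrix(rnorm(m * n), m, n)
      y <- rnorm(m)
    })
    f <- fit_pls(X, y, a = min(m - 1, n, 5))
    expect_equal(colSums(f$W^2), rep(1, f$a), tolerance = 1e-10)
    G <- crossprod(f$T)
    off <- G - diag(diag(G), f$a)
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  }
})

test_that("zero-variance columns are centered with scale one", {
  X <- cbind(rnorm(8), rep(4, 8))
  f <- fit_pls(X, rnorm(8), a = 1)
  expect_equal(f$x_scale[2], 1)
  expect_equal(f$x_center[2], 4)
})

test_that("optimize_lv returns the single candidate and honours the grid", {
  with_seed_local(4, {
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
  })
  res <- optimize_lv(X, y, cv_config(folds = 3, lv_grid = 1))
  expect_equal(res$a, 1L)
  expect_named(res$r2cv, "1")
})

test_that("optimize_lv recovers a known intrinsic dimension of two", {
  with_seed_local(11, {
    m <- 40
    t1 <- rnorm(m); t2 <- rnorm(m)
    load <- matrix(rnorm(12), 2, 6)
  })
  X <- cbind(t1, t2) %*% load         # rank-2 design
  y <- t1 + 0.5 * t2                  # noiseless, needs both directions
  res <- optimize_lv(X, y, cv_config(folds = 5, lv_grid = 1:4, seed = 1))
  expect_equal(res$a, 2L)
})

test_that("optimize_lv is deterministic for a fixed configuration", {
  with_seed_local(6, {
    X <- matrix(rnorm(200), 20, 10)
    y <- rnorm(20)
  })
  cv <- cv_config(folds = 4, lv_grid = 1:5, seed = 9)
  expect_identical(optimize_lv(X, y, cv), optimize_lv(X, y, cv))
})

test_that("VIP satisfies its normalization and single-component reduction", {
  for (seed in 1:10) {
    with_seed_local(seed, {
      m <- sample(10:30, 1); n <- sample(4:25, 1)
      X <- matrix(rnorm(m * n), m, n)
      y <- rnorm(m)
    })
    a <- min(m - 1, n, sample(1:4, 1))
    f <- fit_pls(X, y, a = a)
    v <- vip(f)
    expect_equal(sum(v^2), n, tolerance = 1e-8 * n)
    expect_true(all(v >= 0))
  }
  f1 <- fit_pls(matrix(rnorm(40), 10, 4), rnorm(10), a = 1)
  expect_equal(vip(f1), sqrt(4) * abs(f1$W[, 1]), tolerance = 1e-10)
})

test_that("VIP matches an independent term-by-term summation", {
  with_seed_local(12, {
    X <- matrix(rnorm(24), 6, 4)
    y <- rnorm(6)
  })
  f <- fit_pls(X, y, a = 2)
  # brute-force oracle: explicit loops over variables and components
  n <- ncol(X)
  ss <- vapply(seq_len(f$a), function(j) {
    f$q[j]^2 * sum(f$T[, j] * f$T[, j])
  }, numeric(1))
  expected <- vapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(f$a)) {
      num <- num + ss[j] * (f$W[i, j] / sqrt(sum(f$W[, j]^2)))^2
    }
    sqrt(n * num / sum(ss))
  }, numeric(1))
  expect_equal(vip(f), expected, tolerance = 1e-8)
  # squared variant is the same ordering
  expect_equal(order(vip(f, sqrt = FALSE)), order(vip(f)))
})

test_that("NIPALS predictions and VIP agree with an independent PLS code", {
  skip_if_not_installed("mixOmics")
  with_seed_local(7, {
    X <- matrix(rnorm(80), 16, 5)
    y <- drop(X %*% c(1, -2, 0.5, 0, 0)) + rnorm(16, sd = 0.2)
    Xn <- matrix(rnorm(25), 5, 5)
  })
  colnames(X) <- colnames(Xn) <- paste0("x", 1:5)
  f <- fit_pls(X, y, a = 3)
  mo <- mixOmics::pls(X, matrix(y, dimnames = list(NULL, "y")),
                      ncomp = 3, scale = TRUE, mode = "regression")
  expect_equal(predict(f, Xn),
               unname(drop(predict(mo, Xn)$predict[, , 3])),
               tolerance = 1e-10)
  expect_equal(unname(vip(f)), unname(mixOmics::vip(mo)[, 3]),
               tolerance = 1e-10)
})

test_that("prediction metrics match hand-computed values", {
  expect_equal(prediction_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(r2 = 1, rmse = 0))
  y <- c(0, 1, 2)
  expect_equal(prediction_metrics(y, rep(mean(y), 3))$r2, 0)
  m <- prediction_metrics(c(0, 1, 2), c(0, 1, 5))
  expect_equal(m$rmse, sqrt(3))
  expect_error(prediction_metrics(1:3, 1:2), "mismatch")
  expect_error(prediction_metrics(c(1, 1), c(1, 2)), "constant")
  # squared-Pearson alternative ignores calibration offset
  expect_equal(prediction_metrics(y, y + 10, r2_type = "pearson")$r2, 1)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_pls(matrix(rnorm(10), 5, 2), rnorm(5), a = 5), "a must")
  expect_error(fit_pls(matrix(1, 5, 2), rep(2, 5), a = 1), "constant")
})
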