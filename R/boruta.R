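#' Configuration for the shadow-feature selection engine
#'
#' @param p Percentile (in `(0, 100]`) of the shadow importances used as
#'   the hit threshold. The default 100 uses the maximum shadow importance.
#' @param alpha Significance level of the per-feature two-tailed binomial
#'   test. Default 0.05.
#' @param max_iter Maximum number of shuffle/score iterations (default
#'   100).
#' @param seed Integer seed for the shadow permutations.
#' @param tentative_policy `"exclude"` (default): only confirmed features
#'   are selected; `"include"`: features still tentative at termination are
#'   selected too.
#' @param correction `"none"` (default, a plain per-feature test) or
#'   `"bonferroni"` (alpha divided by the number of features still under
#'   test).
#' @return An object of class `boruta_config`.
#' @export
boruta_config <- function(p = 100, alpha = 0.05, max_iter = 100L, seed = 1L,
                          tentative_policy = c("exclude", "include"),
                          correction = c("none", "bonferroni")) {
  check(p > 0 && p <= 100, "p must be in (0, 100]")
  check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  check(max_iter >= 1L, "at least one iteration required")
  structure(list(p = p, alpha = alpha, max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 tentative_policy = match.arg(tentative_policy),
                 correction = match.arg(correction)),
            class = "boruta_config")
}

#' Shadow copy of a design matrix
#'
#' Permutes every column independently, destroying any association with the
#' response while preserving each column's marginal distribution exactly.
#'
#' @param X Numeric matrix with at least 2 rows.
#' @param seed Optional seed; `NULL` (default) draws from the current RNG
#'   stream.
#' @return Matrix of the same shape; column `c` is a random permutation of
#'   column `c` of `X`.
#' @export
make_shadow <- function(X, seed = NULL) {
  X <- as.matrix(X)
  check(nrow(X) >= 2L && ncol(X) >= 1L, "empty matrix")
  with_seed(seed, {
    apply(X, 2, function(col) col[sample.int(length(col))])
  })
}

#' Binomial decision for one feature
#'
#' Tests the accumulated hit count against the null that a feature beats
#' the shadow threshold with probability 1/2, using an exact two-tailed
#' binomial test (doubled one-tailed tail probability, capped at 1). A
#' significant upper tail confirms the feature, a significant lower tail
#' rejects it, otherwise it stays tentative.
#'
#' @param hits Number of hits, `0 <= hits <= trials`.
#' @param trials Number of iterations so far (>= 1).
#' @param alpha Significance level.
#' @return One of `"confirmed"`, `"rejected"`, `"tentative"`.
#' @export
boruta_decide <- function(hits, trials, alpha = 0.05) {
  check(trials >= 1L, "trials must be >= 1")
  check(hits >= 0L && hits <= trials, "hits must be in [0, trials]")
  p_up <- min(1, 2 * stats::pbinom(hits - 1, trials, 0.5, lower.tail = FALSE))
  p_dn <- min(1, 2 * stats::pbinom(hits, trials, 0.5))
  if (p_up < alpha && hits > trials / 2) return("confirmed")
  if (p_dn < alpha && hits < trials / 2) return("rejected")
  "tentative"
}

#' All-relevant feature selection with shadow features
#'
#' Each iteration: (1) every column of the active design matrix is copied
#' and independently permuted ("shadow features", unrelated to `y` by
#' construction); (2) the provider scores the importance of all original
#' and shadow columns together; (3) the threshold is the `p`-percentile of
#' the shadow importances; (4) active originals strictly above the
#' threshold receive a hit; (5) each feature still under test is re-judged
#' by [boruta_decide()]. Rejected features leave the active set and accrue
#' no further hits; confirmed and rejected states are final. Iteration
#' stops when no feature remains tentative or after `max_iter` rounds.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Numeric response.
#' @param provider Importance function `(X_combined, y) -> numeric`, one
#'   finite non-negative value per column of `X_combined`, larger = more
#'   important. See [vip_importance_provider()] and
#'   [rf_importance_provider()].
#' @param cfg A [boruta_config()].
#' @return List with `selected` (integer indices into the columns of `X`)
#'   and `state`, a `boruta_state` object carrying `hits`, `trials` and the
#'   per-feature `status`.
#' @export
run_boruta <- function(X, y, provider, cfg = boruta_config()) {
  X <- as.matrix(X)
  n <- ncol(X)
  check(n >= 1L, "X must have at least one column")
  check(is.function(provider), "provider must be a function")
  check(inherits(cfg, "boruta_config"), "cfg must be a boruta_config")

  hits <- integer(n)
  status <- rep("tentative", n)
  trials <- 0L
  with_seed(cfg$seed, {
    while (trials < cfg$max_iter && any(status == "tentative")) {
      trials <- trials + 1L
      active <- which(status != "rejected")
      k <- length(active)
      Xa <- X[, active, drop = FALSE]
      Xs <- make_shadow(Xa)
      imp <- provider(cbind(Xa, Xs), y)
      check(length(imp) == 2L * k,
            "provider returned %d importances for %d columns",
            length(imp), 2L * k)
      check(all(is.finite(imp)), "provider returned non-finite importances")
      thr <- stats::quantile(imp[(k + 1L):(2L * k)], cfg$p / 100,
                             names = FALSE, type = 7)
      hit <- imp[seq_len(k)] > thr
      hits[active] <- hits[active] + hit

      under_test <- which(status == "tentative")
      alpha <- if (cfg$correction == "bonferroni") {
        cfg$alpha / length(under_test)
      } else {
        cfg$alpha
      }
      for (i in under_test) {
        status[i] <- boruta_decide(hits[i], trials, alpha)
      }
    }
  })
  state <- structure(list(hits = hits, trials = trials, status = status),
                     class = "boruta_state")
  keep <- c("confirmed",
            if (cfg$tentative_policy == "include") "tentative")
  list(selected = which(status %in% keep), state = state)
}

#' @export
print.boruta_state <- function(x, ...) {
  tab <- table(factor(x$status, c("confirmed", "tentative", "rejected")))
  cat(sprintf(
    "<boruta_state> %d trials: %d confirmed, %d tentative, %d rejected\n",
    x$trials, tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]]))
  invisible(x)
}

#' PLS-VIP importance provider
#'
#' Builds a provider that, for each combined original+shadow matrix,
#' optimizes the latent-variable count by cross-validated r-squared, fits a
#' PLS model and returns the VIP score of every column. With
#' `reuse_lv = TRUE` the latent-variable count is optimized on the first
#' call only and reused afterwards (a faster approximation useful for
#' experimentation; the default re-optimizes every iteration).
#'
#' @param cv A [cv_config()] used for the per-call latent-variable search.
#' @param scaling Passed to [fit_pls()].
#' @param reuse_lv Logical, default `FALSE`.
#' @return A function `(X, y) -> numeric` usable with [run_boruta()].
#' @export
vip_importance_provider <- function(cv = cv_config(), scaling = "autoscale",
                                    reuse_lv = FALSE) {
  cached_a <- NULL
  function(X, y) {
    a <- if (isTRUE(reuse_lv) && !is.null(cached_a)) {
      min(cached_a, min(nrow(X) - 1L, ncol(X)))
    } else {
      a_opt <- optimize_lv(X, y, cv = cv, scaling = scaling)$a
      if (isTRUE(reuse_lv)) cached_a <<- a_opt
      a_opt
    }
    model <- suppressWarnings(fit_pls(X, y, a = a, scaling = scaling))
    vip(model)
  }
}

#' Random-forest importance provider
#'
#' Builds a provider returning the impurity-based variable importance
#' (total decrease in node residual sum of squares) of a random-forest
#' regressor fitted on the combined original+shadow matrix. Negative
#' importances (possible for pure-noise columns) are clipped at zero to
#' satisfy the provider contract.
#'
#' @param n_trees Number of trees (default 500).
#' @param seed Seed applied before every forest fit, making repeated calls
#'   on the same data identical.
#' @return A function `(X, y) -> numeric` usable with [run_boruta()].
#' @export
rf_importance_provider <- function(n_trees = 500L, seed = 1L) {
  check(n_trees >= 1L, "n_trees must be >= 1")
  function(X, y) {
    fit <- with_seed(seed, {
      randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                 importance = FALSE)
    })
    pmax(drop(fit$importance[, "IncNodePurity"]), 0)
  }
}
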