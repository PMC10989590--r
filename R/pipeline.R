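#' Run one calibration method end-to-end and evaluate on test data
#'
#' Fits the requested variant with [nir_calibration()] and evaluates it on
#' held-out culture test samples, returning a one-row evaluation report.
#'
#' @param method One of [nir_methods()].
#' @param analyte Target name.
#' @param train,test Culture `spectra_dataset`s (raw; preprocessing is
#'   governed by `sg`).
#' @param pseudo Optional pseudo-media `spectra_dataset`.
#' @param sg,cv,boruta,rf_trees,scaling,reuse_lv Passed to
#'   [nir_calibration()].
#' @param r2_type Passed to [prediction_metrics()].
#' @return List of class `eval_report`: `method`, `analyte`, `n_lv`, `r2`,
#'   `rmse`, `n_selected`, `ranges` (data frame of per-block selected
#'   ranges), `runtime` (seconds) and `fit` (the fitted model).
#' @export
run_method <- function(method, analyte, train, test, pseudo = NULL,
                       sg = sg_params(), cv = cv_config(),
                       boruta = boruta_config(), rf_trees = 500L,
                       scaling = "autoscale", reuse_lv = FALSE,
                       r2_type = "cod") {
  t0 <- proc.time()[["elapsed"]]
  fit <- nir_calibration(train, analyte, method = method, pseudo = pseudo,
                         sg = sg, cv = cv, boruta = boruta,
                         rf_trees = rf_trees, scaling = scaling,
                         reuse_lv = reuse_lv)
  yhat <- predict(fit, test)
  m <- prediction_metrics(test$targets[[analyte]], yhat, r2_type = r2_type)
  structure(
    list(method = method, analyte = analyte, n_lv = fit$model$a,
         r2 = m$r2, rmse = m$rmse, n_selected = length(fit$selected),
         ranges = selected_ranges(fit),
         runtime = proc.time()[["elapsed"]] - t0, fit = fit),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s: %d LVs, r2 = %.3f, RMSE = %.3f\n",
              x$method, x$analyte, x$n_lv, x$r2, x$rmse))
  invisible(x)
}

#' Compare calibration methods on one analyte
#'
#' Runs all applicable method variants with shared configuration: the
#' three culture-only methods always, plus the four pseudo-media methods
#' when a pseudo dataset is supplied. Reports a summary table (one row per
#' method: latent-variable count, test r-squared, test RMSE) and the
#' selected-wavenumber ranges per method and block.
#'
#' @inheritParams run_method
#' @param methods Methods to run; default all applicable ones.
#' @return List of class `method_comparison` with `table` (data frame),
#'   `ranges` (data frame: method, block, lo, hi) and `reports` (named
#'   list of `eval_report`s).
#' @export
run_comparison <- function(analyte, train, test, pseudo = NULL,
                           methods = NULL, sg = sg_params(),
                           cv = cv_config(), boruta = boruta_config(),
                           rf_trees = 500L, scaling = "autoscale",
                           reuse_lv = FALSE, r2_type = "cod") {
  culture_only <- c("pls", "pls+boruta", "pls+vip-boruta")
  with_pseudo <- c("pls-pooled", "pls+tl", "pls+tl+boruta",
                   "pls+tl+vip-boruta")
  if (is.null(methods)) {
    methods <- c(culture_only, if (!is.null(pseudo)) with_pseudo)
  }
  bad <- setdiff(methods, nir_methods())
  check(length(bad) == 0L, "unknown method '%s'; valid: %s",
        paste(bad, collapse = ", "), paste(nir_methods(), collapse = ", "))

  reports <- lapply(methods, function(mth) {
    run_method(mth, analyte, train, test, pseudo = pseudo, sg = sg,
               cv = cv, boruta = boruta, rf_trees = rf_trees,
               scaling = scaling, reuse_lv = reuse_lv, r2_type = r2_type)
  })
  names(reports) <- methods
  tab <- data.frame(
    method = methods,
    n_lv = vapply(reports, `[[`, integer(1), "n_lv"),
    r2 = vapply(reports, `[[`, numeric(1), "r2"),
    rmse = vapply(reports, `[[`, numeric(1), "rmse"),
    n_selected = vapply(reports, `[[`, integer(1), "n_selected"),
    runtime = vapply(reports, `[[`, numeric(1), "runtime"),
    row.names = NULL)
  ranges <- do.call(rbind, lapply(methods, function(mth) {
    r <- reports[[mth]]$ranges
    if (is.null(r) || nrow(r) == 0L) return(NULL)
    cbind(method = mth, r)
  }))
  structure(list(analyte = analyte, table = tab, ranges = ranges,
                 reports = reports),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison for %s (test-set metrics)\n", x$analyte))
  tab <- x$table
  tab$r2 <- sprintf("%.3f", tab$r2)
  tab$rmse <- sprintf("%.3f", tab$rmse)
  tab$runtime <- sprintf("%.1fs", tab$runtime)
  print(tab, row.names = FALSE)
  invisible(x)
}
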