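#' Method variants
#'
#' The seven calibration strategies the package compares. `pls` uses the
#' culture training samples only; `pls+boruta` and `pls+vip-boruta` add
#' shadow-feature wavelength selection (random-forest and PLS-VIP
#' importance respectively); `pls-pooled` row-concatenates culture and
#' pseudo samples into one plain PLS model; the `tl` variants build the
#' three-block transfer-learning design from culture and pseudo samples,
#' optionally with selection run on the augmented columns.
#'
#' @return Character vector of valid method names.
#' @export
nir_methods <- function() {
  c("pls", "pls+boruta", "pls+vip-boruta", "pls-pooled",
    "pls+tl", "pls+tl+boruta", "pls+tl+vip-boruta")
}

#' Fit an NIR calibration model
#'
#' One entry point for all method variants: optional Savitzky-Golay
#' derivative preprocessing, optional transfer-learning design
#' augmentation, optional shadow-feature wavelength selection, latent-
#' variable count optimization by cross-validation, and a final PLS fit.
#' The returned object is self-contained: [predict.nir_calibration()]
#' applies the same preprocessing, design mapping and column subset to raw
#' new spectra.
#'
#' @param train `spectra_dataset` of culture training samples.
#' @param analyte Name of the target, e.g. `"glucose"`.
#' @param method One of [nir_methods()].
#' @param pseudo `spectra_dataset` of pseudo-media samples; required for
#'   the pooled and `tl` variants.
#' @param sg [sg_params()] applied to every dataset before modelling, or
#'   `NULL` if the data are already preprocessed.
#' @param cv [cv_config()] for the latent-variable search.
#' @param boruta [boruta_config()] for the selection variants.
#' @param rf_trees Trees for the random-forest importance provider.
#' @param scaling Passed to [fit_pls()].
#' @param reuse_lv Passed to [vip_importance_provider()].
#' @return An object of class `nir_calibration`.
#' @export
nir_calibration <- function(train, analyte, method = "pls", pseudo = NULL,
                            sg = sg_params(), cv = cv_config(),
                            boruta = boruta_config(), rf_trees = 500L,
                            scaling = "autoscale", reuse_lv = FALSE) {
  check(method %in% nir_methods(), "unknown method '%s'; valid: %s",
        method, paste(nir_methods(), collapse = ", "))
  validate_spectra_dataset(train)
  check(analyte %in% names(train$targets),
        "analyte '%s' missing from training targets", analyte)
  uses_pseudo <- method %in% c("pls-pooled", "pls+tl", "pls+tl+boruta",
                               "pls+tl+vip-boruta")
  check(!uses_pseudo || !is.null(pseudo),
        "method '%s' requires a pseudo dataset", method)
  t0 <- proc.time()[["elapsed"]]

  if (!is.null(sg)) {
    train <- savitzky_golay(train, sg)
    if (!is.null(pseudo)) pseudo <- savitzky_golay(pseudo, sg)
  }
  n <- length(train$wavenumbers)
  uses_tl <- grepl("tl", method, fixed = TRUE)

  if (uses_tl) {
    design <- tl_training_design(train, pseudo, analyte)
    X <- design$X_C
    y <- design$y_C
  } else if (method == "pls-pooled") {
    check(analyte %in% names(pseudo$targets),
          "analyte '%s' missing from pseudo targets", analyte)
    X <- rbind(train$absorbance, pseudo$absorbance)
    y <- c(train$targets[[analyte]], pseudo$targets[[analyte]])
    design <- NULL
  } else {
    X <- train$absorbance
    y <- train$targets[[analyte]]
    design <- NULL
  }

  sel_state <- NULL
  selected <- seq_len(ncol(X))
  if (grepl("boruta", method, fixed = TRUE)) {
    provider <- if (grepl("vip-boruta", method, fixed = TRUE)) {
      vip_importance_provider(cv = cv, scaling = scaling,
                              reuse_lv = reuse_lv)
    } else {
      rf_importance_provider(n_trees = rf_trees, seed = boruta$seed)
    }
    res <- run_boruta(X, y, provider, boruta)
    check(length(res$selected) >= 1L,
          "selection rejected every wavenumber; nothing left to model")
    selected <- res$selected
    sel_state <- res$state
  }

  Xs <- X[, selected, drop = FALSE]
  opt <- optimize_lv(Xs, y, cv = cv, scaling = scaling)
  model <- suppressWarnings(fit_pls(Xs, y, a = opt$a, scaling = scaling))

  structure(
    list(analyte = analyte, method = method, model = model,
         selected = selected, selection_state = sel_state,
         wavenumbers = train$wavenumbers, n = n, uses_tl = uses_tl,
         sg = sg, cv = cv, r2cv = opt$r2cv,
         fitted_on = list(y = y),
         runtime = proc.time()[["elapsed"]] - t0),
    class = "nir_calibration")
}

# raw spectra dataset/matrix -> the design columns the model was fitted on
.model_design <- function(object, newdata) {
  if (inherits(newdata, "spectra_dataset")) {
    if (!is.null(object$sg)) newdata <- savitzky_golay(newdata, object$sg)
    X <- newdata$absorbance
  } else {
    X <- as.matrix(newdata)
  }
  check(ncol(X) == object$n, "newdata has %d wavenumbers; model expects %d",
        ncol(X), object$n)
  if (object$uses_tl) X <- tl_prediction_design(X, object$n)
  X[, object$selected, drop = FALSE]
}

#' Predict concentrations from an NIR calibration model
#'
#' @param object An `nir_calibration`.
#' @param newdata A `spectra_dataset` of raw culture spectra (the stored
#'   Savitzky-Golay parameters are applied) or a numeric matrix of already
#'   preprocessed spectra with one column per wavenumber.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (g/L).
#' @export
predict.nir_calibration <- function(object, newdata, ...) {
  predict(object$model, .model_design(object, newdata))
}

#' Selected wavenumbers of a calibration model
#'
#' @param object An `nir_calibration`.
#' @return Data frame with columns `block` (always 1 for non-TL methods)
#'   and `wavenumber` (cm^-1), one row per selected design column.
#' @export
selected_wavenumbers <- function(object) {
  check(inherits(object, "nir_calibration"), "not an nir_calibration")
  if (object$uses_tl) {
    per_block <- tl_map_selection(object$selected, object$n)
    do.call(rbind, lapply(1:3, function(b) {
      idx <- per_block[[b]]
      if (!length(idx)) return(NULL)
      data.frame(block = b, wavenumber = object$wavenumbers[idx])
    }))
  } else {
    data.frame(block = 1L, wavenumber = object$wavenumbers[object$selected])
  }
}

#' Collapse selected wavenumbers into contiguous ranges
#'
#' Renders per-block selections as `lo-hi` cm^-1 ranges (contiguous grid
#' runs collapsed), the customary way selected regions are reported.
#'
#' @param object An `nir_calibration`.
#' @return Data frame with columns `block`, `lo`, `hi` (cm^-1).
#' @export
selected_ranges <- function(object) {
  sel <- selected_wavenumbers(object)
  if (is.null(sel) || nrow(sel) == 0L) {
    return(data.frame(block = integer(0), lo = numeric(0), hi = numeric(0)))
  }
  step <- if (length(object$wavenumbers) > 1L) {
    min(diff(object$wavenumbers))
  } else {
    1
  }
  by_block <- split(sel$wavenumber, sel$block)
  out <- lapply(names(by_block), function(b) {
    wn <- sort(by_block[[b]])
    run <- cumsum(c(1, diff(wn) > 1.5 * step))
    data.frame(block = as.integer(b),
               lo = as.numeric(tapply(wn, run, min)),
               hi = as.numeric(tapply(wn, run, max)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.nir_calibration <- function(x, ...) {
  cat(sprintf("<nir_calibration> %s for %s\n", x$method, x$analyte))
  cat(sprintf("  %d latent variables, %d of %d design columns selected\n",
              x$model$a, length(x$selected),
              x$n * if (x$uses_tl) 3L else 1L))
  invisible(x)
}

#' @export
summary.nir_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$selection_state)) print(object$selection_state)
  rng <- selected_ranges(object)
  if (nrow(rng) && nrow(rng) < object$n) {
    cat("  selected ranges (cm-1):\n")
    for (i in seq_len(nrow(rng))) {
      cat(sprintf("    block %d: %.0f-%.0f\n",
                  rng$block[i], rng$lo[i], rng$hi[i]))
    }
  }
  invisible(object)
}

#' @export
residuals.nir_calibration <- function(object, ...) {
  object$fitted_on$y - fitted(object$model)
}

#' Plot a calibration model's selected wavenumbers
#'
#' Draws the cross-validated r-squared curve over the latent-variable grid
#' and, for selection methods, marks the selected wavenumbers.
#'
#' @param x An `nir_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nir_calibration <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(as.integer(names(x$r2cv)), x$r2cv, type = "b",
                 xlab = "latent variables", ylab = "CV r-squared",
                 main = x$method, ...)
  graphics::abline(v = x$model$a, lty = 2)
  sel <- selected_wavenumbers(x)
  graphics::plot(sel$wavenumber, sel$block, pch = 16,
                 col = sel$block, xlim = rev(range(x$wavenumbers)),
                 xlab = "wavenumber (cm-1)", ylab = "block",
                 main = sprintf("%d selected", nrow(sel)))
  invisible(x)
}
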