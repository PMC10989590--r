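#' Build the block-augmented transfer-learning training design
#'
#' Pools culture-media samples (dataset A, the target domain) and
#' pseudo-media samples (dataset B, the source domain) into one design with
#' three n-column blocks: block 1 carries both domains' spectra and learns
#' the relationship common to both; block 2 carries culture spectra only
#' (zero for pseudo rows) and learns the culture-specific part; block 3
#' carries pseudo spectra only (zero for culture rows). The stacked
#' response is `c(y_A, y_B)`.
#'
#' @param ds_A `spectra_dataset` of culture media (may have zero pseudo
#'   counterpart rows in `ds_B`).
#' @param ds_B `spectra_dataset` of pseudo media on the identical
#'   wavenumber grid, or `NULL` for an empty source domain.
#' @param analyte Target name present in both datasets.
#' @return An object of class `tl_design` with `X_C`
#'   (`(m_A+m_B) x 3n`), `y_C`, `block_of` and `wavenumber_of` (integer
#'   vectors over the 3n columns, 1-based), and `m_A`, `m_B`, `n`,
#'   `wavenumbers`.
#' @export
tl_training_design <- function(ds_A, ds_B, analyte) {
  validate_spectra_dataset(ds_A)
  check(analyte %in% names(ds_A$targets),
        "analyte '%s' missing from culture dataset", analyte)
  n <- length(ds_A$wavenumbers)
  m_A <- nrow(ds_A$absorbance)
  if (is.null(ds_B)) {
    X_B <- matrix(0, 0L, n)
    y_B <- numeric(0)
    m_B <- 0L
  } else {
    validate_spectra_dataset(ds_B)
    check(length(ds_B$wavenumbers) == n &&
            all(abs(ds_B$wavenumbers - ds_A$wavenumbers) <=
                  1e-9 * pmax(1, abs(ds_A$wavenumbers))),
          "wavenumber grids of the two datasets differ")
    check(analyte %in% names(ds_B$targets),
          "analyte '%s' missing from pseudo dataset", analyte)
    X_B <- ds_B$absorbance
    y_B <- ds_B$targets[[analyte]]
    m_B <- nrow(X_B)
  }
  X_A <- ds_A$absorbance
  Z_A <- matrix(0, m_A, n)
  Z_B <- matrix(0, m_B, n)
  X_C <- rbind(cbind(X_A, X_A, Z_A),
               cbind(X_B, Z_B, X_B))
  y_C <- c(ds_A$targets[[analyte]], y_B)
  cols <- seq_len(3L * n)
  structure(
    list(X_C = X_C, y_C = y_C,
         block_of = (cols - 1L) %/% n + 1L,
         wavenumber_of = (cols - 1L) %% n + 1L,
         m_A = m_A, m_B = m_B, n = n,
         wavenumbers = ds_A$wavenumbers),
    class = "tl_design")
}

#' @export
print.tl_design <- function(x, ...) {
  cat(sprintf("<tl_design> %d culture + %d pseudo samples, 3 x %d columns\n",
              x$m_A, x$m_B, x$n))
  invisible(x)
}

#' Build the prediction-time design for new culture samples
#'
#' New culture spectra enter blocks 1 and 2; block 3 (the pseudo-specific
#' block) is zero.
#'
#' @param X_new Numeric matrix of new culture spectra, `n` columns. Zero
#'   rows are allowed.
#' @param n Number of wavenumbers.
#' @return Matrix `[X_new | X_new | 0]` of size `nrow(X_new) x 3n`.
#' @export
tl_prediction_design <- function(X_new, n) {
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L && ncol(X_new) == 0L) {
    X_new <- matrix(0, 0L, n)
  }
  check(ncol(X_new) == n, "X_new has %d columns, expected n = %d",
        ncol(X_new), n)
  cbind(X_new, X_new, matrix(0, nrow(X_new), n))
}

#' Map selected augmented-design columns back to blocks and wavenumbers
#'
#' Partitions a set of selected column indices of the 3n-column augmented
#' design into the three blocks and translates each to its original
#' wavenumber index, enabling per-block selected-wavenumber reporting.
#'
#' @param selected Integer indices in `[1, 3n]`.
#' @param n Number of wavenumbers per block.
#' @return Named list `block1`, `block2`, `block3` of sorted wavenumber
#'   indices in `[1, n]`.
#' @export
tl_map_selection <- function(selected, n) {
  selected <- as.integer(selected)
  n <- as.integer(n)
  check(all(selected >= 1L & selected <= 3L * n),
        "selected indices must lie in [1, 3n]")
  block <- (selected - 1L) %/% n + 1L
  wn <- (selected - 1L) %% n + 1L
  lapply(stats::setNames(1:3, paste0("block", 1:3)),
         function(b) sort(wn[block == b]))
}
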