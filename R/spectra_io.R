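#' Construct a spectra dataset
#'
#' The universal data container of the package: a wavenumber grid, a matrix
#' of absorbance spectra (one row per sample), one or more target
#' concentration vectors (g/L), a per-sample domain label and sample
#' identifiers. Wavenumbers are always stored in strictly ascending order;
#' if the inputs arrive in another order the columns are permuted (together
#' with the absorbance matrix) on construction.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, no duplicates.
#' @param absorbance Numeric matrix, `length(wavenumbers)` columns, one row
#'   per sample. Negative values are legal (derivative spectra).
#' @param targets Named list (or data.frame) of numeric vectors, one value
#'   per sample; typically `glucose` and/or `lactate` in g/L.
#' @param domain Character vector of per-sample labels, each `"culture"` or
#'   `"pseudo"`. A single value is recycled.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `s1, s2, ...`.
#' @param meta Optional data.frame of additional per-sample metadata
#'   (e.g. batch, day, split).
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(wavenumbers, absorbance, targets = list(),
                            domain = "culture", sample_ids = NULL,
                            meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  m <- nrow(absorbance)
  if (length(domain) == 1L) domain <- rep(domain, m)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  targets <- lapply(as.list(targets), as.numeric)

  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  colnames(absorbance) <- format(wavenumbers, trim = TRUE, scientific = FALSE)

  ds <- structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         targets = targets, domain = as.character(domain),
         sample_ids = as.character(sample_ids), meta = meta),
    class = "spectra_dataset")
  validate_spectra_dataset(ds)
  ds
}

#' Validate a spectra dataset
#'
#' Checks the structural invariants: strictly increasing wavenumbers whose
#' count matches the absorbance columns, complete absorbance values, target
#' vectors of the right length, and domain labels restricted to
#' `culture`/`pseudo`.
#'
#' @param ds A `spectra_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_spectra_dataset <- function(ds) {
  check(inherits(ds, "spectra_dataset"), "not a spectra_dataset")
  m <- nrow(ds$absorbance)
  n <- length(ds$wavenumbers)
  check(m >= 1L, "empty dataset: no samples")
  check(ncol(ds$absorbance) == n,
        "absorbance has %d columns but %d wavenumbers", ncol(ds$absorbance), n)
  check(!anyNA(ds$wavenumbers) && all(diff(ds$wavenumbers) > 0),
        "wavenumbers must be strictly increasing with no duplicates")
  check(!anyNA(ds$absorbance), "missing absorbance values")
  for (nm in names(ds$targets)) {
    check(length(ds$targets[[nm]]) == m,
          "target '%s' has length %d, expected %d",
          nm, length(ds$targets[[nm]]), m)
    check(!anyNA(ds$targets[[nm]]), "target '%s' has missing values", nm)
  }
  check(all(ds$domain %in% c("culture", "pseudo")),
        "domain labels must be 'culture' or 'pseudo'")
  check(length(ds$domain) == m, "domain has wrong length")
  check(length(ds$sample_ids) == m, "sample_ids has wrong length")
  if (!is.null(ds$meta)) {
    check(nrow(ds$meta) == m, "meta has wrong number of rows")
  }
  invisible(ds)
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d samples x %d wavenumbers (%.0f-%.0f cm-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$targets)) {
    cat("  targets:", paste(names(x$targets), collapse = ", "), "\n")
  }
  cat("  domain :", paste(sprintf("%s (%d)", names(table(x$domain)),
                                  table(x$domain)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spectra dataset by sample
#'
#' @param x A `spectra_dataset`.
#' @param i Row (sample) index vector.
#' @param ... Unused.
#' @return A `spectra_dataset` containing the selected samples.
#' @export
`[.spectra_dataset` <- function(x, i, ...) {
  spectra_dataset(
    wavenumbers = x$wavenumbers,
    absorbance = x$absorbance[i, , drop = FALSE],
    targets = lapply(x$targets, `[`, i),
    domain = x$domain[i],
    sample_ids = x$sample_ids[i],
    meta = if (is.null(x$meta)) NULL else x$meta[i, , drop = FALSE])
}

#' Number of samples in a dataset
#' @param ds A `spectra_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) nrow(ds$absorbance)

#' Read a spectra+targets CSV file
#'
#' Expects one row per sample. Columns with numeric headers are wavenumbers
#' (cm^-1); the named columns listed in `target_columns` are targets;
#' a `domain` column and a `sample_id` column are picked up when present,
#' and any remaining named columns become per-sample metadata. Wavenumber
#' columns may appear in any order in the file; they are stored ascending.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param target_columns Character vector of target column names expected in
#'   the file. Defaults to intersecting with `c("glucose", "lactate")`.
#' @return A `spectra_dataset`.
#' @export
read_spectra <- function(path, target_columns = NULL) {
  check(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check(nrow(df) >= 1L, "empty dataset: %s has a header but no samples", path)

  headers <- names(df)
  wn <- suppressWarnings(as.numeric(headers))
  is_wn <- !is.na(wn)
  check(any(is_wn), "no numeric wavenumber columns in %s", path)
  check(!anyDuplicated(wn[is_wn]), "duplicate wavenumber columns in %s", path)

  named <- headers[!is_wn]
  if (is.null(target_columns)) {
    target_columns <- intersect(c("glucose", "lactate"), named)
  }
  missing <- setdiff(target_columns, named)
  check(length(missing) == 0L, "target column(s) absent: %s",
        paste(missing, collapse = ", "))

  A <- as.matrix(df[, is_wn, drop = FALSE])
  check(is.numeric(A) && !anyNA(A), "non-numeric or missing absorbance values")
  targets <- lapply(df[target_columns], as.numeric)
  names(targets) <- target_columns

  domain <- if ("domain" %in% named) df$domain else "culture"
  ids <- if ("sample_id" %in% named) as.character(df$sample_id) else NULL
  meta_cols <- setdiff(named, c(target_columns, "domain", "sample_id"))
  meta <- if (length(meta_cols)) df[meta_cols] else NULL

  spectra_dataset(wavenumbers = wn[is_wn], absorbance = A, targets = targets,
                  domain = domain, sample_ids = ids, meta = meta)
}

#' Write a spectra dataset to CSV
#'
#' Inverse of [read_spectra()]: wavenumber columns first (ascending, numeric
#' headers), then targets, then `domain`, `sample_id` and any metadata
#' columns. `read_spectra(write_spectra(ds, p))` reproduces `ds` exactly.
#'
#' @param ds A `spectra_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  validate_spectra_dataset(ds)
  num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly
  A <- matrix(num(ds$absorbance), nrow = nrow(ds$absorbance))
  df <- as.data.frame(A, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- num(ds$wavenumbers)
  for (nm in names(ds$targets)) df[[nm]] <- num(ds$targets[[nm]])
  df$domain <- ds$domain
  df$sample_id <- ds$sample_ids
  if (!is.null(ds$meta)) for (nm in names(ds$meta)) df[[nm]] <- ds$meta[[nm]]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  check(ok, "could not write to %s", path)
  invisible(path)
}
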