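# fixtures built in code; all randomness goes through explicit seeds

random_dataset <- function(m, n, seed, targets = c("glucose"),
                           domain = "culture") {
  with_seed_local(seed, {
    tg <- lapply(seq_along(targets), function(i) runif(m, 0, 8))
    names(tg) <- targets
    spectra_dataset(
      wavenumbers = sort(sample(seq(4000, 12000, by = 2), n)),
      absorbance = matrix(rnorm(m * n), m, n),
      targets = tg, domain = domain)
  })
}

# local copy of the package-internal seed guard (tests run against the
# installed package, which does not export it)
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# a small uniform-grid dataset whose response is exactly linear in the
# absorbance matrix (noise-free), for end-to-end sanity checks
linear_dataset <- function(m, n, seed, beta = NULL) {
  with_seed_local(seed, {
    if (is.null(beta)) beta <- rnorm(n)
    A <- matrix(rnorm(m * n), m, n)
    spectra_dataset(
      wavenumbers = seq(4000, by = 8, length.out = n),
      absorbance = A,
      targets = list(glucose = drop(A %*% beta)))
  })
}

# fast synthetic scenario for pipeline-level tests (coarse grid)
fast_config <- function(seed = 1L) {
  synthetic_config(grid_step = 64, seed = seed)
}
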