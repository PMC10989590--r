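#' Default component band definitions
#'
#' Gaussian absorption bands for each mixture component. Water contributes
#' the two broad dominant bands near 7000 and 5100 cm^-1 that shape every
#' aqueous NIR spectrum. Glucose bands sit at the C-H/O-H overtone and
#' combination positions characteristic of saccharides (around 8710,
#' 5807, 4762, 4393, 4295 and 4252 cm^-1); lactate bands sit in the
#' 5900-5700 and 4470-4240 cm^-1 combination regions. Three interferents
#' (glutamine, ammonia, a serum-protein background) carry bands that
#' overlap the analyte regions, so no analyte has a clean isolated peak.
#' Analyte amplitudes are roughly three orders of magnitude below the
#' water bands: raw spectra show no visible analyte peaks, which is what
#' makes derivative preprocessing and wavelength selection necessary.
#' All amplitudes except water's are absorbance units per g/L.
#'
#' @return Named list of data.frames with columns `center` (cm^-1),
#'   `width` (Gaussian sigma, cm^-1) and `amplitude`.
#' @export
default_components <- function() {
  band <- function(center, width, amplitude) {
    data.frame(center = center, width = width, amplitude = amplitude)
  }
  list(
    water = band(c(7000, 5150), c(280, 220), c(0.55, 1.0)),
    glucose = band(c(8710, 5807, 4762, 4393, 4295, 4252),
                   c(70, 48, 32, 26, 24, 18),
                   c(0.4e-3, 2.0e-3, 1.4e-3, 2.0e-3, 1.4e-3, 1.0e-3)),
    lactate = band(c(5830, 4355), c(45, 40), c(1.8e-3, 2.0e-3)),
    glutamine = band(c(6850, 4600), c(60, 45), c(1.2e-3, 1.6e-3)),
    ammonia = band(c(5010, 4550), c(50, 40), c(1.2e-3, 1.0e-3)),
    protein = band(c(5755, 4060), c(55, 40), c(1.0e-3, 1.5e-3))
  )
}

#' Configuration of the synthetic NIR batch-culture generator
#'
#' Defines the wavenumber grid, the component bands, the batch-culture
#' trajectory parameters, the pseudo-media blending scheme, the noise and
#' baseline model and the sample counts. Defaults emulate a CHO
#' batch-culture study: glucose added at 5-7 g/L is consumed over the
#' culture days while lactate and other metabolites accumulate (inducing
#' strong glucose-lactate-interferent correlations), 45 culture samples
#' split 22 train / 23 test by batch, and 102 pseudo-media samples whose
#' glucose is set by an independent spike so its correlation with the
#' other components is broken.
#'
#' @param grid_min,grid_max,grid_step Wavenumber grid in cm^-1. The
#'   default 4000-12000 at 16 cm^-1 (501 points) keeps simulations fast; a
#'   4 cm^-1 step gives an instrument-resolution grid.
#' @param components Band table as from [default_components()].
#' @param n_batches,days Culture batches and sampling days per batch.
#' @param glucose0_range Initial glucose concentration range, g/L.
#' @param decay_range Per-batch first-order glucose consumption rate range
#'   (per day).
#' @param yield_range Per-batch lactate yield range (g lactate per g
#'   glucose consumed).
#' @param n_culture_train,n_culture_test Culture train/test sample counts.
#' @param n_pseudo Number of pseudo-media samples.
#' @param pseudo_glucose_range Glucose span of the pseudo media (g/L),
#'   achieved by spiking.
#' @param pseudo_lactate_range Admissible lactate span of the pseudo
#'   media (g/L).
#' @param noise_sd Iid Gaussian absorbance noise, AU.
#' @param baseline_sd Scale of the per-sample degree-2 polynomial baseline
#'   coefficients, AU.
#' @param water_sd Per-sample relative variation of the water pathlength.
#' @param conc_jitter_sd Per-sample jitter on interferent concentrations,
#'   g/L.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_min = 4000, grid_max = 12000,
                             grid_step = 16,
                             components = default_components(),
                             n_batches = 5L, days = 0:8,
                             glucose0_range = c(5, 7),
                             decay_range = c(0.25, 0.35),
                             yield_range = c(0.40, 0.55),
                             n_culture_train = 22L, n_culture_test = 23L,
                             n_pseudo = 102L,
                             pseudo_glucose_range = c(0.87, 8.0),
                             pseudo_lactate_range = c(0.12, 3.1),
                             noise_sd = 1e-4, baseline_sd = 3e-4,
                             water_sd = 0.002, conc_jitter_sd = 0.02,
                             seed = 1L) {
  check(grid_step > 0, "grid_step must be positive")
  check(n_batches >= 1L && length(days) >= 2L, "need batches and days")
  check(noise_sd >= 0 && baseline_sd >= 0, "noise scales must be >= 0")
  n_culture <- n_batches * length(days)
  check(n_culture_train + n_culture_test <= n_culture,
        "train+test (%d) exceeds generated culture samples (%d)",
        n_culture_train + n_culture_test, n_culture)
  structure(
    list(grid = seq(grid_min, grid_max, by = grid_step),
         components = components,
         n_batches = as.integer(n_batches), days = days,
         glucose0_range = glucose0_range, decay_range = decay_range,
         yield_range = yield_range,
         n_culture_train = as.integer(n_culture_train),
         n_culture_test = as.integer(n_culture_test),
         n_pseudo = as.integer(n_pseudo),
         pseudo_glucose_range = pseudo_glucose_range,
         pseudo_lactate_range = pseudo_lactate_range,
         noise_sd = noise_sd, baseline_sd = baseline_sd,
         water_sd = water_sd, conc_jitter_sd = conc_jitter_sd,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Per-component extinction profiles on the grid
#'
#' Sums each component's Gaussian bands:
#' `eps(nu) = sum_bands amplitude * exp(-(nu - center)^2 / (2 width^2))`.
#' Bands centered outside the grid raise a warning (not an error).
#'
#' @param cfg A [synthetic_config()].
#' @return Matrix, one row per component (rownames = component names), one
#'   column per grid point.
#' @export
component_spectra <- function(cfg) {
  nu <- cfg$grid
  E <- t(vapply(cfg$components, function(bands) {
    out <- numeric(length(nu))
    if (nrow(bands) == 0L) return(out)
    for (b in seq_len(nrow(bands))) {
      if (bands$center[b] < min(nu) || bands$center[b] > max(nu)) {
        warning(sprintf("band at %.0f cm-1 lies outside the grid",
                        bands$center[b]))
      }
      check(bands$width[b] > 0, "band width must be positive")
      out <- out + bands$amplitude[b] *
        exp(-(nu - bands$center[b])^2 / (2 * bands$width[b]^2))
    }
    out
  }, numeric(length(nu))))
  rownames(E) <- names(cfg$components)
  E
}

# absorbance = C %*% E + per-sample polynomial baseline + iid noise
.assemble_spectra <- function(C, cfg) {
  E <- suppressWarnings(component_spectra(cfg))
  A <- C %*% E
  m <- nrow(A)
  nu <- cfg$grid
  u <- (nu - mean(nu)) / (diff(range(nu)) / 2)
  if (cfg$baseline_sd > 0) {
    B <- matrix(stats::rnorm(3 * m, sd = cfg$baseline_sd), m, 3)
    A <- A + B %*% rbind(rep(1, length(u)), u, u^2)
  }
  if (cfg$noise_sd > 0) {
    A <- A + matrix(stats::rnorm(length(A), sd = cfg$noise_sd), m)
  }
  A
}

# batch trajectories; returns per-sample concentration data.frame
.culture_concentrations <- function(cfg) {
  out <- list()
  for (b in seq_len(cfg$n_batches)) {
    g0 <- stats::runif(1, cfg$glucose0_range[1], cfg$glucose0_range[2])
    k <- stats::runif(1, cfg$decay_range[1], cfg$decay_range[2])
    yield <- stats::runif(1, cfg$yield_range[1], cfg$yield_range[2])
    amm_amp <- stats::runif(1, 0.2, 0.5)
    prot_slope <- stats::runif(1, -0.5, 0.5)
    d <- cfg$days
    glucose <- g0 * exp(-k * d)
    depletion <- 1 - glucose / g0
    jit <- function(x) {
      pmax(x + stats::rnorm(length(x), sd = cfg$conc_jitter_sd), 0)
    }
    out[[b]] <- data.frame(
      batch = b, day = d,
      water = stats::rnorm(length(d), 1, cfg$water_sd),
      glucose = glucose,
      lactate = jit(yield * (g0 - glucose) + 0.1),
      glutamine = jit(0.58 * (1 - 0.8 * depletion)),
      ammonia = jit(amm_amp * depletion),
      protein = jit(3.0 + prot_slope * depletion))
  }
  do.call(rbind, out)
}

#' Simulate batch-culture media spectra
#'
#' Each batch follows a daily trajectory: glucose decays exponentially
#' from its initial 5-7 g/L, lactate accumulates proportionally to the
#' consumed glucose, and the interferents follow correlated monotone
#' trajectories (glutamine consumed, ammonia produced, the protein
#' background drifting), so the metabolite concentrations are strongly
#' mutually correlated within the culture domain. Spectra follow
#' Beer-Lambert mixing of the component profiles plus a small per-sample
#' polynomial baseline and iid noise. The train/test split is by batch:
#' whole batches fill the training set in order, the next batch is split
#' by alternating days to reach the configured 22/23 counts, and the
#' remaining batches form the test set (recorded in `meta$split`).
#'
#' @param cfg A [synthetic_config()].
#' @return A `spectra_dataset` with targets `glucose` and `lactate`,
#'   domain `"culture"` and metadata columns `batch`, `day`, `split`.
#' @export
simulate_culture <- function(cfg = synthetic_config()) {
  conc <- with_seed(cfg$seed, {
    conc <- .culture_concentrations(cfg)
    attr(conc, "A") <- .assemble_spectra(
      as.matrix(conc[names(cfg$components)]), cfg)
    conc
  })
  A <- attr(conc, "A")

  m <- nrow(conc)
  n_train <- cfg$n_culture_train
  n_test <- cfg$n_culture_test
  split <- rep("unused", m)
  taken <- 0L
  for (b in seq_len(cfg$n_batches)) {
    if (taken >= n_train) break
    rows <- which(conc$batch == b)
    if (taken + length(rows) <= n_train) {
      split[rows] <- "train"
      taken <- taken + length(rows)
    } else {
      need <- n_train - taken
      # alternate days so both splits see the whole trajectory
      pick <- if (need <= ceiling(length(rows) / 2)) {
        rows[seq(1L, by = 2L, length.out = need)]
      } else {
        rows[seq_len(need)]
      }
      split[pick] <- "train"
      taken <- n_train
    }
  }
  rest <- which(split == "unused")
  split[rest[seq_len(min(n_test, length(rest)))]] <- "test"

  keep <- split != "unused"
  spectra_dataset(
    wavenumbers = cfg$grid,
    absorbance = A[keep, , drop = FALSE],
    targets = list(glucose = conc$glucose[keep],
                   lactate = conc$lactate[keep]),
    domain = "culture",
    sample_ids = sprintf("cultureB%dD%d", conc$batch[keep], conc$day[keep]),
    meta = data.frame(batch = conc$batch[keep], day = conc$day[keep],
                      split = split[keep]))
}

#' Simulate pseudo-media spectra
#'
#' Pseudo media emulate lab-blended mixtures of fresh medium, spent
#' (end-of-culture) medium and a glucose spike. Each sample blends a fresh
#' composition with the terminal composition of one of two source batches
#' by a random fraction (which keeps lactate and the interferents mutually
#' correlated), then replaces glucose with an independent draw spanning
#' the configured 0.87-8.0 g/L range - breaking the glucose-interferent
#' correlation that dominates the culture domain. Lactate is clipped to
#' its configured span.
#'
#' @param cfg A [synthetic_config()].
#' @return A `spectra_dataset` with domain `"pseudo"`, default 102
#'   samples.
#' @export
simulate_pseudo <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed + 1L, {
    m <- cfg$n_pseudo
    fresh <- c(glucose = 0, lactate = 0.1, glutamine = 0.58,
               ammonia = 0, protein = 3.0)
    ends <- lapply(1:2, function(i) {
      g0 <- stats::runif(1, cfg$glucose0_range[1], cfg$glucose0_range[2])
      k <- stats::runif(1, cfg$decay_range[1], cfg$decay_range[2])
      yield <- stats::runif(1, cfg$yield_range[1], cfg$yield_range[2])
      gend <- g0 * exp(-k * max(cfg$days))
      c(glucose = gend, lactate = yield * (g0 - gend) + 0.1,
        glutamine = 0.58 * (1 - 0.8 * (1 - gend / g0)),
        ammonia = stats::runif(1, 0.2, 0.5) * (1 - gend / g0),
        protein = 3.0 + stats::runif(1, -0.5, 0.5) * (1 - gend / g0))
    })
    phi <- stats::runif(m)
    src <- sample(1:2, m, replace = TRUE)
    comp <- t(vapply(seq_len(m), function(i) {
      (1 - phi[i]) * fresh + phi[i] * ends[[src[i]]]
    }, numeric(5)))
    colnames(comp) <- names(fresh)
    jitter <- matrix(stats::rnorm(length(comp), sd = cfg$conc_jitter_sd),
                     nrow = m)
    comp <- pmax(comp + jitter, 0)
    # independent glucose spike: decorrelates glucose from the rest
    comp[, "glucose"] <- stats::runif(m, cfg$pseudo_glucose_range[1],
                                      cfg$pseudo_glucose_range[2])
    comp[, "lactate"] <- pmin(pmax(comp[, "lactate"],
                                   cfg$pseudo_lactate_range[1]),
                              cfg$pseudo_lactate_range[2])
    C <- cbind(water = stats::rnorm(m, 1, cfg$water_sd), comp)
    C <- C[, names(cfg$components), drop = FALSE]
    A <- .assemble_spectra(C, cfg)
    spectra_dataset(
      wavenumbers = cfg$grid,
      absorbance = A,
      targets = list(glucose = C[, "glucose"], lactate = C[, "lactate"]),
      domain = "pseudo",
      sample_ids = sprintf("pseudo%03d", seq_len(m)))
  })
}

#' Ground-truth informative wavenumber indices for an analyte
#'
#' Grid indices within `n_widths` Gaussian widths of any band center of
#' the analyte - the "true" wavenumbers a selector should recover.
#'
#' @param cfg A [synthetic_config()].
#' @param analyte Component name, e.g. `"glucose"`.
#' @param n_widths Half-width of the window around each center, in band
#'   sigmas (default 2).
#' @return Sorted integer vector of grid indices.
#' @export
truth_mask <- function(cfg, analyte = "glucose", n_widths = 2) {
  check(analyte %in% names(cfg$components), "unknown component '%s'", analyte)
  bands <- cfg$components[[analyte]]
  idx <- integer(0)
  for (b in seq_len(nrow(bands))) {
    idx <- c(idx, which(abs(cfg$grid - bands$center[b]) <=
                          n_widths * bands$width[b]))
  }
  sort(unique(idx))
}

#' Flat-noise wavenumber indices
#'
#' Grid indices farther than `n_widths` band widths (plus an optional
#' guard) from every band of every component - wavenumbers carrying only
#' baseline and noise, used to score false selections. When spectra are
#' differentiated with a Savitzky-Golay filter before selection, a column
#' up to half a filter window away from a band still carries smeared band
#' signal; pass `guard = (window - 1) / 2 * grid_step` (in cm^-1) so that
#' such columns are not counted as flat noise.
#'
#' @param cfg A [synthetic_config()].
#' @param n_widths Exclusion half-width in band sigmas (default 3).
#' @param guard Additional exclusion margin in cm^-1 (default 0).
#' @return Sorted integer vector of grid indices.
#' @export
noise_mask <- function(cfg, n_widths = 3, guard = 0) {
  informative <- unlist(lapply(cfg$components, function(bands) {
    unlist(lapply(seq_len(nrow(bands)), function(b) {
      which(abs(cfg$grid - bands$center[b]) <=
              n_widths * bands$width[b] + guard)
    }))
  }))
  setdiff(seq_along(cfg$grid), informative)
}

#' Split a simulated culture dataset into train and test parts
#'
#' @param ds A `spectra_dataset` from [simulate_culture()] (requires
#'   `meta$split`).
#' @return List with elements `train` and `test`.
#' @export
split_culture <- function(ds) {
  check(!is.null(ds$meta) && "split" %in% names(ds$meta),
        "dataset has no split metadata")
  list(train = ds[ds$meta$split == "train"],
       test = ds[ds$meta$split == "test"])
}
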