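test_that("the same seed reproduces both datasets bit for bit", {
  cfg <- fast_config(seed = 5)
  expect_identical(simulate_culture(cfg), simulate_culture(cfg))
  expect_identical(simulate_pseudo(cfg), simulate_pseudo(cfg))
  cfg2 <- fast_config(seed = 6)
  expect_false(identical(simulate_culture(cfg)$absorbance,
                         simulate_culture(cfg2)$absorbance))
})

test_that("component profiles are Gaussian band sums with peak amplitude", {
  cfg <- synthetic_config(grid_min = 4000, grid_max = 6000, grid_step = 10,
                          components = list(
                            water = data.frame(center = 5000, width = 100,
                                               amplitude = 0.7),
                            empty = data.frame(center = numeric(0),
                                               width = numeric(0),
                                               amplitude = numeric(0))))
  E <- component_spectra(cfg)
  expect_equal(unname(E["empty", ]), rep(0, length(cfg$grid)))
  expect_equal(max(E["water", ]), 0.7)
  expect_equal(cfg$grid[which.max(E["water", ])], 5000)
  # analytic oracle at an off-center point
  expect_equal(unname(E["water", cfg$grid == 5200]),
               0.7 * exp(-200^2 / (2 * 100^2)), tolerance = 1e-12)
  cfg$components$water$center <- 3000
  expect_warning(component_spectra(cfg), "outside the grid")
})

test_that("noise-free spectra follow Beer-Lambert mixing exactly", {
  # water only, no variability: every sample equals the water profile
  water_only <- synthetic_config(
    components = default_components()["water"],
    noise_sd = 0, baseline_sd = 0, water_sd = 0, seed = 2)
  ds <- simulate_culture(water_only)
  bands <- default_components()$water
  profile <- colSums(t(vapply(1:2, function(b) {
    bands$amplitude[b] *
      exp(-(water_only$grid - bands$center[b])^2 / (2 * bands$width[b]^2))
  }, numeric(length(water_only$grid)))))
  for (i in seq_len(n_samples(ds))) {
    expect_equal(unname(ds$absorbance[i, ]), profile, tolerance = 1e-12)
  }

  # water + glucose: absorbance equals the concentration-weighted sum
  wg <- synthetic_config(
    components = default_components()[c("water", "glucose")],
    noise_sd = 0, baseline_sd = 0, water_sd = 0, seed = 3)
  ds2 <- simulate_culture(wg)
  E <- component_spectra(wg)
  expected <- cbind(1, ds2$targets$glucose) %*% E
  expect_equal(unname(ds2$absorbance), unname(expected), tolerance = 1e-10)
})

test_that("default counts and batch split match the study layout", {
  cfg <- fast_config(seed = 1)
  cu <- simulate_culture(cfg)
  expect_equal(n_samples(cu), 45L)
  sp <- split_culture(cu)
  expect_equal(n_samples(sp$train), 22L)
  expect_equal(n_samples(sp$test), 23L)
  # whole early batches are training; later batches are test
  expect_true(all(sp$train$meta$batch %in% 1:3))
  expect_true(all(4:5 %in% sp$test$meta$batch))
  expect_equal(n_samples(simulate_pseudo(cfg)), 102L)
  expect_true(all(simulate_pseudo(cfg)$domain == "pseudo"))
})

test_that("culture trajectories induce the expected correlation structure", {
  for (seed in 1:5) {
    cfg <- fast_config(seed = seed)
    cu <- simulate_culture(cfg)
    ps <- simulate_pseudo(cfg)
    # glucose falls while lactate rises: strong negative correlation
    expect_lt(cor(cu$targets$glucose, cu$targets$lactate), -0.8)
    # glucose spans the fed range and decays within each batch
    expect_true(all(diff(cu$targets$glucose[cu$meta$batch == 1]) < 0))
    # spiking decorrelates glucose in the pseudo domain
    expect_lt(abs(cor(ps$targets$glucose, ps$targets$lactate)),
              abs(cor(cu$targets$glucose, cu$targets$lactate)))
    # pseudo concentration ranges respect the configured spans
    expect_true(all(ps$targets$glucose >= 0.87 & ps$targets$glucose <= 8.0))
    expect_true(all(ps$targets$lactate >= 0.12 & ps$targets$lactate <= 3.1))
  }
})

test_that("glucose correlates with interferent absorption only in culture", {
  cfg <- synthetic_config(seed = 4)
  cu <- simulate_culture(cfg)
  ps <- simulate_pseudo(cfg)
  # absorbance at the glutamine band center tracks the interferent level
  j <- which.min(abs(cfg$grid - 4600))
  r_cu <- abs(cor(cu$targets$glucose, cu$absorbance[, j]))
  r_ps <- abs(cor(ps$targets$glucose, ps$absorbance[, j]))
  expect_lt(r_ps, r_cu)
})

test_that("truth masks cover the configured band neighbourhoods", {
  cfg <- synthetic_config(grid_min = 4000, grid_max = 4400, grid_step = 10,
                          components = list(
                            glucose = data.frame(center = 4200, width = 10,
                                                 amplitude = 1)))
  mask <- truth_mask(cfg, "glucose", n_widths = 2)
  expect_equal(cfg$grid[mask], c(4180, 4190, 4200, 4210, 4220))

  # disjoint bands contribute additively
  cfg$components$glucose <- data.frame(center = c(4100, 4300),
                                       width = c(10, 10), amplitude = 1)
  expect_length(truth_mask(cfg, "glucose", n_widths = 2), 10L)

  # default glucose mask covers the C-H first-overtone region
  dflt <- synthetic_config()
  covered <- dflt$grid[truth_mask(dflt, "glucose")]
  expect_true(all(seq(5712, 5888, by = 16) %in% covered))
  expect_error(truth_mask(dflt, "caffeine"), "unknown component")
})

test_that("noise mask excludes every band neighbourhood plus the guard", {
  cfg <- synthetic_config()
  nm <- noise_mask(cfg, n_widths = 3, guard = 160)
  for (cmp in names(cfg$components)) {
    expect_length(intersect(nm, truth_mask(cfg, cmp, n_widths = 3)), 0L)
  }
  # guard widens the exclusion
  expect_lt(length(nm), length(noise_mask(cfg, n_widths = 3, guard = 0)))
})
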