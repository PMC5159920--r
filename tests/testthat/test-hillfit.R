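noiseless_gene <- function(a = 0.1, b = 0.9, k = 8.33, n = 4) {
  sample_hill_profile(c(a = a, b = b, k = k, n = n),
    noise_cv = 0, n_replicates = 2
  )
}

test_that("log posterior is -Inf out of bounds and maximal at the truth", {
  d <- noiseless_gene()
  bounds <- default_prior_bounds(d$dose, d$value)
  lp_true <- log_posterior(
    c(a = 0.1, b = 0.9, k = 8.33, n = 4), d$dose, d$value,
    sigma = 0.05, bounds = bounds
  )
  expect_true(is.finite(lp_true))
  expect_equal(
    log_posterior(
      c(a = -1, b = 0.9, k = 8.33, n = 4), d$dose, d$value,
      bounds = bounds
    ),
    -Inf
  )
  expect_equal(
    log_posterior(
      c(a = 0.1, b = 0.9, k = 8.33, n = 1000), d$dose, d$value,
      bounds = bounds
    ),
    -Inf
  )
  # coarse grid search: nothing beats the generating parameters
  set.seed(3)
  for (i in 1:200) {
    p <- c(
      a = runif(1, 0, 1), b = runif(1, 0.2, 3),
      k = exp(runif(1, log(0.5), log(16))), n = exp(runif(1, log(0.3), log(10)))
    )
    expect_lte(
      log_posterior(p, d$dose, d$value, sigma = 0.05, bounds = bounds),
      lp_true + 1e-9
    )
  }
})

test_that("MH chains are deterministic given the seed", {
  d <- sample_hill_profile(c(a = 0.1, b = 0.9, k = 8.33, n = 4),
    noise_cv = 0.1, seed = 5
  )
  f1 <- mh_fit(d, fit_config(n_steps = 3000, seed = 99))
  f2 <- mh_fit(d, fit_config(n_steps = 3000, seed = 99))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$modes, f2$modes)
  f3 <- mh_fit(d, fit_config(n_steps = 3000, seed = 100))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("kept sample count follows the burn-in contract", {
  d <- noiseless_gene()
  f <- suppressWarnings(
    mh_fit(d, fit_config(n_steps = 2000, burn_in_fraction = 0.2, seed = 1))
  )
  expect_equal(nrow(f$samples), 2000 * 0.8)
  expect_true(f$acceptance_rate >= 0 && f$acceptance_rate <= 1)
  f0 <- suppressWarnings(
    mh_fit(d, fit_config(n_steps = 1000, burn_in_fraction = 0, seed = 1))
  )
  expect_equal(nrow(f0$samples), 1000)
})

test_that("grid oracle returns grid-aligned parameters exactly", {
  d <- noiseless_gene()
  bounds <- list(
    a = c(0, 1), b = c(0.5, 2), k = c(1, 16.7), n = c(1, 10), sigma = c(1e-3, 10)
  )
  # plant a gene on the oracle's own grid, then ask for it back
  grid_a <- seq(0, 1, length.out = 10)
  grid_b <- exp(seq(log(0.5), log(2), length.out = 10))
  grid_k <- exp(seq(log(1), log(16.7), length.out = 10))
  grid_n <- exp(seq(log(1), log(10), length.out = 10))
  p <- c(a = grid_a[3], b = grid_b[5], k = grid_k[6], n = grid_n[4])
  d2 <- sample_hill_profile(p, noise_cv = 0, n_replicates = 2)
  g <- grid_oracle(d2, bounds = bounds, resolution = 10)
  expect_equal(c(a = g$a, b = g$b, k = g$k, n = g$n), p, tolerance = 1e-12)
  expect_equal(g$rss, 0, tolerance = 1e-20)

  # flat data pushes the dynamic range to the bottom of its grid
  flat <- tibble::tibble(
    dose = rep(default_dose_grid(), 2),
    value = rep(2, 12) + rep(c(0, 1e-6), each = 6)
  )
  gf <- grid_oracle(flat)
  expect_equal(gf$b, min(attr(gf, "grid")$b))
})

test_that("degenerate observations yield an unidentifiable flag, not an error", {
  d <- tibble::tibble(dose = rep(default_dose_grid(), 2), value = rep(3, 12))
  f <- mh_fit(d, fit_config(n_steps = 500, seed = 1))
  expect_true("unidentifiable" %in% f$flags)
  expect_true(is.na(f$n_binned_mode))
  expect_equal(nrow(f$samples), 0)
})

test_that("binned mode uses 0.5-wide bins with ties broken downward", {
  expect_equal(ultrahill:::binned_mode(c(0.6, 0.7, 3.2), 0.5), 0.75)
  # tie between bins [0,0.5) and [2,2.5): lower bin wins
  expect_equal(ultrahill:::binned_mode(c(0.1, 0.2, 2.1, 2.2), 0.5), 0.25)
  expect_equal(ultrahill:::binned_mode(c(1.4, 1.4, 1.4), 0.5), 1.25)
})

test_that("fitted scale equivariance: response units move a,b; dose units move k", {
  d <- sample_hill_profile(c(a = 0.5, b = 4, k = 4.2, n = 2),
    noise_cv = 0.05, seed = 11
  )
  cfg <- fit_config(n_steps = 8000, seed = 7, scale = "raw", noise_sigma = "sampled")
  f1 <- mh_fit(d, cfg)
  d10 <- dplyr::mutate(d, value = value * 10)
  f2 <- mh_fit(d10, cfg)
  expect_equal(f2$modes[["a"]] / f1$modes[["a"]], 10, tolerance = 0.35)
  expect_equal(f2$modes[["b"]] / f1$modes[["b"]], 10, tolerance = 0.35)
  expect_equal(f2$modes[["n"]], f1$modes[["n"]], tolerance = 0.5)

  dx <- dplyr::mutate(d, dose = dose * 3)
  f3 <- mh_fit(dx, cfg)
  expect_equal(f3$modes[["k"]] / f1$modes[["k"]], 3, tolerance = 0.35)
  expect_equal(f3$modes[["n"]], f1$modes[["n"]], tolerance = 0.5)
})

test_that("cohort fitting tabulates per-gene fits and the n histogram", {
  co <- simulate_cohort(cohort_spec(
    n_genes = 30, seed = 17, noise_cv = 0.05,
    class_proportions = c(increase = 0.7, decrease = 0.3)
  ))
  inc <- co$truth$gene_id[co$truth$class == "increase"]
  fits <- suppressWarnings(
    fit_cohort(co$expression, inc, fit_config(n_steps = 2000, seed = 2))
  )
  expect_equal(nrow(fits), length(inc))
  expect_true(all(is.na(fits$error)))
  expect_true(all(fits$acceptance_rate > 0))

  h <- hill_histogram(fits)
  expect_equal(sum(h$count), length(inc))
  expect_equal(h$bin_lo, seq(0, max(h$bin_lo), by = 0.5))
  expect_equal(
    attr(h, "n_above_1") + attr(h, "n_at_most_1"), length(inc)
  )

  empty <- fit_cohort(co$expression, character(0), fit_config(n_steps = 100))
  expect_equal(nrow(empty), 0)
})

test_that("tidy and glance summarize a fit", {
  d <- noiseless_gene()
  f <- suppressWarnings(mh_fit(d, fit_config(n_steps = 2000, seed = 4)))
  td <- tidy(f)
  expect_equal(td$term, c("a", "b", "k", "n"))
  expect_true(all(td$conf.low <= td$mode & td$mode <= td$conf.high))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(is.logical(gl$ultrasensitive))
  expect_equal(nrow(tidy(f, "samples")), nrow(f$samples))
})
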