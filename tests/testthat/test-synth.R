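test_that("noiseless Hill profiles are exact and noisy ones match the CV", {
  d <- sample_hill_profile(c(a = 0.1, b = 0.9, k = 8.33, n = 4),
    dose_grid = c(0, 1, 2.1, 4.2, 8.33, 16.7), noise_cv = 0, n_replicates = 2
  )
  expect_equal(d$value[d$dose == 8.33], rep(0.55, 2))
  expect_equal(d$value[d$dose == 0], rep(0.1, 2))

  # Monte-Carlo check of the multiplicative noise model: unit median, stated CV
  set.seed(20)
  f <- ultrahill:::noise_factor(10000, 0.1)
  expect_equal(sd(f) / mean(f), 0.1, tolerance = 0.01)
  expect_equal(median(f), 1, tolerance = 0.01)

  expect_error(
    sample_hill_profile(c(a = NA, b = 1, k = 1, n = 1)), "finite"
  )
})

test_that("baseline mixture splits at 1 FPKM with the stated weight", {
  x <- sample_basal_distribution(10000, basal_mixture(w_low = 0.28), seed = 5)
  expect_true(all(x >= 0))
  expect_equal(mean(x < 1), 0.28, tolerance = 0.02)

  # pure high component has almost all mass above 1 FPKM
  expect_gt(mean(sample_basal_distribution(
    2000, basal_mixture(w_low = 0), seed = 1
  ) >= 1), 0.95)
  expect_true(mean(sample_basal_distribution(
    2000, basal_mixture(w_low = 1), seed = 1
  ) < 1) > 0.99)
})

test_that("cohorts are deterministic and respect class proportions", {
  spec <- cohort_spec(n_genes = 800, seed = 42)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth, c2$truth)

  # planted class counts within 3 sigma of the multinomial expectation
  props <- spec$class_proportions
  counts <- table(factor(c1$truth$class, levels = names(props)))
  for (cl in names(props)) {
    expected <- 800 * props[[cl]]
    sdev <- sqrt(800 * props[[cl]] * (1 - props[[cl]]))
    expect_lte(abs(counts[[cl]] - expected), 3 * sdev + 1e-9)
  }

  expect_error(
    cohort_spec(class_proportions = c(increase = 0.5, decrease = 0.4)),
    "sum to 1"
  )
})

test_that("noiseless planted profiles satisfy their own class definitions", {
  co <- simulate_cohort(cohort_spec(
    n_genes = 400, seed = 9, noise_cv = 0,
    class_proportions = c(
      increase = 0.4, decrease = 0.3, stripe = 0.2, antistripe = 0.1
    )
  ))
  # increase-class genes are exactly monotone non-decreasing
  inc <- co$truth$gene_id[co$truth$class == "increase"]
  mono <- co$expression |>
    dplyr::filter(gene_id %in% inc, replicate == "rep1") |>
    dplyr::arrange(gene_id, dose) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(mono = all(diff(fpkm) >= 0))
  expect_true(all(mono$mono))

  # round-trip through the shape classifier recovers every planted class
  prof <- normalize_profiles(co$expression)
  sh <- classify_shapes(prof)
  m <- dplyr::inner_join(sh, co$truth, by = "gene_id")
  expect_equal(mean(m$shape == m$class), 1)
})

test_that("increase-class truth records the planted Hill parameters", {
  co <- simulate_cohort(cohort_spec(n_genes = 200, seed = 3, noise_cv = 0))
  inc <- dplyr::filter(co$truth, class == "increase")
  expect_true(all(is.finite(inc$a) & is.finite(inc$n)))
  other <- dplyr::filter(co$truth, class != "increase")
  expect_true(all(is.na(other$n)))

  # planted means reproduce hill() at every dose for one spot-checked gene
  g <- inc$gene_id[1]
  mu <- co$truth_profiles |>
    dplyr::filter(gene_id == g) |>
    dplyr::arrange(dose)
  expect_equal(
    mu$mean,
    hill(mu$dose, inc$a[1], inc$b[1], inc$k[1], inc$n[1])
  )
})
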