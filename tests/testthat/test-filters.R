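test_that("nonzero and expression filters apply their definitions", {
  e <- make_expr(list(
    silent = rep(0, 6),
    whisper = c(0.001, rep(0, 5)),
    low = c(0.4, 0.6, 0.8, 0.9, 0.95, 0.99),
    spike = c(0, 0, 1.5, 0, 0, 0)
  ))
  expect_setequal(filter_nonzero(e), c("whisper", "low", "spike"))
  expect_setequal(filter_expression(e), "spike")
  # the treated-only reading ignores detectability at dose zero
  e2 <- make_expr(list(basal_only = c(5, 0, 0, 0, 0, 0)))
  expect_equal(filter_expression(e2, scope = "all"), "basal_only")
  expect_equal(filter_expression(e2, scope = "treated"), character(0))
})

test_that("Kruskal-Wallis H equals brute-force rank arithmetic", {
  # frozen 3-groups-of-2 case: H = 12/(6*7) * [2*(1.5-3.5)^2 + 0 + 2*(5.5-3.5)^2]
  #                              = 32/7
  e <- make_expr(list(g = c(1, 3, 5, 2, 4, 6)), doses = c(0, 1, 2), n_rep = 2)
  kw <- kw_test(e)
  expect_equal(kw$statistic, 32 / 7)
  expect_equal(kw$statistic, brute_kw_h(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2)))
  expect_true(kw$small_groups)

  # randomized cases, with and without ties, across group layouts
  set.seed(33)
  for (layout in list(rep(1:3, each = 2), rep(1:4, each = 2), rep(1:3, each = 3))) {
    for (i in 1:10) {
      v <- round(rlnorm(length(layout), 1, 1), 1) # rounding induces ties
      doses <- seq_along(unique(layout)) - 1
      e <- make_expr(
        list(g = v[order(rep(doses, table(layout)))]),
        doses = doses, n_rep = length(layout) / length(doses)
      )
      # build directly instead: one gene, groups by dose
      e <- tibble::tibble(
        gene_id = "g", dose = rep(doses, table(layout)),
        replicate = paste0("rep", unlist(lapply(table(layout), seq_len))),
        fpkm = v
      )
      expect_equal(kw_test(e)$statistic, brute_kw_h(v, layout))
    }
  }

  # all observations identical: H = 0, p = 1 by convention
  e0 <- make_expr(list(g = rep(2, 6)))
  expect_equal(kw_test(e0)$statistic, 0)
  expect_equal(kw_test(e0)$p_value, 1)
})

test_that("chi-squared KW p-values are close to the exact permutation law", {
  # exhaustive enumeration of all distinct group assignments (N <= 9);
  # with 2-3 observations per group the chi-squared approximation deviates
  # from the exact law by up to ~0.17 (the bound documented in ?kw_test)
  set.seed(44)
  layouts <- list(rep(1:3, each = 2), rep(1:4, each = 2), rep(1:3, each = 3))
  for (g in layouts) {
    for (i in 1:5) {
      v <- round(rlnorm(length(g), 1, 1), 1)
      e <- tibble::tibble(
        gene_id = "g", dose = g - 1,
        replicate = paste0("rep", unlist(lapply(table(g), seq_len))),
        fpkm = v
      )
      p_impl <- kw_test(e)$p_value
      p_exact <- perm_kw_pvalue(v, g)
      expect_lt(abs(p_impl - p_exact), 0.17)
    }
  }
})

test_that("replicate correlation filter matches the closed-form t transform", {
  # strong but imperfect replicate agreement over 6 doses: the one-sided p
  # must equal the closed form p = P(T_4 > r * sqrt(4 / (1 - r^2)))
  v1 <- c(1, 2, 3, 4, 5, 6)
  v2 <- c(1.4, 1.9, 3.3, 3.8, 5.4, 5.9)
  e <- tibble::tibble(
    gene_id = "g",
    dose = rep(default_dose_grid(), 2),
    replicate = rep(c("rep1", "rep2"), each = 6),
    fpkm = abs(c(v1, v2))
  )
  rc <- replicate_correlation(e)
  r <- rc$r
  expect_equal(rc$p_value, pt(r * sqrt(4 / (1 - r^2)), 4, lower.tail = FALSE))

  # identical non-constant replicates: r = 1, p ~ 0 -> kept
  e1 <- make_expr(list(g = cbind(1:6, 1:6)))
  expect_equal(replicate_correlation(e1)$r, 1)
  expect_equal(filter_replicate_correlation(e1), "g")

  # exactly anti-correlated replicates are dropped by the one-sided test
  e2 <- make_expr(list(g = cbind(1:6, 6:1)))
  expect_equal(replicate_correlation(e2)$r, -1)
  expect_equal(filter_replicate_correlation(e2), character(0))

  # constant replicate -> degenerate, distinct label in the tree
  e3 <- make_expr(list(g = cbind(rep(2, 6), 1:6)))
  expect_true(replicate_correlation(e3)$degenerate)

  expect_error(
    replicate_correlation(make_expr(list(g = cbind(1:2, 2:1)), doses = 0:1)),
    ">= 3 doses"
  )
})

test_that("filter tree partitions the cohort and counts are non-increasing", {
  co <- simulate_cohort(cohort_spec(n_genes = 400, seed = 77, noise_cv = 0.05))
  led <- run_filter_tree(co$expression)
  counts <- stage_counts(led)

  expect_equal(counts[["input"]], 400)
  expect_true(all(diff(counts) <= 0))
  # every gene lands in exactly one bucket and buckets add up
  expect_equal(nrow(led), 400)
  expect_equal(anyDuplicated(led$gene_id), 0)
  drop_sum <- sum(led$stage != "responsive") + counts[["responsive"]]
  expect_equal(drop_sum, 400)
  expect_equal(sum(led$stage == "responsive"), counts[["responsive"]])

  # planted all-zero genes are exactly the nonzero-stage casualties
  n_zero <- sum(co$truth$class == "zero")
  expect_equal(counts[["input"]] - counts[["nonzero"]], n_zero)
})

test_that("raising alpha thresholds never shrinks the surviving set", {
  co <- simulate_cohort(cohort_spec(n_genes = 150, seed = 13, noise_cv = 0.2))
  e <- co$expression
  base_kw <- filter_kw(e, alpha = 0.2)
  wide_kw <- filter_kw(e, alpha = 0.5)
  expect_true(all(base_kw %in% wide_kw))
  expect_setequal(filter_kw(e, alpha = 1.0), unique(e$gene_id))

  base_rc <- filter_replicate_correlation(e, alpha = 0.05)
  wide_rc <- filter_replicate_correlation(e, alpha = 0.3)
  expect_true(all(base_rc %in% wide_rc))
})
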