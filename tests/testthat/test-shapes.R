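test_that("profiles normalize to replicate means scaled to max 1", {
  e <- make_expr(list(g = c(2, 4, 8, 8, 8, 8)))
  p <- normalize_profiles(e)
  expect_equal(p$value, c(0.25, 0.5, 1, 1, 1, 1))

  e2 <- make_expr(list(g = rep(5, 6)))
  expect_equal(normalize_profiles(e2)$value, rep(1, 6))

  # replicate averaging happens before scaling
  e3 <- make_expr(list(g = cbind(c(2, 4, 6, 8, 10, 12), c(4, 8, 12, 16, 20, 24))))
  expect_equal(normalize_profiles(e3)$value, (1:6) / 6)

  expect_error(normalize_profiles(make_expr(list(g = rep(0, 6)))), "all-zero")
})

test_that("shape classifier applies the deterministic four-class rule", {
  expect_equal(classify_profile(c(0.1, 0.2, 0.5, 0.8, 0.95, 1.0)), "increase")
  expect_equal(classify_profile(c(1.0, 0.8, 0.5, 0.3, 0.2, 0.1)), "decrease")
  expect_equal(classify_profile(c(0.2, 0.5, 1.0, 0.6, 0.3, 0.2)), "stripe")
  expect_equal(classify_profile(1 - c(0.2, 0.5, 1.0, 0.6, 0.3, 0.2)), "antistripe")
  # constant profiles hit the increase tie-break and get flagged
  e <- make_expr(list(g = rep(3, 6)))
  sh <- classify_shapes(normalize_profiles(e))
  expect_equal(sh$shape, "increase")
  expect_true(sh$flat_flag)
  # small dips within tolerance stay monotone
  expect_equal(classify_profile(c(0.1, 0.3, 0.28, 0.6, 0.8, 1.0)), "increase")
})

test_that("classification is invariant to positive rescaling", {
  set.seed(55)
  for (i in 1:25) {
    v <- runif(6)
    v <- v / max(v)
    c1 <- classify_profile(v)
    for (s in c(0.01, 1, 7, 1000)) {
      expect_equal(classify_profile(v * s / max(v * s)), c1)
    }
  }
})

test_that("growing the tolerance never reassigns monotone to interior classes", {
  set.seed(66)
  for (i in 1:40) {
    v <- runif(6)
    v <- v / max(v)
    shapes <- vapply(
      c(0, 0.02, 0.05, 0.1, 0.2), function(e) classify_profile(v, e), ""
    )
    mono_at <- shapes %in% c("increase", "decrease")
    # once monotone under some epsilon, monotone under every larger epsilon
    if (any(mono_at)) {
      expect_true(all(mono_at[which(mono_at)[1]:length(shapes)]))
    }
  }
})

test_that("clustering recovers planted archetypes and merges duplicates", {
  # two identical profiles merge at height 0
  p0 <- tibble::tibble(
    gene_id = rep(c("a", "b"), each = 3),
    dose = rep(0:2, 2), value = rep(c(0.1, 0.5, 1), 2)
  )
  cl0 <- cluster_profiles(p0)
  expect_equal(cl0$hclust$height, 0)
  expect_equal(max(cl0$labels$cluster), 1)

  # 3 archetypes (step-up, step-down, bump), 50 noisy copies each
  arch <- list(
    up = c(0.05, 0.1, 0.2, 0.8, 0.95, 1.0),
    down = c(1.0, 0.95, 0.8, 0.2, 0.1, 0.05),
    bump = c(0.1, 0.5, 1.0, 0.5, 0.2, 0.1)
  )
  set.seed(12)
  vals <- list()
  truth <- character()
  for (nm in names(arch)) {
    for (i in 1:50) {
      g <- paste0(nm, i)
      noisy <- arch[[nm]] * exp(rnorm(6, 0, sqrt(log(1 + 0.05^2))))
      vals[[g]] <- noisy / max(noisy)
      truth[g] <- nm
    }
  }
  prof <- tibble::tibble(
    gene_id = rep(names(vals), each = 6),
    dose = rep(default_dose_grid(), length(vals)),
    value = unlist(vals, use.names = FALSE)
  )
  cl <- cluster_profiles(prof, cut_height = 0.5)
  m <- cl$labels
  ari <- adjusted_rand(truth[m$gene_id], m$cluster)
  expect_gte(ari, 0.95)

  # Newick export round-trips through ape
  nwk <- write_newick(cl)
  expect_equal(length(ape::read.tree(text = nwk)$tip.label), 150)
})

test_that("PCA report conserves variance and flags degenerate input", {
  # rank-1 matrix: one component carries everything
  e <- make_expr(list(
    g1 = 1 * (1:6), g2 = 2 * (1:6), g3 = 3 * (1:6), g4 = 5 * (1:6)
  ))
  pr <- pca_report(e)
  expect_equal(pr$variance_explained[1], 1.0)
  expect_equal(sum(pr$variance_explained), 1.0, tolerance = 1e-9)

  co <- simulate_cohort(cohort_spec(n_genes = 60, seed = 21))
  pr2 <- pca_report(co$expression)
  expect_equal(sum(pr2$variance_explained), 1.0, tolerance = 1e-9)
  expect_equal(nrow(pr2$scores), 60)
  expect_equal(nrow(pr2$loadings), 6)

  flat <- make_expr(list(g1 = rep(1, 6), g2 = rep(1, 6)))
  expect_error(pca_report(flat), "constant")
})
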