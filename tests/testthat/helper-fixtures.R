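# Shared fixture builders. Everything is generated in code; no data files.

# A long expression tibble from a named list of per-gene cell values.
# `values[[gene]]` is a matrix doses x replicates (or a vector recycled
# across replicates).
make_expr <- function(values, doses = default_dose_grid(), n_rep = 2) {
  rows <- lapply(names(values), function(g) {
    v <- values[[g]]
    if (is.null(dim(v))) v <- matrix(v, length(doses), n_rep)
    tibble::tibble(
      gene_id = g,
      dose = rep(doses, times = ncol(v)),
      replicate = rep(paste0("rep", seq_len(ncol(v))), each = length(doses)),
      fpkm = as.vector(v)
    )
  })
  dplyr::bind_rows(rows)
}

# Brute-force Kruskal-Wallis H from rank arithmetic (independent of
# stats::kruskal.test), with the standard tie correction.
brute_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gm <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(ns * (gm - (N + 1) / 2)^2)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# All distinct permutations of a multiset of group labels (recursive).
multiset_perms <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  if (n == 1) {
    return(matrix(labels, 1, 1))
  }
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    sub <- multiset_perms(rest)
    out[[length(out) + 1]] <- cbind(u, sub)
  }
  do.call(rbind, out)
}

# Exact permutation p-value of the KW statistic: enumerate every distinct
# assignment of observations to groups (vectorised via rank reuse).
perm_kw_pvalue <- function(values, groups) {
  perms <- multiset_perms(groups)
  H_obs <- brute_kw_h(values, groups)
  H_all <- apply(perms, 1, function(g) brute_kw_h(values, g))
  mean(H_all >= H_obs - 1e-12)
}

# Adjusted Rand index between two label vectors (closed form from the
# contingency table; independent of any clustering package).
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  (a - expected) / (maxi - expected)
}
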