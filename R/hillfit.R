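#' Configuration for the Metropolis-Hastings Hill fit
#'
#' @param n_steps Total MCMC steps (default 100000).
#' @param burn_in_fraction Fraction of the chain discarded before
#'   summarizing, in `[0, 1)` (default 0.2). Proposal-scale adaptation runs
#'   inside the burn-in window (at most its first 10000 steps) and is
#'   frozen afterwards, so the retained chain has fixed proposals and
#'   detailed balance; `burn_in_fraction = 0` keeps every sample and
#'   disables adaptation.
#' @param proposal_scales Named standard deviations of the Gaussian
#'   random-walk proposal on the transformed coordinates
#'   `(log(a + a_offset), log b, log k, log n, log sigma)`.
#' @param prior_bounds Optional named list of `c(lo, hi)` bounds for
#'   `a`, `b`, `k`, `n`, `sigma`; defaults are derived from the data (see
#'   [default_prior_bounds()]). Priors are uniform on the transformed
#'   (log) coordinates within these bounds.
#' @param noise_sigma `"sampled"` (default): the observation-noise scale is
#'   a fifth chain coordinate under a half-normal prior; `"fixed"`: held at
#'   `sigma_fixed`.
#' @param sigma_fixed Noise scale used when `noise_sigma = "fixed"`.
#' @param sigma_prior_scale Scale of the half-normal prior on sigma.
#' @param scale Likelihood scale: `"log1p"` (default; Gaussian residuals
#'   between log1p-transformed observations and model, robust over the
#'   0-756 FPKM range and compatible with multiplicative noise) or
#'   `"raw"`.
#' @param a_offset Offset used in the `log(a + a_offset)` transform so that
#'   `a = 0` stays reachable.
#' @param mode_bin_width Histogram bin width for the binned posterior mode
#'   of the Hill coefficient (default 0.5).
#' @param seed Integer RNG seed; chains are deterministic given the seed.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_steps = 100000, burn_in_fraction = 0.2,
                       proposal_scales = c(
                         a = 0.15, b = 0.15, k = 0.15, n = 0.15, sigma = 0.15
                       ),
                       prior_bounds = NULL,
                       noise_sigma = c("sampled", "fixed"),
                       sigma_fixed = 0.2, sigma_prior_scale = 1,
                       scale = c("log1p", "raw"),
                       a_offset = 0.01,
                       mode_bin_width = 0.5, seed = 1L) {
  noise_sigma <- match.arg(noise_sigma)
  scale <- match.arg(scale)
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    abort("`burn_in_fraction` must be in [0, 1).")
  }
  if (mode_bin_width <= 0) abort("`mode_bin_width` must be > 0.")
  structure(
    list(
      n_steps = as.integer(n_steps), burn_in_fraction = burn_in_fraction,
      proposal_scales = proposal_scales, prior_bounds = prior_bounds,
      noise_sigma = noise_sigma, sigma_fixed = sigma_fixed,
      sigma_prior_scale = sigma_prior_scale, scale = scale,
      a_offset = a_offset, mode_bin_width = mode_bin_width,
      seed = as.integer(seed)
    ),
    class = "fit_config"
  )
}

#' Data-driven default prior bounds for the Hill fit
#'
#' Weakly informative, dose-grid-aware bounds: basal `a` up to the largest
#' observation; dynamic range `b` up to 10 times it; half-maximal dose `k`
#' from a tenth of the smallest positive dose to 10 times the largest;
#' Hill coefficient `n` in `[0.1, 100]` (the upper bound accommodates the
#' steepest responses seen empirically, n of order 76); noise scale in
#' `[1e-3, 10]`.
#'
#' @param doses Dose vector.
#' @param observations Observation vector (same length).
#' @return Named list of `c(lo, hi)` bounds for `a`, `b`, `k`, `n`,
#'   `sigma`.
#' @export
default_prior_bounds <- function(doses, observations) {
  ymax <- max(observations)
  if (ymax <= 0) ymax <- 1
  pos <- doses[doses > 0]
  list(
    a = c(0, ymax),
    b = c(ymax * 1e-4, 10 * ymax),
    k = c(min(pos) / 10, 10 * max(doses)),
    n = c(0.1, 100),
    sigma = c(1e-3, 10)
  )
}

#' Unnormalized log posterior of the Hill model
#'
#' Gaussian likelihood of the observations (optionally log1p-transformed,
#' the default) around the Hill curve, plus flat priors on the
#' log-transformed parameters inside `bounds` and a half-normal prior on
#' `sigma`. Returns `-Inf` outside the bounds.
#'
#' @param params Named vector/list with `a`, `b`, `k`, `n`.
#' @param doses,observations Paired numeric vectors (>= 4 pairs spanning
#'   >= 3 distinct doses).
#' @param sigma Observation-noise scale on the likelihood scale.
#' @param bounds Prior bounds as from [default_prior_bounds()].
#' @param scale `"log1p"` or `"raw"`.
#' @param sigma_prior_scale Half-normal prior scale for sigma.
#' @return A scalar log density (unnormalized), `-Inf` out of bounds.
#' @export
log_posterior <- function(params, doses, observations, sigma = 0.2,
                          bounds = default_prior_bounds(doses, observations),
                          scale = "log1p", sigma_prior_scale = 1) {
  params <- as.list(params)
  with_bounds <- function(v, b) v >= b[1] && v <= b[2]
  if (!with_bounds(params$a, bounds$a) || !with_bounds(params$b, bounds$b) ||
    !with_bounds(params$k, bounds$k) || !with_bounds(params$n, bounds$n) ||
    !with_bounds(sigma, bounds$sigma)) {
    return(-Inf)
  }
  m <- hill(doses, params$a, params$b, params$k, params$n)
  if (scale == "log1p") {
    y <- log1p(observations)
    m <- log1p(m)
  } else {
    y <- observations
  }
  sum(dnorm(y, m, sigma, log = TRUE)) - 0.5 * (sigma / sigma_prior_scale)^2
}

check_fit_data <- function(doses, observations) {
  if (length(doses) != length(observations)) {
    abort("`doses` and `observations` must have equal length")
  }
  if (length(doses) < 4 || length(unique(doses)) < 3) {
    abort("Hill fit needs >= 4 observations spanning >= 3 distinct doses")
  }
  if (any(!is.finite(observations)) || any(observations < 0)) {
    abort("observations must be finite and non-negative")
  }
}

extract_fit_data <- function(data) {
  ycol <- intersect(c("value", "fpkm"), names(data))[1]
  if (!"dose" %in% names(data) || is.na(ycol)) {
    abort("`data` must have a `dose` column and a `value` or `fpkm` column")
  }
  list(doses = data$dose, observations = data[[ycol]])
}

#' Fit a Hill function by Metropolis-Hastings MCMC
#'
#' Random-walk Metropolis-Hastings on the transformed coordinates
#' `(log(a + a_offset), log b, log k, log n[, log sigma])`, targeting
#' [log_posterior()]. Proposal scales are adapted towards ~30% acceptance
#' during (at most the first 10000 steps of) the burn-in window and then
#' frozen; posterior summaries use the post-burn-in chain only. The
#' point estimate of each parameter is its posterior mode; the Hill
#' coefficient additionally gets a binned mode (histogram bins of width
#' `mode_bin_width`, ties broken toward the lower bin) and the gene is
#' called ultrasensitive when that binned mode lies above 1.
#'
#' @param data Tibble with a `dose` column and a `value` (or `fpkm`)
#'   column; replicate observations are separate rows.
#' @param config A [fit_config()].
#' @return An object of class `hill_fit`: list with `samples` (post-burn-in
#'   tibble of `a`, `b`, `k`, `n`, `sigma`, `log_post`), `modes` (marginal
#'   posterior modes), `map` (joint maximum-a-posteriori sample — the chain
#'   state with the highest log posterior, the analogue of a least-squares
#'   optimum), `n_binned_mode`, `ultrasensitive`, `acceptance_rate`,
#'   `flags`, `data`, `config`.
#' @export
#' @examples
#' d <- sample_hill_profile(c(a = 0.1, b = 0.9, k = 8.33, n = 4),
#'   noise_cv = 0.05, seed = 1
#' )
#' fit <- mh_fit(d, fit_config(n_steps = 2000, seed = 1))
#' glance(fit)
mh_fit <- function(data, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  fd <- extract_fit_data(data)
  x <- fd$doses
  y <- fd$observations
  check_fit_data(x, y)
  set.seed(config$seed)

  flags <- character()
  if (length(unique(y)) == 1) {
    return(structure(
      list(
        samples = tibble::tibble(
          a = numeric(), b = numeric(), k = numeric(), n = numeric(),
          sigma = numeric(), log_post = numeric()
        ),
        modes = c(a = NA_real_, b = NA_real_, k = NA_real_, n = NA_real_),
        map = c(
          a = NA_real_, b = NA_real_, k = NA_real_, n = NA_real_,
          sigma = NA_real_
        ),
        n_binned_mode = NA_real_, ultrasensitive = NA,
        acceptance_rate = NA_real_, flags = "unidentifiable",
        data = tibble::tibble(dose = x, value = y), config = config
      ),
      class = "hill_fit"
    ))
  }

  bounds <- config$prior_bounds %||% default_prior_bounds(x, y)
  d <- config$a_offset
  sample_sigma <- config$noise_sigma == "sampled"
  npar <- if (sample_sigma) 5L else 4L

  ty <- if (config$scale == "log1p") log1p(y) else y
  pos <- x > 0
  lx <- log(x[pos])
  s0 <- config$sigma_prior_scale

  # log posterior on transformed coordinates (flat prior there = log-uniform
  # on natural scale; the sigma Jacobian is absorbed by the flat-in-log prior)
  tlo <- c(
    log(bounds$a[1] + d), log(bounds$b[1]), log(bounds$k[1]), log(bounds$n[1])
  )
  thi <- c(
    log(bounds$a[2] + d), log(bounds$b[2]), log(bounds$k[2]), log(bounds$n[2])
  )
  if (sample_sigma) {
    tlo <- c(tlo, log(bounds$sigma[1]))
    thi <- c(thi, log(bounds$sigma[2]))
  }
  lp <- function(th) {
    if (any(th < tlo) || any(th > thi)) {
      return(-Inf)
    }
    a <- exp(th[1]) - d
    b <- exp(th[2])
    k <- exp(th[3])
    n <- exp(th[4])
    s <- if (sample_sigma) exp(th[5]) else config$sigma_fixed
    m <- numeric(length(x))
    m[pos] <- a + b * stats::plogis(n * (lx - log(k)))
    m[!pos] <- a
    if (config$scale == "log1p") m <- log1p(m)
    sum(dnorm(ty, m, s, log = TRUE)) - 0.5 * (s / s0)^2
  }

  # initial state: data-driven, clamped into bounds
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  th <- c(
    log(clamp(min(y), bounds$a[1], bounds$a[2]) + d),
    log(clamp(max(y) - min(y), bounds$b[1], bounds$b[2])),
    log(clamp(median(x[pos]), bounds$k[1], bounds$k[2])),
    log(1)
  )
  if (sample_sigma) th <- c(th, log(0.2))
  sc <- unname(config$proposal_scales[seq_len(npar)])

  n_steps <- config$n_steps
  burn <- floor(config$burn_in_fraction * n_steps)
  adapt_end <- min(10000L, burn)
  chain <- matrix(NA_real_, n_steps, npar)
  lp_trace <- numeric(n_steps)
  cur <- lp(th)
  if (!is.finite(cur)) {
    # nudge into the interior if the data-driven start is out of bounds
    th <- (tlo + thi) / 2
    cur <- lp(th)
  }
  acc_window <- 0L
  acc_post <- 0L
  for (i in seq_len(n_steps)) {
    prop <- th + rnorm(npar) * sc
    lpp <- lp(prop)
    if (lpp - cur > log(runif(1))) {
      th <- prop
      cur <- lpp
      acc_window <- acc_window + 1L
      if (i > burn) acc_post <- acc_post + 1L
    }
    chain[i, ] <- th
    lp_trace[i] <- cur
    if (i <= adapt_end && i %% 100L == 0L) {
      rate <- acc_window / 100
      sc <- sc * clamp(exp(rate - 0.3), 0.7, 1.4)
      acc_window <- 0L
    } else if (i %% 100L == 0L) {
      acc_window <- 0L
    }
  }

  keep <- (burn + 1L):n_steps
  acceptance_rate <- acc_post / length(keep)
  if (acceptance_rate < 0.05 || acceptance_rate > 0.8) {
    flags <- c(flags, "acceptance_rate_extreme")
    warn(sprintf(
      "acceptance rate %.3f outside [0.05, 0.8] after adaptation",
      acceptance_rate
    ))
  }
  nat <- exp(chain[keep, , drop = FALSE])
  nat[, 1] <- nat[, 1] - d
  samples <- tibble::tibble(
    a = nat[, 1], b = nat[, 2], k = nat[, 3], n = nat[, 4],
    sigma = if (sample_sigma) nat[, 5] else config$sigma_fixed,
    log_post = lp_trace[keep]
  )
  modes <- c(
    a = density_mode(samples$a), b = density_mode(samples$b),
    k = density_mode(samples$k), n = density_mode(samples$n)
  )
  imap <- which.max(samples$log_post)
  map <- c(
    a = samples$a[imap], b = samples$b[imap], k = samples$k[imap],
    n = samples$n[imap], sigma = samples$sigma[imap]
  )
  bm <- binned_mode(samples$n, config$mode_bin_width)
  structure(
    list(
      samples = samples, modes = modes, map = map, n_binned_mode = bm,
      ultrasensitive = bm > 1, acceptance_rate = acceptance_rate,
      flags = flags, data = tibble::tibble(dose = x, value = y),
      config = config
    ),
    class = "hill_fit"
  )
}

# posterior mode via kernel density argmax (falls back to median for
# near-degenerate samples where the bandwidth collapses)
density_mode <- function(v) {
  if (length(unique(v)) < 10 || stats::bw.nrd0(v) <= 0) {
    return(median(v))
  }
  dd <- stats::density(v, n = 512)
  dd$x[which.max(dd$y)]
}

# histogram mode with fixed-width bins anchored at 0; ties toward the
# lower bin; returns the bin midpoint
binned_mode <- function(v, width = 0.5) {
  idx <- floor(v / width)
  tab <- table(idx)
  win <- min(as.numeric(names(tab))[tab == max(tab)]) # tie -> lower bin
  (win + 0.5) * width
}

#' @export
print.hill_fit <- function(x, ...) {
  if ("unidentifiable" %in% x$flags) {
    cat("<hill_fit> unidentifiable (constant observations)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> modes: a=%.3g b=%.3g k=%.3g n=%.3g | binned n mode %.2f (%s) | acc %.2f\n",
    x$modes["a"], x$modes["b"], x$modes["k"], x$modes["n"],
    x$n_binned_mode,
    if (isTRUE(x$ultrasensitive)) "ultrasensitive" else "not ultrasensitive",
    x$acceptance_rate
  ))
  invisible(x)
}

#' Exhaustive grid-search least-squares Hill fit
#'
#' Brute-force oracle for validating the MCMC fit: evaluates the residual
#' sum of squares (on the likelihood scale) over a full grid of parameter
#' combinations inside the prior bounds and returns the argmin. `a` is
#' gridded linearly, `b`, `k`, `n` geometrically.
#'
#' @param data Tibble with `dose` and `value`/`fpkm` columns.
#' @param bounds Prior bounds (default from [default_prior_bounds()]).
#' @param resolution Grid points per parameter (default 20, i.e. 20^4
#'   combinations).
#' @param scale Likelihood scale, `"log1p"` (default) or `"raw"`.
#' @return One-row tibble `a`, `b`, `k`, `n`, `rss`, with attribute `grid`
#'   (the per-parameter grids).
#' @export
grid_oracle <- function(data, bounds = NULL, resolution = 20,
                        scale = c("log1p", "raw")) {
  scale <- match.arg(scale)
  fd <- extract_fit_data(data)
  x <- fd$doses
  y <- fd$observations
  check_fit_data(x, y)
  bounds <- bounds %||% default_prior_bounds(x, y)
  grid <- list(
    a = seq(bounds$a[1], bounds$a[2], length.out = resolution),
    b = exp(seq(log(bounds$b[1]), log(bounds$b[2]), length.out = resolution)),
    k = exp(seq(log(bounds$k[1]), log(bounds$k[2]), length.out = resolution)),
    n = exp(seq(log(bounds$n[1]), log(bounds$n[2]), length.out = resolution))
  )
  ty <- if (scale == "log1p") log1p(y) else y
  kn <- tidyr::expand_grid(k = grid$k, n = grid$n)
  # response ratio r(x) = x^n/(k^n + x^n) for every (k, n) combo: rows combos
  pos <- x > 0
  R <- matrix(0, nrow(kn), length(x))
  R[, pos] <- stats::plogis(
    outer(kn$n, rep(1, sum(pos))) *
      (matrix(log(x[pos]), nrow(kn), sum(pos), byrow = TRUE) - log(kn$k))
  )
  best <- list(rss = Inf)
  for (a in grid$a) {
    for (b in grid$b) {
      m <- a + b * R
      tm <- if (scale == "log1p") log1p(m) else m
      rss <- rowSums((tm - matrix(ty, nrow(kn), length(x), byrow = TRUE))^2)
      j <- which.min(rss)
      if (rss[j] < best$rss) {
        best <- list(a = a, b = b, k = kn$k[j], n = kn$n[j], rss = rss[j])
      }
    }
  }
  out <- tibble::as_tibble(best[c("a", "b", "k", "n", "rss")])
  attr(out, "grid") <- grid
  out
}

#' Fit Hill functions across a gene cohort
#'
#' Runs [mh_fit()] for each gene (both replicates enter as observations),
#' derives per-gene seeds from the config seed, and tabulates posterior
#' modes, binned Hill-coefficient modes, and ultrasensitivity calls.
#' Per-gene failures are recorded in the `error` column and do not stop
#' the cohort run.
#'
#' @param expr Long expression tibble.
#' @param genes Gene ids to fit (typically the increase-class genes).
#' @param config A [fit_config()].
#' @return A tibble of class `hill_cohort` with one row per gene:
#'   `gene_id`, `a_mode`, `b_mode`, `k_mode`, `n_mode`, `n_binned_mode`,
#'   `acceptance_rate`, `ultrasensitive`, `flags`, `error`.
#' @export
fit_cohort <- function(expr, genes, config = fit_config()) {
  check_expression(expr)
  genes <- unique(genes)
  if (length(genes) == 0) {
    out <- tibble::tibble(
      gene_id = character(), a_mode = numeric(), b_mode = numeric(),
      k_mode = numeric(), n_mode = numeric(), n_binned_mode = numeric(),
      acceptance_rate = numeric(), ultrasensitive = logical(),
      flags = character(), error = character()
    )
    class(out) <- c("hill_cohort", class(out))
    attr(out, "bin_width") <- config$mode_bin_width
    return(out)
  }
  by_gene <- expr |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_split()
  names(by_gene) <- vapply(by_gene, function(d) d$gene_id[1], "")
  by_gene <- by_gene[intersect(genes, names(by_gene))]

  rows <- purrr::imap(by_gene, function(d, g) {
    cfg <- config
    cfg$seed <- (config$seed + match(g, genes)) %% .Machine$integer.max
    res <- tryCatch(
      {
        fit <- mh_fit(dplyr::select(d, "dose", value = "fpkm"), cfg)
        tibble::tibble(
          gene_id = g,
          a_mode = unname(fit$modes["a"]), b_mode = unname(fit$modes["b"]),
          k_mode = unname(fit$modes["k"]), n_mode = unname(fit$modes["n"]),
          n_binned_mode = fit$n_binned_mode,
          acceptance_rate = fit$acceptance_rate,
          ultrasensitive = fit$ultrasensitive,
          flags = paste(fit$flags, collapse = ";"),
          error = NA_character_
        )
      },
      error = function(e) {
        tibble::tibble(
          gene_id = g, a_mode = NA_real_, b_mode = NA_real_, k_mode = NA_real_,
          n_mode = NA_real_, n_binned_mode = NA_real_,
          acceptance_rate = NA_real_, ultrasensitive = NA,
          flags = "error", error = conditionMessage(e)
        )
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hill_cohort", class(out))
  attr(out, "bin_width") <- config$mode_bin_width
  out
}

#' Histogram of binned Hill-coefficient modes across a cohort
#'
#' Bin edges sit at 0, `bin_width`, `2 * bin_width`, ... as in the cohort
#' summary figure convention.
#'
#' @param fits A [fit_cohort()] result.
#' @param bin_width Bin width (default: the width stored on `fits`).
#' @return A tibble `bin_lo`, `bin_hi`, `count`, plus counts of
#'   ultrasensitive (n > 1) and non-ultrasensitive genes as attributes
#'   `n_above_1` and `n_at_most_1`.
#' @export
hill_histogram <- function(fits, bin_width = NULL) {
  bin_width <- bin_width %||% attr(fits, "bin_width") %||% 0.5
  v <- fits$n_binned_mode[!is.na(fits$n_binned_mode)]
  if (length(v) == 0) {
    out <- tibble::tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer())
  } else {
    idx <- floor(v / bin_width + 1e-9)
    tab <- table(factor(idx, levels = 0:max(idx)))
    out <- tibble::tibble(
      bin_lo = as.numeric(names(tab)) * bin_width,
      bin_hi = (as.numeric(names(tab)) + 1) * bin_width,
      count = as.integer(tab)
    )
  }
  attr(out, "n_above_1") <- sum(fits$ultrasensitive, na.rm = TRUE)
  attr(out, "n_at_most_1") <- sum(!fits$ultrasensitive, na.rm = TRUE)
  out
}
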