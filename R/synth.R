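#' Parameters of the bimodal baseline-expression mixture
#'
#' Baseline FPKM levels in a typical bulk transcriptome are bimodal on the
#' log scale, with an antimode near 1 FPKM separating a minority of barely
#' detected genes from the actively expressed majority. The generator models
#' this as a two-component lognormal mixture; `w_low` is the weight of the
#' sub-1-FPKM component.
#'
#' @param w_low Weight of the low-expression component, in `[0, 1]`.
#' @param meanlog_low,sdlog_low Lognormal parameters of the low component.
#' @param meanlog_high,sdlog_high Lognormal parameters of the high component.
#' @return A named list of class `basal_mixture`.
#' @export
basal_mixture <- function(w_low = 0.28,
                          meanlog_low = log(0.15), sdlog_low = 0.6,
                          meanlog_high = log(20), sdlog_high = 1.2) {
  if (w_low < 0 || w_low > 1) abort("`w_low` must be in [0, 1].")
  if (sdlog_low <= 0 || sdlog_high <= 0) abort("sdlog parameters must be > 0.")
  structure(
    list(
      w_low = w_low, meanlog_low = meanlog_low, sdlog_low = sdlog_low,
      meanlog_high = meanlog_high, sdlog_high = sdlog_high
    ),
    class = "basal_mixture"
  )
}

#' Draw baseline expression levels from the bimodal mixture
#'
#' @param n_genes Number of levels to draw.
#' @param mixture A [basal_mixture()].
#' @param seed Optional integer seed (sets the RNG).
#' @return Numeric vector of `n_genes` non-negative FPKM levels.
#' @export
#' @examples
#' x <- sample_basal_distribution(1000, seed = 1)
#' mean(x < 1) # close to the low-component weight
sample_basal_distribution <- function(n_genes, mixture = basal_mixture(),
                                      seed = NULL) {
  stopifnot(inherits(mixture, "basal_mixture"), n_genes >= 0)
  if (!is.null(seed)) set.seed(seed)
  low <- runif(n_genes) < mixture$w_low
  out <- numeric(n_genes)
  out[low] <- rlnorm(sum(low), mixture$meanlog_low, mixture$sdlog_low)
  out[!low] <- rlnorm(sum(!low), mixture$meanlog_high, mixture$sdlog_high)
  out
}

#' Default sampling ranges for planted Hill parameters
#'
#' Ranges span the regimes seen when fitting empirical dose responses:
#' basal levels up to a few FPKM, dynamic ranges up to 1000 FPKM,
#' half-maximal doses inside the dose grid, and Hill coefficients from
#' negative cooperativity (0.3) to strongly switch-like (10).
#'
#' @return A named list of length-2 numeric ranges for `a`, `b`, `k`, `n`.
#' @export
hill_ranges <- function() {
  list(a = c(0, 5), b = c(1, 1000), k = c(0.5, 16.7), n = c(0.3, 10))
}

#' Specification of a synthetic expression cohort
#'
#' Bundles everything [simulate_cohort()] needs: the number of genes, the
#' mix of planted dose-response classes, the dose grid, replication, the
#' replicate-noise level, the baseline-expression mixture, and the Hill
#' parameter sampling ranges.
#'
#' Planted classes:
#' \describe{
#'   \item{zero}{silent gene, FPKM 0 in every cell}
#'   \item{low}{flat expression below 1 FPKM in every condition}
#'   \item{flat}{dose-independent expression above 1 FPKM}
#'   \item{increase}{monotone Hill activation with recorded `(a, b, k, n)`}
#'   \item{decrease}{monotone Hill repression (mirrored Hill)}
#'   \item{stripe}{unimodal bump with an interior global maximum}
#'   \item{antistripe}{unimodal dip with an interior global minimum}
#' }
#'
#' The default proportions plant 5% silent and 28% sub-1-FPKM genes, and
#' split the responsive remainder 51/36/12.5/0.1 between increase, decrease,
#' stripe, and antistripe — the split observed in HGF-treated MDCK cysts.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric vector over (a subset of) the
#'   classes above; must sum to 1.
#' @param dose_grid Strictly increasing non-negative doses, length >= 4.
#' @param n_replicates Biological replicates per condition, >= 2.
#' @param noise_cv Coefficient of variation of the replicate noise
#'   (dimensionless, >= 0).
#' @param noise_model `"lognormal"` (multiplicative, unit median; default)
#'   or `"additive"` (Gaussian with sd `noise_cv * mean`, clamped at 0).
#' @param basal A [basal_mixture()] for baseline levels.
#' @param ranges Hill parameter sampling ranges, see [hill_ranges()].
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the full spec including this seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 1000,
                        class_proportions = c(
                          zero = 0.05, low = 0.28,
                          increase = 0.345, decrease = 0.241,
                          stripe = 0.083, antistripe = 0.001
                        ),
                        dose_grid = default_dose_grid(),
                        n_replicates = 2,
                        noise_cv = 0.1,
                        noise_model = c("lognormal", "additive"),
                        basal = basal_mixture(),
                        ranges = hill_ranges(),
                        seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_dose_grid(dose_grid)
  known <- c("zero", "low", "flat", "increase", "decrease", "stripe", "antistripe")
  if (is.null(names(class_proportions)) ||
    !all(names(class_proportions) %in% known)) {
    abort(paste0(
      "`class_proportions` must be named with classes among: ",
      paste(known, collapse = ", ")
    ))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1.")
  }
  if (any(class_proportions < 0)) abort("`class_proportions` must be >= 0.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  stopifnot(inherits(basal, "basal_mixture"))
  structure(
    list(
      n_genes = as.integer(n_genes),
      class_proportions = class_proportions,
      dose_grid = dose_grid,
      n_replicates = as.integer(n_replicates),
      noise_cv = noise_cv,
      noise_model = noise_model,
      basal = basal,
      ranges = ranges,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Multiplicative lognormal noise with unit median and the requested CV;
# sdlog solves CV^2 = exp(sdlog^2) - 1.
noise_factor <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

apply_noise <- function(means, cv, model) {
  if (model == "lognormal") {
    means * noise_factor(length(means), cv)
  } else {
    pmax(0, means + rnorm(length(means), 0, cv * means))
  }
}

#' Sample noisy replicate observations from a Hill dose response
#'
#' @param params Named vector or list with elements `a`, `b`, `k`, `n`.
#' @param dose_grid Doses at which to observe the curve.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 returns the exact Hill curve.
#' @param n_replicates Replicates per dose.
#' @param seed Optional integer seed.
#' @param noise_model See [cohort_spec()].
#' @return A tibble with columns `dose`, `replicate`, `value`.
#' @export
#' @examples
#' sample_hill_profile(c(a = 0.1, b = 0.9, k = 8.33, n = 4),
#'   noise_cv = 0, n_replicates = 2
#' )
sample_hill_profile <- function(params, dose_grid = default_dose_grid(),
                                noise_cv = 0.1, n_replicates = 2, seed = NULL,
                                noise_model = c("lognormal", "additive")) {
  noise_model <- match.arg(noise_model)
  params <- as.list(params)
  check_hill_params(params$a, params$b, params$k, params$n)
  check_dose_grid(dose_grid)
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  means <- hill(dose_grid, params$a, params$b, params$k, params$n)
  tibble::tibble(
    dose = rep(dose_grid, times = n_replicates),
    replicate = rep(paste0("rep", seq_len(n_replicates)), each = length(dose_grid)),
    value = apply_noise(rep(means, times = n_replicates), noise_cv, noise_model)
  )
}

# Truncated lognormal draw via inverse-CDF so the rejection never loops.
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# Draw one planted mean profile for a class. Responsive classes are
# rejection-sampled until the noiseless max-normalised profile satisfies the
# shape classifier's definition of the class (guaranteeing the noiseless
# round-trip through classify_shapes), which a small fraction of raw draws
# (e.g. near-flat repression curves) would not.
planted_profile <- function(class, spec) {
  grid <- spec$dose_grid
  nd <- length(grid)
  bm <- spec$basal
  r <- spec$ranges
  draw <- function() {
    switch(class,
      zero = list(means = rep(0, nd), params = NULL),
      low = list(
        means = rep(rlnorm_trunc(1, bm$meanlog_low, bm$sdlog_low, upper = 1), nd),
        params = NULL
      ),
      flat = list(
        means = rep(rlnorm_trunc(1, bm$meanlog_high, bm$sdlog_high, lower = 1), nd),
        params = NULL
      ),
      increase = {
        p <- c(
          a = runif(1, r$a[1], r$a[2]), b = runif_log(1, r$b),
          k = runif_log(1, r$k), n = runif_log(1, r$n)
        )
        list(means = hill(grid, p["a"], p["b"], p["k"], p["n"]), params = p)
      },
      decrease = {
        p <- c(
          a = runif(1, r$a[1], r$a[2]), b = runif_log(1, r$b),
          k = runif_log(1, r$k), n = runif_log(1, r$n)
        )
        m <- p["a"] + p["b"] - hill(grid, 0, p["b"], p["k"], p["n"])
        list(means = unname(m), params = NULL)
      },
      stripe = {
        base <- rlnorm_trunc(1, bm$meanlog_high, bm$sdlog_high, lower = 1)
        amp <- base * runif(1, 1, 5)
        j0 <- sample(2:(nd - 1), 1)
        w <- runif(1, 0.5, 1.2)
        j <- seq_len(nd)
        list(means = base + amp * exp(-(j - j0)^2 / (2 * w^2)), params = NULL)
      },
      antistripe = {
        base <- rlnorm_trunc(1, bm$meanlog_high, bm$sdlog_high, lower = 1)
        depth <- runif(1, 0.3, 0.9)
        j0 <- sample(2:(nd - 1), 1)
        w <- runif(1, 0.5, 1.2)
        j <- seq_len(nd)
        list(means = base * (1 - depth * exp(-(j - j0)^2 / (2 * w^2))), params = NULL)
      },
      abort(paste0("unknown class: ", class))
    )
  }
  if (!class %in% c("increase", "decrease", "stripe", "antistripe")) {
    return(draw())
  }
  for (i in 1:100) {
    cand <- draw()
    got <- classify_profile(cand$means / max(cand$means), epsilon = 0.05)
    if (got == class) {
      return(cand)
    }
  }
  abort(paste0("failed to draw a valid '", class, "' profile in 100 tries"))
}

#' Generate a synthetic expression cohort with known ground truth
#'
#' Draws per-gene dose-response classes from the spec's proportions, builds
#' the noiseless mean profile for each gene (see [cohort_spec()] for the
#' class definitions), then adds per-cell replicate noise. The return value
#' carries the full planted truth so recovery can be scored at every
#' pipeline stage.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{expression}{long tibble `gene_id`, `dose`, `replicate`, `fpkm`}
#'     \item{truth}{tibble `gene_id`, `class`, and for increase-class genes
#'       the planted `a`, `b`, `k`, `n` (NA otherwise)}
#'     \item{truth_profiles}{tibble `gene_id`, `dose`, `mean` of the
#'       noiseless planted profile}
#'     \item{spec}{the input spec}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_genes = 50, seed = 7))
#' dplyr::count(cohort$truth, class)
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  classes <- sample(names(spec$class_proportions), n,
    replace = TRUE, prob = spec$class_proportions
  )
  gene_ids <- sprintf("g%05d", seq_len(n))
  nd <- length(spec$dose_grid)

  drawn <- purrr::map(classes, planted_profile, spec = spec)
  mean_mat <- do.call(rbind, purrr::map(drawn, "means"))
  params <- purrr::map(drawn, "params")

  reps <- paste0("rep", seq_len(spec$n_replicates))
  expression <- tidyr::expand_grid(
    gene_id = gene_ids, replicate = reps, dose = spec$dose_grid
  )
  # expand_grid iterates dose fastest, then replicate, then gene; build the
  # matching vector of per-cell means before adding noise
  mu_full <- as.vector(t(mean_mat)[, rep(seq_len(n), each = spec$n_replicates)])
  expression$fpkm <- apply_noise(mu_full, spec$noise_cv, spec$noise_model)
  expression <- dplyr::select(
    expression, "gene_id", "dose", "replicate", "fpkm"
  )

  truth <- tibble::tibble(
    gene_id = gene_ids,
    class = classes,
    a = purrr::map_dbl(params, ~ if (is.null(.x)) NA_real_ else .x[["a"]]),
    b = purrr::map_dbl(params, ~ if (is.null(.x)) NA_real_ else .x[["b"]]),
    k = purrr::map_dbl(params, ~ if (is.null(.x)) NA_real_ else .x[["k"]]),
    n = purrr::map_dbl(params, ~ if (is.null(.x)) NA_real_ else .x[["n"]])
  )
  truth_profiles <- tibble::tibble(
    gene_id = rep(gene_ids, each = nd),
    dose = rep(spec$dose_grid, times = n),
    mean = as.vector(t(mean_mat))
  )
  structure(
    list(
      expression = expression, truth = truth,
      truth_profiles = truth_profiles, spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort>", x$spec$n_genes, "genes,",
    length(x$spec$dose_grid), "doses,", x$spec$n_replicates,
    "replicates, noise_cv =", x$spec$noise_cv, "\n"
  )
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}
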