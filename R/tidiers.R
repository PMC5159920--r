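#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Hill fit
#'
#' @param x A [mh_fit()] result.
#' @param type `"summary"` (one row per parameter: posterior mode, mean,
#'   median, central 95% interval) or `"samples"` (the post-burn-in chain).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hill_fit <- function(x, type = c("summary", "samples"), ...) {
  type <- match.arg(type)
  if (type == "samples") {
    return(x$samples)
  }
  if (nrow(x$samples) == 0) {
    return(tibble::tibble(
      term = character(), mode = numeric(), mean = numeric(),
      median = numeric(), conf.low = numeric(), conf.high = numeric()
    ))
  }
  purrr::map_dfr(c("a", "b", "k", "n"), function(p) {
    v <- x$samples[[p]]
    tibble::tibble(
      term = p,
      mode = unname(x$modes[p]),
      mean = mean(v), median = median(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975))
    )
  })
}

#' One-row summary of a Hill fit
#'
#' @param x A [mh_fit()] result.
#' @param ... Unused.
#' @return A one-row tibble with parameter modes, the binned Hill
#'   coefficient mode, the ultrasensitivity call, the acceptance rate and
#'   chain length.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    a_mode = unname(x$modes["a"]), b_mode = unname(x$modes["b"]),
    k_mode = unname(x$modes["k"]), n_mode = unname(x$modes["n"]),
    n_binned_mode = x$n_binned_mode,
    ultrasensitive = x$ultrasensitive,
    acceptance_rate = x$acceptance_rate,
    n_samples = nrow(x$samples),
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy a PCA report
#'
#' @param x A [pca_report()] result.
#' @param type `"variance"`, `"scores"` or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pca_report <- function(x, type = c("variance", "scores", "loadings"), ...) {
  type <- match.arg(type)
  switch(type,
    variance = tibble::tibble(
      component = paste0("PC", seq_along(x$variance_explained)),
      variance_explained = x$variance_explained
    ),
    scores = x$scores,
    loadings = x$loadings
  )
}

#' Tidy a filter ledger
#'
#' @param x A [run_filter_tree()] result.
#' @param ... Unused.
#' @return The per-gene ledger as a plain tibble.
#' @export
tidy.filter_ledger <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "filter_ledger")
  out
}

#' One-row summary of a filter ledger
#'
#' @param x A [run_filter_tree()] result.
#' @param ... Unused.
#' @return A one-row tibble of per-stage survivor counts.
#' @export
glance.filter_ledger <- function(x, ...) {
  tibble::as_tibble(as.list(stage_counts(x)))
}
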