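#' Max-normalized, replicate-averaged dose-response profiles
#'
#' Per gene: average the replicates within each dose, then divide by the
#' maximum across doses, so every profile peaks at exactly 1 and the shape
#' of the response — not the magnitude of expression — drives clustering
#' and classification.
#'
#' @param expr Long expression tibble.
#' @param genes Optional subset of gene ids (e.g. the responsive set).
#' @return A tibble `gene_id`, `dose`, `value` with `value` in `[0, 1]` and
#'   per-gene maximum exactly 1.
#' @export
#' @examples
#' expr <- sample_hill_profile(c(a = 1, b = 3, k = 4, n = 2), noise_cv = 0)
#' expr <- dplyr::mutate(expr, gene_id = "g1", fpkm = value)
#' normalize_profiles(expr)
normalize_profiles <- function(expr, genes = NULL) {
  check_expression(expr)
  if (!is.null(genes)) expr <- dplyr::filter(expr, .data$gene_id %in% genes)
  out <- condition_means(expr) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(value = .data$mean_fpkm / max(.data$mean_fpkm)) |>
    dplyr::ungroup()
  if (anyNA(out$value)) {
    bad <- unique(out$gene_id[is.na(out$value)])
    abort(paste0(
      "cannot normalize all-zero gene(s): ", paste(head(bad, 3), collapse = ", ")
    ))
  }
  dplyr::select(out, "gene_id", "dose", "value") |>
    dplyr::arrange(.data$gene_id, .data$dose)
}

#' Classify a single normalized profile
#'
#' Deterministic shape rule on a max-normalized profile `v` with
#' monotonicity tolerance `epsilon`:
#' \itemize{
#'   \item *increase*: every successive step `>= -epsilon`;
#'   \item *decrease*: every successive step `<= +epsilon`;
#'   \item *stripe*: global maximum interior and both boundary values below
#'     `max - epsilon`;
#'   \item *antistripe*: global minimum interior and both boundary values
#'     above `min + epsilon`;
#'   \item *ambiguous* otherwise.
#' }
#' Ties are broken in the priority order increase > decrease > stripe >
#' antistripe, so a constant profile classifies as increase (callers flag
#' such profiles separately, see [classify_shapes()]).
#'
#' @param values Numeric profile of length >= 3 (normally in `[0, 1]`).
#' @param epsilon Monotonicity tolerance (default 0.05); 0 gives strict
#'   monotonicity.
#' @return One of `"increase"`, `"decrease"`, `"stripe"`, `"antistripe"`,
#'   `"ambiguous"`.
#' @export
#' @examples
#' classify_profile(c(0.1, 0.2, 0.5, 0.8, 0.95, 1))
#' classify_profile(c(0.2, 0.5, 1, 0.6, 0.3, 0.2))
classify_profile <- function(values, epsilon = 0.05) {
  if (length(values) < 3) abort("profile must have length >= 3")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  steps <- diff(values)
  if (all(steps >= -epsilon)) {
    return("increase")
  }
  if (all(steps <= epsilon)) {
    return("decrease")
  }
  imax <- which.max(values)
  interior_max <- imax > 1 && imax < length(values)
  if (interior_max &&
    values[1] < max(values) - epsilon &&
    values[length(values)] < max(values) - epsilon) {
    return("stripe")
  }
  imin <- which.min(values)
  interior_min <- imin > 1 && imin < length(values)
  if (interior_min &&
    values[1] > min(values) + epsilon &&
    values[length(values)] > min(values) + epsilon) {
    return("antistripe")
  }
  "ambiguous"
}

#' Classify dose-response shapes for a profile collection
#'
#' Applies [classify_profile()] per gene and flags constant (flat)
#' profiles, which satisfy both monotone definitions and are reported as
#' increase by the tie-break.
#'
#' @param profiles Normalized profiles from [normalize_profiles()].
#' @param epsilon Monotonicity tolerance.
#' @return A tibble `gene_id`, `shape`, `flat_flag`, plus an `epsilon`
#'   attribute.
#' @export
classify_shapes <- function(profiles, epsilon = 0.05) {
  out <- profiles |>
    dplyr::arrange(.data$gene_id, .data$dose) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      shape = classify_profile(.data$value, epsilon),
      flat_flag = max(.data$value) - min(.data$value) <= epsilon,
      .groups = "drop"
    )
  attr(out, "epsilon") <- epsilon
  out
}

#' Hierarchical clustering of normalized profiles
#'
#' Agglomerative clustering on squared Euclidean distances between
#' max-normalized, replicate-averaged profiles; flat cluster labels are
#' obtained by cutting the tree at `cut_height` (linkage distance), so
#' genes whose branches merge below that height share a label.
#'
#' @param profiles Normalized profiles from [normalize_profiles()].
#' @param method Linkage method for [stats::hclust()] (default
#'   `"average"`; `"ward.D"` is the Ward option for squared distances).
#' @param cut_height Height at which to cut for flat labels (default 4).
#' @return A list of class `profile_clustering`: `hclust` (the merge tree),
#'   `labels` (tibble `gene_id`, `cluster`), `leaf_order` (gene ids in
#'   dendrogram order), `cut_height`.
#' @export
cluster_profiles <- function(profiles, method = "average", cut_height = 4) {
  wide <- profiles |>
    tidyr::pivot_wider(names_from = "dose", values_from = "value") |>
    tibble::column_to_rownames("gene_id")
  if (nrow(wide) < 2) abort("clustering needs >= 2 profiles")
  d2 <- stats::dist(as.matrix(wide))^2
  hc <- stats::hclust(d2, method = method)
  cl <- stats::cutree(hc, h = cut_height)
  structure(
    list(
      hclust = hc,
      labels = tibble::tibble(
        gene_id = names(cl), cluster = unname(cl)
      ),
      leaf_order = hc$labels[hc$order],
      cut_height = cut_height
    ),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(
    "<profile_clustering>", length(x$leaf_order), "genes,",
    max(x$labels$cluster), "clusters at cut height", x$cut_height, "\n"
  )
  invisible(x)
}

#' Export a clustering merge tree as Newick text
#'
#' @param clustering A [cluster_profiles()] result.
#' @param path Optional output path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' PCA report over conditions
#'
#' Centered principal component analysis of the gene-by-condition matrix
#' (replicate means, or normalized profiles if given), for biplot-style
#' reporting: per-gene component scores, per-condition loadings, and
#' variance-explained fractions.
#'
#' @param expr Long expression tibble, or a profile tibble with a `value`
#'   column as from [normalize_profiles()].
#' @param genes Optional subset of gene ids.
#' @return A list of class `pca_report`: `scores` (tibble `gene_id`,
#'   `PC1`, ...), `loadings` (tibble `dose`, `PC1`, ...),
#'   `variance_explained` (numeric, sums to 1).
#' @export
pca_report <- function(expr, genes = NULL) {
  if ("value" %in% names(expr) && !"fpkm" %in% names(expr)) {
    mat_long <- dplyr::rename(expr, mean_fpkm = "value")
  } else {
    check_expression(expr)
    mat_long <- condition_means(expr)
  }
  if (!is.null(genes)) {
    mat_long <- dplyr::filter(mat_long, .data$gene_id %in% genes)
  }
  wide <- mat_long |>
    tidyr::pivot_wider(names_from = "dose", values_from = "mean_fpkm") |>
    tibble::column_to_rownames("gene_id") |>
    as.matrix()
  if (nrow(wide) < 2 || ncol(wide) < 2) {
    abort("PCA needs >= 2 genes and >= 2 conditions")
  }
  if (sum(scale(wide, center = TRUE, scale = FALSE)^2) == 0) {
    abort("constant matrix: PCA undefined")
  }
  pc <- prcomp(wide, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble::as_tibble(pc$x, rownames = "gene_id"),
      loadings = tibble::as_tibble(pc$rotation, rownames = "dose"),
      variance_explained = ve
    ),
    class = "pca_report"
  )
}

#' @export
print.pca_report <- function(x, ...) {
  cat("<pca_report>", nrow(x$scores), "genes\n")
  cat(
    "variance explained:",
    paste0(round(100 * head(x$variance_explained, 3), 1), "%", collapse = ", "),
    "...\n"
  )
  invisible(x)
}
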