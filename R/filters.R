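#' Genes with non-zero expression anywhere
#'
#' Keeps genes with FPKM > 0 in at least one (dose, replicate) cell.
#'
#' @param expr Long expression tibble.
#' @return Character vector of surviving gene ids.
#' @export
filter_nonzero <- function(expr) {
  check_expression(expr)
  expr |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(keep = any(.data$fpkm > 0)) |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("gene_id")
}

#' Genes detectably expressed in at least one condition
#'
#' Keeps genes whose replicate-mean FPKM exceeds `cutoff` in at least one
#' condition. `scope = "all"` considers every dose; `scope = "treated"`
#' considers only non-zero doses (an alternative reading in which
#' detectability must come from a stimulated condition).
#'
#' @param expr Long expression tibble.
#' @param cutoff Detectability cutoff in FPKM (default 1, roughly one mRNA
#'   per cell).
#' @param scope `"all"` (default) or `"treated"`.
#' @return Character vector of surviving gene ids.
#' @export
filter_expression <- function(expr, cutoff = 1, scope = c("all", "treated")) {
  scope <- match.arg(scope)
  check_expression(expr)
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  cm <- condition_means(expr)
  if (scope == "treated") cm <- dplyr::filter(cm, .data$dose > 0)
  cm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(keep = any(.data$mean_fpkm > cutoff)) |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("gene_id")
}

#' Kruskal-Wallis test across dose groups, per gene
#'
#' Rank-based omnibus test for any difference in expression among the dose
#' groups (replicates are the observations within each group). The H
#' statistic uses the standard tie correction and the p-value the
#' chi-squared approximation with (groups - 1) degrees of freedom, as
#' computed by [stats::kruskal.test()]. With few replicates per group the
#' approximation is rough — against the exact permutation distribution the
#' p-value can deviate by up to about 0.17 with 2-3 observations per group —
#' so `small_groups` flags genes where any group has fewer than 5
#' observations. Genes whose observations are all identical get H = 0,
#' p = 1.
#'
#' @param expr Long expression tibble.
#' @param genes Optional subset of gene ids (default: all genes).
#' @return A tibble `gene_id`, `statistic`, `p_value`, `df`, `small_groups`.
#' @export
kw_test <- function(expr, genes = NULL) {
  check_expression(expr)
  if (!is.null(genes)) expr <- dplyr::filter(expr, .data$gene_id %in% genes)
  expr |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(res = list(kw_one(.data$fpkm, .data$dose)), .groups = "drop") |>
    tidyr::unnest_wider("res")
}

kw_one <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 1)) {
    abort("Kruskal-Wallis needs >= 2 groups with >= 1 observation each")
  }
  if (length(unique(values)) == 1) {
    return(list(
      statistic = 0, p_value = 1, df = length(sizes) - 1L,
      small_groups = any(sizes < 5)
    ))
  }
  kt <- kruskal.test(values, groups)
  list(
    statistic = unname(kt$statistic), p_value = kt$p.value,
    df = unname(kt$parameter), small_groups = any(sizes < 5)
  )
}

#' Dose-responsive genes by Kruskal-Wallis
#'
#' Keeps genes with Kruskal-Wallis p < `alpha` across the dose groups.
#' The permissive default (0.33) deliberately trades false positives for
#' sensitivity to weak monotone trends; no multiple-testing correction is
#' applied at any stage of the filter tree. `mode = "pairwise_min"` instead
#' tests each treated dose against dose 0 (two-group tests) and uses the
#' smallest p-value.
#'
#' @param expr Long expression tibble.
#' @param alpha Significance cutoff in (0, 1); default 0.33.
#' @param genes Optional subset of gene ids.
#' @param mode `"omnibus"` (default) or `"pairwise_min"`.
#' @return Character vector of surviving gene ids.
#' @export
filter_kw <- function(expr, alpha = 0.33, genes = NULL,
                      mode = c("omnibus", "pairwise_min")) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  p <- kw_pvalues(expr, genes, mode)
  # alpha = 1 disables the filter entirely (otherwise constant genes with
  # p exactly 1 would still be dropped by the strict inequality)
  if (alpha >= 1) {
    return(p$gene_id)
  }
  p$gene_id[p$p_value < alpha]
}

kw_pvalues <- function(expr, genes = NULL, mode = "omnibus") {
  if (mode == "omnibus") {
    return(kw_test(expr, genes)[, c("gene_id", "p_value")])
  }
  check_expression(expr)
  if (!is.null(genes)) expr <- dplyr::filter(expr, .data$gene_id %in% genes)
  zero_dose <- min(expr$dose)
  expr |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      p_value = {
        base <- .data$fpkm[.data$dose == zero_dose]
        treated <- split(
          .data$fpkm[.data$dose != zero_dose],
          .data$dose[.data$dose != zero_dose]
        )
        min(vapply(
          treated,
          function(v) kw_one(c(base, v), rep(1:2, c(length(base), length(v))))$p_value,
          1.0
        ))
      },
      .groups = "drop"
    )
}

#' Replicate-consistency filter
#'
#' For each gene, the Pearson correlation between the two replicate
#' dose-response vectors is tested for significant positive correlation
#' (one-sided t test, `df = doses - 2`); genes with p < `alpha` are kept.
#' Small p means reproducible response, so this step excludes
#' highly-variable genes while preserving truly responsive ones. Genes with
#' zero variance in either replicate vector have no defined correlation and
#' are reported with `degenerate = TRUE`.
#'
#' @param expr Long expression tibble with exactly 2 replicates and >= 3
#'   doses.
#' @param genes Optional subset of gene ids.
#' @param log_scale Correlate log1p-transformed values instead of raw FPKM.
#' @return A tibble `gene_id`, `r`, `p_value`, `degenerate`.
#' @export
replicate_correlation <- function(expr, genes = NULL, log_scale = FALSE) {
  check_expression(expr)
  if (!is.null(genes)) expr <- dplyr::filter(expr, .data$gene_id %in% genes)
  reps <- unique(expr$replicate)
  if (length(reps) != 2) abort("replicate correlation needs exactly 2 replicates")
  doses <- unique(expr$dose)
  if (length(doses) < 3) abort("replicate correlation needs >= 3 doses")
  df <- length(doses) - 2
  expr |>
    dplyr::mutate(y = if (log_scale) log1p(.data$fpkm) else .data$fpkm) |>
    dplyr::arrange(.data$dose) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      res = {
        v1 <- .data$y[.data$replicate == reps[1]]
        v2 <- .data$y[.data$replicate == reps[2]]
        if (sd(v1) == 0 || sd(v2) == 0) {
          list(list(r = NA_real_, p_value = NA_real_, degenerate = TRUE))
        } else {
          r <- cor(v1, v2)
          tt <- r * sqrt(df / (1 - r^2))
          list(list(
            r = r, p_value = pt(tt, df, lower.tail = FALSE), degenerate = FALSE
          ))
        }
      },
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
}

#' Genes passing the replicate-correlation filter
#'
#' @inheritParams replicate_correlation
#' @param alpha One-sided p-value cutoff (default 0.1).
#' @return Character vector of surviving gene ids.
#' @export
filter_replicate_correlation <- function(expr, alpha = 0.1, genes = NULL,
                                         log_scale = FALSE) {
  rc <- replicate_correlation(expr, genes, log_scale)
  rc$gene_id[!rc$degenerate & rc$p_value < alpha]
}

#' Run the staged filter tree
#'
#' Applies, in order: non-zero expression, detectable expression
#' (replicate-mean > `fpkm_cutoff` in some condition), Kruskal-Wallis dose
#' response (p < `kw_alpha`), and replicate correlation (one-sided
#' p < `corr_alpha`). Survivors of all four stages are the *responsive*
#' genes. The returned ledger assigns every input gene to exactly one
#' bucket, so bucket counts partition the input and stage survivor counts
#' are non-increasing.
#'
#' @param expr Long expression tibble.
#' @param fpkm_cutoff Detectability cutoff (FPKM), default 1.
#' @param kw_alpha Kruskal-Wallis cutoff, default 0.33.
#' @param corr_alpha Replicate-correlation cutoff, default 0.1.
#' @param expression_scope Passed to [filter_expression()] (`"all"` or
#'   `"treated"`).
#' @param kw_mode Passed to [filter_kw()].
#' @param corr_log_scale Passed to [replicate_correlation()].
#' @return A tibble of class `filter_ledger` with columns `gene_id`,
#'   `stage` (one of `dropped_zero`, `dropped_low`, `dropped_kw`,
#'   `dropped_corr_degenerate`, `dropped_corr`, `responsive`), `kw_p`,
#'   `corr_r`, `corr_p`; attributes `stage_counts` and `thresholds`.
#' @export
run_filter_tree <- function(expr, fpkm_cutoff = 1, kw_alpha = 0.33,
                            corr_alpha = 0.1,
                            expression_scope = c("all", "treated"),
                            kw_mode = c("omnibus", "pairwise_min"),
                            corr_log_scale = FALSE) {
  expression_scope <- match.arg(expression_scope)
  kw_mode <- match.arg(kw_mode)
  check_expression(expr)
  all_genes <- unique(expr$gene_id)

  s1 <- filter_nonzero(expr)
  e1 <- dplyr::filter(expr, .data$gene_id %in% s1)
  s2 <- filter_expression(e1, cutoff = fpkm_cutoff, scope = expression_scope)
  e2 <- dplyr::filter(e1, .data$gene_id %in% s2)
  kw <- kw_pvalues(e2, mode = kw_mode)
  s3 <- kw$gene_id[kw$p_value < kw_alpha]
  e3 <- dplyr::filter(e2, .data$gene_id %in% s3)
  rc <- replicate_correlation(e3, log_scale = corr_log_scale)
  s4 <- rc$gene_id[!rc$degenerate & rc$p_value < corr_alpha]

  stage <- rep("dropped_zero", length(all_genes))
  names(stage) <- all_genes
  stage[s1] <- "dropped_low"
  stage[s2] <- "dropped_kw"
  stage[intersect(s3, rc$gene_id[rc$degenerate])] <- "dropped_corr_degenerate"
  stage[intersect(s3, rc$gene_id[!rc$degenerate])] <- "dropped_corr"
  stage[s4] <- "responsive"

  ledger <- tibble::tibble(gene_id = all_genes, stage = unname(stage)) |>
    dplyr::left_join(
      dplyr::rename(kw, kw_p = "p_value"),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      dplyr::select(rc, "gene_id", corr_r = "r", corr_p = "p_value"),
      by = "gene_id"
    )
  attr(ledger, "stage_counts") <- c(
    input = length(all_genes), nonzero = length(s1),
    expressed = length(s2), kw = length(s3), responsive = length(s4)
  )
  attr(ledger, "thresholds") <- list(
    fpkm_cutoff = fpkm_cutoff, kw_alpha = kw_alpha, corr_alpha = corr_alpha,
    expression_scope = expression_scope, kw_mode = kw_mode,
    corr_log_scale = corr_log_scale
  )
  class(ledger) <- c("filter_ledger", class(ledger))
  ledger
}

#' Per-stage survivor counts of a filter ledger
#'
#' @param ledger A [run_filter_tree()] result.
#' @return Named integer vector: input, nonzero, expressed, kw, responsive.
#' @export
stage_counts <- function(ledger) {
  attr(ledger, "stage_counts")
}

#' Responsive genes of a filter ledger
#'
#' @param ledger A [run_filter_tree()] result.
#' @return Character vector of gene ids that survived all stages.
#' @export
responsive_genes <- function(ledger) {
  ledger$gene_id[ledger$stage == "responsive"]
}
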