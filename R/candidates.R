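#' Log2 fold change between the top and zero dose
#'
#' Per gene: `log2((mean_top + pseudocount) / (mean_zero + pseudocount))`
#' on replicate means per condition. The pseudocount (default 0.1 FPKM, an
#' order of magnitude below the 1-FPKM detectability cutoff) keeps genes
#' with zero basal expression finite; a gene at 0 in both boundary
#' conditions has fold change exactly 0.
#'
#' @param expr Long expression tibble containing both boundary doses.
#' @param pseudocount Added to both means before the ratio (default 0.1).
#' @return A tibble `gene_id`, `mean_zero`, `mean_top`, `log2_fc`.
#' @export
#' @examples
#' # a gene rising from 0 to 102.3 FPKM: log2(102.4 / 0.1) = 10
log2_fold_change <- function(expr, pseudocount = 0.1) {
  check_expression(expr)
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  doses <- range(expr$dose)
  condition_means(expr) |>
    dplyr::filter(.data$dose %in% doses) |>
    tidyr::pivot_wider(
      names_from = "dose", values_from = "mean_fpkm",
      names_prefix = "d"
    ) |>
    dplyr::rename(
      mean_zero = paste0("d", format_dose(doses[1])),
      mean_top = paste0("d", format_dose(doses[2]))
    ) |>
    dplyr::mutate(
      log2_fc = ifelse(
        .data$mean_zero == 0 & .data$mean_top == 0, 0,
        log2((.data$mean_top + pseudocount) / (.data$mean_zero + pseudocount))
      )
    )
}

#' Select ultrasensitive candidate genes
#'
#' Applies the candidate criteria to a cohort of Hill fits: binned-mode
#' Hill coefficient above 1 (ultrasensitive), log2 fold change between the
#' boundary doses at least `fc_threshold`, and basal FPKM below
#' `basal_threshold` in at least one replicate at the zero dose (high-basal
#' genes make the apparent Hill coefficient physiologically unreliable).
#' Candidates are ordered by descending Hill coefficient, then descending
#' fold change.
#'
#' @param fits A [fit_cohort()] result.
#' @param expr Long expression tibble the fits came from.
#' @param fc_threshold Minimum log2 fold change (default 0.7).
#' @param basal_threshold Basal FPKM ceiling (default 50), applied as
#'   "below in at least one replicate" (`basal_rule = "any"`) or in both
#'   (`"all"`).
#' @param pseudocount Passed to [log2_fold_change()].
#' @param basal_rule `"any"` (default) or `"all"`.
#' @param top Optional: keep only the first `top` candidates after
#'   ordering.
#' @return A tibble: `gene_id`, `n_binned_mode`, `log2_fc`, `basal_min`,
#'   `basal_max`, and logical flags `ultrasensitive`, `fc_pass`,
#'   `low_basal_pass`, with only genes passing all three retained.
#' @export
select_candidates <- function(fits, expr, fc_threshold = 0.7,
                              basal_threshold = 50, pseudocount = 0.1,
                              basal_rule = c("any", "all"), top = NULL) {
  basal_rule <- match.arg(basal_rule)
  check_expression(expr)
  fc <- log2_fold_change(expr, pseudocount)
  zero_dose <- min(expr$dose)
  basal <- expr |>
    dplyr::filter(.data$dose == zero_dose) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      basal_min = min(.data$fpkm), basal_max = max(.data$fpkm),
      .groups = "drop"
    )
  out <- fits |>
    tibble::as_tibble() |>
    dplyr::select("gene_id", "n_binned_mode", "ultrasensitive") |>
    dplyr::left_join(dplyr::select(fc, "gene_id", "log2_fc"), by = "gene_id") |>
    dplyr::left_join(basal, by = "gene_id") |>
    dplyr::mutate(
      fc_pass = .data$log2_fc >= fc_threshold,
      low_basal_pass = if (basal_rule == "any") {
        .data$basal_min < basal_threshold
      } else {
        .data$basal_max < basal_threshold
      }
    ) |>
    dplyr::filter(
      .data$ultrasensitive & .data$fc_pass & .data$low_basal_pass
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_binned_mode), dplyr::desc(.data$log2_fc))
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Genes rising from undetectable basal expression to a high fold change
#'
#' The "off-to-on" subset: replicate-mean FPKM below `basal_cut` at the
#' zero dose and a boundary fold change above `fc_cut`. `fc_cut` is
#' interpreted on the log2 scale by default (consistent with the 0.7 log2
#' threshold convention); set `fc_scale = "linear"` for a plain ratio.
#'
#' @param expr Long expression tibble.
#' @param basal_cut Basal replicate-mean FPKM ceiling (default 1).
#' @param fc_cut Fold-change floor (default 1.7).
#' @param fc_scale `"log2"` (default) or `"linear"`.
#' @param pseudocount Passed to [log2_fold_change()].
#' @return A tibble `gene_id`, `mean_zero`, `log2_fc` of qualifying genes.
#' @export
low_basal_high_fc <- function(expr, basal_cut = 1, fc_cut = 1.7,
                              fc_scale = c("log2", "linear"),
                              pseudocount = 0.1) {
  fc_scale <- match.arg(fc_scale)
  fc <- log2_fold_change(expr, pseudocount)
  cut <- if (fc_scale == "log2") fc_cut else log2(fc_cut)
  fc |>
    dplyr::filter(.data$mean_zero < basal_cut, .data$log2_fc > cut) |>
    dplyr::select("gene_id", "mean_zero", "log2_fc")
}
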