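#' Plot a Hill fit: data, posterior-mode curve, and n posterior
#'
#' @param object A [mh_fit()] result.
#' @param ... Unused.
#' @return A ggplot: observed points with the posterior-mode Hill curve.
#' @export
autoplot.hill_fit <- function(object, ...) {
  if ("unidentifiable" %in% object$flags) {
    abort("cannot plot an unidentifiable fit")
  }
  m <- object$modes
  grid <- seq(min(object$data$dose), max(object$data$dose), length.out = 200)
  curve_df <- tibble::tibble(
    dose = grid, value = hill(grid, m["a"], m["b"], m["k"], m["n"])
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$value)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(data = curve_df, colour = "steelblue") +
    ggplot2::labs(
      x = "dose (ng/ml)", y = "response",
      title = sprintf(
        "Hill fit: n (binned mode) = %.2f%s", object$n_binned_mode,
        if (isTRUE(object$ultrasensitive)) " (ultrasensitive)" else ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of Hill-coefficient modes across a fitted cohort
#'
#' @param fits A [fit_cohort()] result.
#' @param bin_width Bin width (default from the fits).
#' @return A ggplot bar chart over the fixed 0.5-width bins, with the n = 1
#'   ultrasensitivity boundary marked.
#' @export
plot_hill_histogram <- function(fits, bin_width = NULL) {
  h <- hill_histogram(fits, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo)[1] * 0.9, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "apparent Hill coefficient (binned mode)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Bar chart of filter-tree survivor counts
#'
#' @param ledger A [run_filter_tree()] result.
#' @return A ggplot of the per-stage survivor counts.
#' @export
plot_filter_tree <- function(ledger) {
  counts <- stage_counts(ledger)
  df <- tibble::tibble(
    stage = factor(names(counts), levels = names(counts)),
    genes = as.integer(counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$genes)) +
    ggplot2::geom_col(fill = "mediumpurple") +
    ggplot2::geom_text(ggplot2::aes(label = .data$genes), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "surviving genes") +
    ggplot2::theme_minimal()
}

#' PCA biplot of genes and condition loadings
#'
#' Component scores of every gene plus the condition loading vectors
#' (scaled to the score range) for the first two components.
#'
#' @param pca A [pca_report()] result.
#' @return A ggplot biplot.
#' @export
plot_pca_biplot <- function(pca) {
  sc <- pca$scores
  lo <- pca$loadings
  scale_f <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(lo$PC1, lo$PC2)))
  ve <- round(100 * pca$variance_explained[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "firebrick") +
    ggplot2::geom_segment(
      data = lo,
      ggplot2::aes(
        x = 0, y = 0,
        xend = .data$PC1 * scale_f, yend = .data$PC2 * scale_f
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "black"
    ) +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(
        x = .data$PC1 * scale_f, y = .data$PC2 * scale_f,
        label = paste0(.data$dose, " ng/ml")
      ),
      hjust = -0.1, size = 3
    ) +
    ggplot2::labs(
      x = paste0("PC1 (", ve[1], "%)"), y = paste0("PC2 (", ve[2], "%)")
    ) +
    ggplot2::theme_minimal()
}

#' Per-chromosome expression totals by condition
#'
#' @param totals A [chromosome_totals()] result.
#' @return A ggplot dodged bar chart.
#' @export
plot_chromosome_totals <- function(totals) {
  totals <- dplyr::mutate(totals,
    chromosome = factor(.data$chromosome, levels = unique(.data$chromosome))
  )
  ggplot2::ggplot(totals, ggplot2::aes(
    x = .data$chromosome, y = .data$total_fpkm, fill = factor(.data$dose)
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromosome", y = "total FPKM", fill = "dose (ng/ml)") +
    ggplot2::theme_minimal()
}

#' Positional map of up/down-regulated genes along chromosomes
#'
#' @param posmap A [deg_positional_map()] result.
#' @return A ggplot with one facet per chromosome, genes as points at
#'   their start coordinate, coloured by direction.
#' @export
plot_positional_map <- function(posmap) {
  posmap <- dplyr::mutate(posmap,
    chromosome = factor(.data$chromosome, levels = unique(.data$chromosome))
  )
  ggplot2::ggplot(posmap, ggplot2::aes(
    x = .data$start, y = .data$log2_fc, colour = .data$direction
  )) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = "position (bp)", y = "log2 fold change") +
    ggplot2::theme_minimal()
}
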