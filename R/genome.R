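#' Total expression per chromosome and condition
#'
#' Sums replicate-mean FPKM of the given genes per chromosome and dose.
#' Genes missing from the annotation are excluded and their count reported
#' as a message and as the `n_unannotated` attribute.
#'
#' @param expr Long expression tibble.
#' @param annotation Annotation tibble from [read_annotation()].
#' @param genes Gene subset to summarize (default: all genes in `expr`).
#' @return A tibble `chromosome`, `dose`, `total_fpkm`, ordered by
#'   chromosome (natural-numeric where labels are numeric) then dose.
#' @export
chromosome_totals <- function(expr, annotation, genes = NULL) {
  check_expression(expr)
  genes <- genes %||% unique(expr$gene_id)
  mapped <- intersect(genes, annotation$gene_id)
  n_un <- length(genes) - length(mapped)
  if (n_un > 0) {
    inform(paste0(n_un, " gene(s) absent from the annotation were skipped"))
  }
  if (length(mapped) == 0) {
    warn("no genes in common between expression subset and annotation")
    out <- tibble::tibble(
      chromosome = character(), dose = numeric(), total_fpkm = numeric()
    )
    attr(out, "n_unannotated") <- n_un
    return(out)
  }
  out <- condition_means(dplyr::filter(expr, .data$gene_id %in% mapped)) |>
    dplyr::left_join(
      dplyr::select(annotation, "gene_id", "chromosome"),
      by = "gene_id"
    ) |>
    dplyr::group_by(.data$chromosome, .data$dose) |>
    dplyr::summarise(total_fpkm = sum(.data$mean_fpkm), .groups = "drop") |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$dose)
  attr(out, "n_unannotated") <- n_un
  out
}

# natural ordering key: numeric labels (possibly "chr"-prefixed) rank
# numerically, the rest lexicographically after them; equal labels share a
# key so downstream sort columns still break ties
chrom_order <- function(chrom) {
  u <- unique(chrom)
  stripped <- sub("^chr", "", u)
  num <- suppressWarnings(as.numeric(stripped))
  match(chrom, u[order(ifelse(is.na(num), Inf, num), stripped)])
}

#' Positional map of responsive genes with fold-change direction
#'
#' Joins per-gene log2 fold changes onto genomic coordinates: direction is
#' `up` for positive, `down` for negative; genes at exactly 0 are kept but
#' flagged `neutral` (direction `down` under the strict `> 0` rule).
#' Output is sorted by chromosome, then start coordinate.
#'
#' @param fold_changes Tibble from [log2_fold_change()] (or any tibble with
#'   `gene_id` and `log2_fc`), typically restricted to responsive genes.
#' @param annotation Annotation tibble from [read_annotation()].
#' @return A tibble `chromosome`, `start`, `end`, `gene_id`, `log2_fc`,
#'   `direction`, `neutral`.
#' @export
deg_positional_map <- function(fold_changes, annotation) {
  if (!all(c("gene_id", "log2_fc") %in% names(fold_changes))) {
    abort("`fold_changes` needs columns gene_id and log2_fc")
  }
  fold_changes |>
    dplyr::inner_join(
      dplyr::select(annotation, "gene_id", "chromosome", "start", "end"),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      direction = ifelse(.data$log2_fc > 0, "up", "down"),
      neutral = .data$log2_fc == 0
    ) |>
    dplyr::select(
      "chromosome", "start", "end", "gene_id", "log2_fc", "direction", "neutral"
    ) |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$start)
}
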