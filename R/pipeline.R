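#' Synthetic gene annotation for a cohort
#'
#' Places genes uniformly at random on a small set of chromosomes, with
#' 10 kb gene bodies at uniform start positions — enough structure for the
#' per-chromosome summaries to be exercised and audited on synthetic data.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_chromosomes Number of chromosomes (default 3, labelled
#'   `"chr1"`, ...).
#' @param chrom_length Chromosome length in bp (default 1e8).
#' @param seed Optional integer seed.
#' @return An annotation tibble as from [read_annotation()].
#' @export
synthetic_annotation <- function(gene_ids, n_chromosomes = 3,
                                 chrom_length = 1e8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gene_ids)
  start <- sample.int(chrom_length - 1e4, n, replace = TRUE)
  tibble::tibble(
    gene_id = gene_ids,
    gene_name = gene_ids,
    chromosome = paste0("chr", sample.int(n_chromosomes, n, replace = TRUE)),
    start = as.integer(start),
    end = as.integer(start + 1e4 - 1),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

#' Default end-to-end pipeline configuration
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return A nested list understood by [run_pipeline()]; any subset of the
#'   entries may be overridden in a user config (YAML file or list).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(
      n_genes = 1000,
      noise_cv = 0.1,
      n_replicates = 2
    ),
    filters = list(
      fpkm_cutoff = 1, kw_alpha = 0.33, corr_alpha = 0.1,
      expression_scope = "all", kw_mode = "omnibus", corr_log_scale = FALSE
    ),
    shapes = list(epsilon = 0.05, linkage = "average", cut_height = 4),
    hillfit = list(
      n_steps = 5000, burn_in_fraction = 0.2, mode_bin_width = 0.5,
      scale = "log1p"
    ),
    candidates = list(
      fc_threshold = 0.7, basal_threshold = 50, pseudocount = 0.1,
      low_basal_cut = 1, high_fc_cut = 1.7
    ),
    genome = list(n_chromosomes = 3),
    out_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' One-call end-to-end run: simulate a cohort, apply the staged filter
#' tree, normalize and classify shapes (with clustering and a PCA report),
#' fit Hill functions to the increase-class genes by MCMC, select
#' ultrasensitive candidates, and summarize expression per chromosome.
#' When `out_dir` is set, every stage result is written as TSV (plus the
#' dendrogram as Newick and a config echo as YAML).
#'
#' @param config A nested list as from [default_config()], or a path to a
#'   YAML file with (a subset of) the same entries; missing entries take
#'   their defaults.
#' @return A list of class `ultrahill_run` with elements `cohort`,
#'   `ledger`, `profiles`, `shapes`, `clustering`, `pca`, `fits`,
#'   `fold_changes`, `candidates`, `low_basal_high_fc`, `annotation`,
#'   `chromosome_totals`, `positional_map`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  seed <- as.integer(config$seed)

  synth_args <- config$synth
  synth_args$seed <- synth_args$seed %||% seed
  spec <- do.call(cohort_spec, synth_args)
  cohort <- simulate_cohort(spec)
  expr <- cohort$expression

  ledger <- run_filter_tree(
    expr,
    fpkm_cutoff = config$filters$fpkm_cutoff,
    kw_alpha = config$filters$kw_alpha,
    corr_alpha = config$filters$corr_alpha,
    expression_scope = config$filters$expression_scope,
    kw_mode = config$filters$kw_mode,
    corr_log_scale = config$filters$corr_log_scale
  )
  responsive <- responsive_genes(ledger)

  profiles <- normalize_profiles(expr, responsive)
  shapes <- classify_shapes(profiles, epsilon = config$shapes$epsilon)
  clustering <- if (length(responsive) >= 2) {
    cluster_profiles(profiles,
      method = config$shapes$linkage,
      cut_height = config$shapes$cut_height
    )
  } else {
    NULL
  }
  pca <- if (length(responsive) >= 2) pca_report(profiles) else NULL

  increase <- shapes$gene_id[shapes$shape == "increase" & !shapes$flat_flag]
  fit_cfg <- fit_config(
    n_steps = config$hillfit$n_steps,
    burn_in_fraction = config$hillfit$burn_in_fraction,
    mode_bin_width = config$hillfit$mode_bin_width,
    scale = config$hillfit$scale,
    seed = seed
  )
  fits <- fit_cohort(expr, increase, fit_cfg)

  fold_changes <- log2_fold_change(expr, config$candidates$pseudocount)
  cands <- select_candidates(
    fits, expr,
    fc_threshold = config$candidates$fc_threshold,
    basal_threshold = config$candidates$basal_threshold,
    pseudocount = config$candidates$pseudocount
  )
  lbhf <- low_basal_high_fc(
    expr,
    basal_cut = config$candidates$low_basal_cut,
    fc_cut = config$candidates$high_fc_cut,
    pseudocount = config$candidates$pseudocount
  )

  annotation <- synthetic_annotation(
    unique(expr$gene_id),
    n_chromosomes = config$genome$n_chromosomes, seed = seed
  )
  expressed <- ledger$gene_id[
    ledger$stage %in% c("dropped_kw", "dropped_corr", "dropped_corr_degenerate", "responsive")
  ]
  chr_totals <- chromosome_totals(expr, annotation, expressed)
  posmap <- deg_positional_map(
    dplyr::filter(fold_changes, .data$gene_id %in% responsive), annotation
  )

  run <- structure(
    list(
      cohort = cohort, ledger = ledger, profiles = profiles, shapes = shapes,
      clustering = clustering, pca = pca, fits = fits,
      fold_changes = fold_changes, candidates = cands,
      low_basal_high_fc = lbhf, annotation = annotation,
      chromosome_totals = chr_totals, positional_map = posmap,
      config = config
    ),
    class = "ultrahill_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Write every stage result of a pipeline run as plain text
#'
#' @param run An [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_expression_table(run$cohort$expression, p("expression.tsv"))
  readr::write_tsv(run$cohort$truth, p("truth.tsv"))
  readr::write_tsv(tidy(run$ledger), p("filter_ledger.tsv"))
  readr::write_tsv(glance(run$ledger), p("filter_counts.tsv"))
  readr::write_tsv(run$profiles, p("normalized_profiles.tsv"))
  readr::write_tsv(run$shapes, p("shape_calls.tsv"))
  if (!is.null(run$clustering)) {
    write_newick(run$clustering, p("dendrogram.nwk"))
    readr::write_tsv(run$clustering$labels, p("cluster_labels.tsv"))
  }
  if (!is.null(run$pca)) {
    readr::write_tsv(run$pca$scores, p("pca_scores.tsv"))
    readr::write_tsv(run$pca$loadings, p("pca_loadings.tsv"))
    readr::write_tsv(tidy(run$pca, "variance"), p("pca_variance.tsv"))
  }
  readr::write_tsv(tibble::as_tibble(run$fits), p("hill_fits.tsv"))
  readr::write_tsv(hill_histogram(run$fits), p("hill_histogram.tsv"))
  readr::write_tsv(run$fold_changes, p("fold_changes.tsv"))
  readr::write_tsv(run$candidates, p("candidates.tsv"))
  readr::write_tsv(run$low_basal_high_fc, p("low_basal_high_fc.tsv"))
  readr::write_tsv(run$annotation, p("annotation.tsv"))
  readr::write_tsv(run$chromosome_totals, p("chromosome_totals.tsv"))
  readr::write_tsv(run$positional_map, p("positional_map.tsv"))
  yaml::write_yaml(run$config, p("config.yaml"))
  invisible(out_dir)
}

#' @export
print.ultrahill_run <- function(x, ...) {
  counts <- stage_counts(x$ledger)
  cat("<ultrahill_run>\n")
  cat(
    "  filter tree:",
    paste(names(counts), counts, sep = "=", collapse = " > "), "\n"
  )
  cat("  shapes:", paste(
    names(table(x$shapes$shape)), table(x$shapes$shape),
    sep = "=", collapse = " "
  ), "\n")
  cat(
    "  fitted:", nrow(x$fits), "genes;",
    sum(x$fits$ultrasensitive, na.rm = TRUE), "ultrasensitive;",
    nrow(x$candidates), "candidates\n"
  )
  invisible(x)
}
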