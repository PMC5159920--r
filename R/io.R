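#' Read an expression table
#'
#' Canonical dialect: TSV with a `gene_id` first column and one column per
#' (dose, replicate) cell named `<dose>ng_<replicate>`, e.g. `2.1ng_rep1`.
#' Values are FPKM-like, non-negative. Missing cells are an input error —
#' every gene must have a value for every (dose, replicate) pair.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `gene_id`, `dose`, `replicate`,
#'   `fpkm`, with doses sorted increasingly.
#' @seealso [write_expression_table()] — the two round-trip exactly.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # parse numbers as text first, then convert with base strtod: the fast
  # vroom double parser can be one ulp off, which would break the
  # byte-exact round-trip contract
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  for (cn in setdiff(names(raw), "gene_id")) {
    v <- as.numeric(raw[[cn]])
    raw[[cn]] <- v
  }
  if (!"gene_id" %in% names(raw) || ncol(raw) < 2) {
    abort("malformed header: expected `gene_id` plus `<dose>ng_<rep>` columns")
  }
  cells <- setdiff(names(raw), "gene_id")
  m <- regmatches(cells, regexec("^([0-9.]+)ng_(.+)$", cells))
  bad <- cells[vapply(m, length, 1L) != 3]
  if (length(bad) > 0) {
    abort(paste0(
      "malformed column name(s): ", paste(bad, collapse = ", "),
      " (expected `<dose>ng_<replicate>`)"
    ))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0(
      "parse error at line ", prob$row[1] + 1L, ": ", prob$expected[1]
    ))
  }
  long <- raw |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell", values_to = "fpkm") |>
    tidyr::separate_wider_regex(
      "cell",
      patterns = c(dose = "[0-9.]+", "ng_", replicate = ".+")
    ) |>
    dplyr::mutate(dose = as.numeric(.data$dose)) |>
    dplyr::arrange(
      match(.data$gene_id, raw$gene_id), .data$replicate, .data$dose
    ) |>
    dplyr::select("gene_id", "dose", "replicate", "fpkm")
  if (anyNA(long$fpkm)) {
    row <- which(is.na(long$fpkm))[1]
    abort(paste0("missing expression value for gene ", long$gene_id[row]))
  }
  neg <- which(long$fpkm < 0)
  if (length(neg) > 0) {
    line <- match(long$gene_id[neg[1]], raw$gene_id) + 1L
    abort(paste0("negative FPKM at line ", line, " (gene ", long$gene_id[neg[1]], ")"))
  }
  check_expression(long)
  long
}

#' Write an expression table in the canonical dialect
#'
#' @param expr Long expression tibble (`gene_id`, `dose`, `replicate`, `fpkm`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  check_expression(expr)
  wide <- expr |>
    dplyr::mutate(cell = paste0(
      vapply(.data$dose, format_dose, ""), "ng_", .data$replicate
    )) |>
    dplyr::select("gene_id", "cell", "fpkm") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "fpkm")
  readr::write_tsv(wide, path)
  invisible(path)
}

# print doses compactly and stably (0, 1, 2.1, 16.7, ...)
format_dose <- function(d) {
  format(d, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Read a gene annotation table (BED6 or GTF)
#'
#' Coordinates are stored 1-based inclusive internally; BED input (0-based,
#' half-open) is converted on read. For GTF input only `gene` features are
#' kept (falling back to all features if the file has no `type` column).
#' Parsing is delegated to `rtracklayer::import()`.
#'
#' @param path Path to a `.bed`, `.gtf`/`.gff` file.
#' @param format `"auto"` (from extension), `"bed"`, or `"gtf"`.
#' @return A tibble with columns `gene_id`, `gene_name`, `chromosome`,
#'   `start`, `end`, `strand`. Empty input yields an empty tibble with a
#'   warning.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2", "gff3")) "gtf" else "bed"
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading annotation requires the rtracklayer package")
  }
  if (file.size(path) == 0 ||
    all(grepl("^\\s*(#|$)", readLines(path, warn = FALSE)))) {
    warn("annotation file is empty; returning an empty annotation")
    return(tibble::tibble(
      gene_id = character(), gene_name = character(), chromosome = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gtf" && "type" %in% names(df)) {
    keep <- df$type == "gene"
    if (any(keep)) df <- df[keep, , drop = FALSE]
  }
  ids <- df[["gene_id"]] %||% df[["name"]] %||% df[["ID"]]
  if (is.null(ids)) abort("annotation has no gene identifier column")
  out <- tibble::tibble(
    gene_id = as.character(ids),
    gene_name = as.character(df[["gene_name"]] %||% ids),
    chromosome = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
      as.character(df$strand), "unknown"
    )
  )
  if (any(out$start > out$end)) abort("annotation has start > end")
  out
}

#' Read a qPCR Ct table
#'
#' Expected TSV columns: `gene_id`, `dose`, `bio_rep`, `tech_rep`,
#' `ct_gene`, `ct_reference` (reference = housekeeping gene).
#'
#' @param path Path to a TSV file.
#' @return A tibble with those columns.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    dose = readr::col_double(),
    bio_rep = readr::col_character(),
    tech_rep = readr::col_character(),
    ct_gene = readr::col_double(),
    ct_reference = readr::col_double()
  ))
  if (any(!is.finite(out$ct_gene)) || any(!is.finite(out$ct_reference)) ||
    any(out$ct_gene <= 0) || any(out$ct_reference <= 0)) {
    abort("Ct values must be positive and finite")
  }
  out
}

#' Relative copy numbers from qPCR Ct values
#'
#' Computes `2^-(Ct_gene - Ct_reference)` per (gene, dose, biological
#' replicate), the standard delta-Ct quantification against a housekeeping
#' reference. Technical replicates are averaged on the Ct scale before the
#' transform.
#'
#' @param qpcr A tibble as returned by [read_qpcr()].
#' @return A tibble `gene_id`, `dose`, `bio_rep`, `rcn` with one row per
#'   (gene, dose, biological replicate).
#' @export
#' @examples
#' q <- tibble::tibble(
#'   gene_id = "g1", dose = 0, bio_rep = "b1", tech_rep = c("t1", "t2"),
#'   ct_gene = c(24, 24), ct_reference = c(25, 25)
#' )
#' relative_copy_number(q) # rcn = 2
relative_copy_number <- function(qpcr) {
  need <- c("gene_id", "dose", "bio_rep", "ct_gene", "ct_reference")
  if (!all(need %in% names(qpcr))) {
    abort(paste0("`qpcr` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(qpcr$ct_gene)) || any(!is.finite(qpcr$ct_reference))) {
    abort("Ct values must be finite")
  }
  qpcr |>
    dplyr::group_by(.data$gene_id, .data$dose, .data$bio_rep) |>
    dplyr::summarise(
      rcn = 2^-(mean(.data$ct_gene) - mean(.data$ct_reference)),
      .groups = "drop"
    )
}
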