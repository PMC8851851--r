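# Reading counts/design tables, TPM conversion, and the expression filter.

#' Read an expression matrix and study design from TSV files
#'
#' Reads the three tab-separated inputs of a layered-culture analysis:
#' a counts table (first column `gene_id`, remaining columns one per sample),
#' a gene-length table (`gene_id`, `length` in bases), and a design table
#' (`sample_id`, `group` with groups among [cn_groups()]). Validates
#' identifiers, non-negativity and the sample/design correspondence, and
#' harmonizes sample order.
#'
#' @param counts_path,lengths_path,design_path Paths to TSV files.
#' @return A list with `expression` (tibble: `gene_id`, `length`, one column
#'   per sample, units attribute `"counts"`) and `design` (tibble:
#'   `sample_id`, `group`).
#' @export
read_expression <- function(counts_path, lengths_path, design_path) {
  for (p in c(counts_path, lengths_path, design_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(counts)[1] != "gene_id") names(counts)[1] <- "gene_id"
  lengths <- readr::read_tsv(lengths_path, show_col_types = FALSE,
                             col_names = c("gene_id", "length"), skip = 1)
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            col_names = c("sample_id", "group"), skip = 1)

  if (anyDuplicated(lengths$gene_id)) {
    stop("duplicate gene_id in lengths file", call. = FALSE)
  }
  missing_len <- setdiff(counts$gene_id, lengths$gene_id)
  if (length(missing_len) > 0) {
    stop(sprintf("gene(s) missing from lengths file: %s",
                 paste(utils::head(missing_len, 5), collapse = ", ")),
         call. = FALSE)
  }
  x <- counts |>
    left_join(lengths, by = "gene_id") |>
    relocate("length", .after = "gene_id") |>
    as_tibble()
  validate_expression(x, require_length = TRUE)
  validate_design(design, x)
  # harmonize column order with the design
  x <- x[c("gene_id", "length", design$sample_id)]
  expression_units(x) <- "counts"
  list(expression = x, design = as_tibble(design))
}

#' Convert counts to transcripts per million (TPM)
#'
#' Per sample `s`, `TPM(g, s) = (count(g, s) / length(g)) /
#' sum_g'(count(g', s) / length(g')) * 1e6`, so every column sums to one
#' million. Counts may be non-integer (estimated counts are accepted).
#'
#' @param x Expression tibble of counts with a `length` column (bases).
#' @return Expression tibble of the same shape with TPM values and units
#'   attribute `"tpm"`.
#' @export
#' @examples
#' x <- tibble::tibble(gene_id = c("a", "b"), length = c(1000, 2000),
#'                     s1 = c(10, 10))
#' tpm_normalize(x)
tpm_normalize <- function(x) {
  validate_expression(x, require_length = TRUE)
  if (identical(expression_units(x), "tpm")) {
    stop("input is already TPM-normalized", call. = FALSE)
  }
  sc <- sample_cols(x)
  m <- as.matrix(x[sc])
  rate <- m / x$length
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    stop(sprintf("TPM undefined for all-zero sample(s): %s",
                 paste(sc[zero], collapse = ", ")), call. = FALSE)
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- x
  out[sc] <- as.data.frame(tpm)
  expression_units(out) <- "tpm"
  out
}

#' Filter genes on minimum group-mean TPM
#'
#' Keeps a gene if its mean TPM within at least one study group is greater
#' than or equal to `min_tpm` (inclusive boundary). With
#' `scope = "any_sample"` a single sample at or above the threshold suffices
#' instead.
#'
#' @param tpm TPM expression tibble (see [tpm_normalize()]).
#' @param design Design tibble (`sample_id`, `group`).
#' @param min_tpm Inclusive expression threshold in TPM (default 1).
#' @param scope `"group_mean"` (default) or `"any_sample"`.
#' @return Tibble with `gene_id`, one mean-TPM column per group, and a
#'   logical `expressed` column.
#' @export
expression_filter <- function(tpm, design, min_tpm = 1,
                              scope = c("group_mean", "any_sample")) {
  scope <- match.arg(scope)
  validate_expression(tpm)
  validate_design(design, tpm)
  if (nrow(tpm) == 0) stop("empty expression matrix", call. = FALSE)
  gm <- group_mean_matrix(tpm, design)
  expressed <- if (scope == "group_mean") {
    apply(gm, 1, max) >= min_tpm
  } else {
    apply(as.matrix(tpm[design$sample_id]), 1, max) >= min_tpm
  }
  bind_cols(
    tibble(gene_id = tpm$gene_id),
    as_tibble(gm),
    tibble(expressed = unname(expressed))
  )
}
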