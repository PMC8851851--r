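# The three-stage classification cascade: Src effect, contact-normalization
# reversal, cadherin dependence, composed into the onion-layer summary.

# Replicate-value matrix for a set of genes and one group, optionally on the
# log2(TPM + 1) scale used for t-tests when config$log_transform is on.
group_values <- function(tpm, design, group, genes, log_transform = FALSE) {
  sbg <- samples_by_group(design)
  if (!group %in% names(sbg)) {
    stop(sprintf("design is missing required group '%s'", group),
         call. = FALSE)
  }
  idx <- match(genes, tpm$gene_id)
  if (anyNA(idx)) stop("gene(s) absent from expression data", call. = FALSE)
  m <- as.matrix(tpm[idx, sbg[[group]], drop = FALSE])
  if (log_transform) m <- log2(m + 1)
  m
}

stage_p_adjust <- function(p, method) {
  if (identical(method, "BH")) p.adjust(p, method = "BH") else p
}

#' Classify the Src-transformation effect per gene
#'
#' Compares transformed-self (`T_self`) against normal-self (`N_self`)
#' replicate TPMs. A gene is `up` if its fold change (T_self over N_self,
#' pseudocount-stabilized) is at least `src_fold` with t-test p below
#' `src_alpha`; `down` if the fold change is at most `1/src_fold` with p
#' below `src_alpha`; otherwise `none`. Fold boundaries are inclusive.
#'
#' @param tpm TPM expression tibble.
#' @param design Design tibble covering groups `N_self` and `T_self`.
#' @param config A [cascade_config()].
#' @param genes Gene identifiers to classify (default: all genes in `tpm`;
#'   normally the expression-filtered set).
#' @return Tibble with `gene_id`, `src_fc`, `src_p`, `src_class`.
#' @export
classify_src_effect <- function(tpm, design, config = cascade_config(),
                                genes = tpm$gene_id) {
  A <- group_values(tpm, design, "T_self", genes, config$log_transform)
  B <- group_values(tpm, design, "N_self", genes, config$log_transform)
  Ar <- group_values(tpm, design, "T_self", genes)
  Br <- group_values(tpm, design, "N_self", genes)
  tt <- row_t_test(A, B)
  p <- stage_p_adjust(tt$p, config$p_adjust)
  fc <- fold_change(rowMeans(Ar), rowMeans(Br), config$pseudocount)
  cls <- rep("none", length(genes))
  cls[fc >= config$src_fold & p < config$src_alpha] <- "up"
  cls[fc <= 1 / config$src_fold & p < config$src_alpha] <- "down"
  tibble(gene_id = genes, src_fc = unname(fc), src_p = p, src_class = cls)
}

#' Classify contact-normalization reversal per gene
#'
#' For Src-affected genes only, compares transformed cells cocultured with
#' cadherin-competent nontransformed cells (`T_vs_N`) against transformed-self
#' (`T_self`). In the default `inverse_change` mode the relative change is
#' `(mean T_vs_N - mean T_self) / (mean T_self + pseudocount)`; a gene is
#' reversed when that change is opposite in sign to its Src effect, at least
#' `reversal_fraction` in magnitude, and the t-test p is below
#' `reversal_alpha`. In `restoration` mode the change is measured as the
#' fraction of the Src displacement recovered toward the normal-self baseline.
#'
#' @inheritParams classify_src_effect
#' @param src_classes Tibble from [classify_src_effect()] restricted to
#'   Src-affected genes (`src_class` of `up` or `down`).
#' @return Tibble with `gene_id`, `reversal_change`, `reversal_p`, `reversed`.
#' @export
classify_reversal <- function(tpm, design, config = cascade_config(),
                              src_classes) {
  if (!all(c("gene_id", "src_class") %in% names(src_classes))) {
    stop("src_classes must have columns gene_id and src_class", call. = FALSE)
  }
  if (any(src_classes$src_class == "none")) {
    stop("classify_reversal applies only to Src-affected genes", call. = FALSE)
  }
  genes <- src_classes$gene_id
  A <- group_values(tpm, design, "T_self", genes, config$log_transform)
  B <- group_values(tpm, design, "T_vs_N", genes, config$log_transform)
  tt <- row_t_test(A, B)
  p <- stage_p_adjust(tt$p, config$p_adjust)
  m_self <- rowMeans(group_values(tpm, design, "T_self", genes))
  m_cc <- rowMeans(group_values(tpm, design, "T_vs_N", genes))
  up <- src_classes$src_class == "up"
  if (config$reversal_mode == "inverse_change") {
    change <- (m_cc - m_self) / (m_self + config$pseudocount)
    opposite <- ifelse(up, change < 0, change > 0)
    reversed <- opposite & abs(change) >= config$reversal_fraction &
      p < config$reversal_alpha
  } else {
    m_norm <- rowMeans(group_values(tpm, design, "N_self", genes))
    displacement <- m_norm - m_self
    change <- ifelse(displacement == 0, 0, (m_cc - m_self) / displacement)
    reversed <- change >= config$reversal_fraction & p < config$reversal_alpha
  }
  tibble(gene_id = genes, reversal_change = unname(change),
         reversal_p = p, reversed = unname(reversed))
}

#' Classify cadherin dependence of reversed genes
#'
#' For reversed genes only, compares transformed cells over cadherin-knockout
#' cells (`T_vs_KO`) against transformed cells over cadherin-competent cells
#' (`T_vs_N`). A gene is cadherin `dependent` when the knockout coculture
#' fails to normalize it — expression moves back toward the transformed-self
#' direction by at least `cdh_fold` (fold >= `cdh_fold` for Src-up genes,
#' <= `1/cdh_fold` for Src-down genes) with t-test p below `cdh_alpha` —
#' and `independent` otherwise. A differential in the direction inconsistent
#' with the original Src effect does not count as dependence.
#'
#' @inheritParams classify_reversal
#' @param reversed_set Tibble from [classify_reversal()] restricted to
#'   reversed genes.
#' @return Tibble with `gene_id`, `cdh_fc`, `cdh_p`, `cdh_class`.
#' @export
classify_cadherin_dependence <- function(tpm, design,
                                         config = cascade_config(),
                                         reversed_set, src_classes) {
  if (!all(reversed_set$reversed)) {
    stop("classify_cadherin_dependence applies only to reversed genes",
         call. = FALSE)
  }
  genes <- reversed_set$gene_id
  src <- src_classes$src_class[match(genes, src_classes$gene_id)]
  if (anyNA(src)) {
    stop("reversed gene(s) missing from src_classes", call. = FALSE)
  }
  A <- group_values(tpm, design, "T_vs_KO", genes, config$log_transform)
  B <- group_values(tpm, design, "T_vs_N", genes, config$log_transform)
  tt <- row_t_test(A, B)
  p <- stage_p_adjust(tt$p, config$p_adjust)
  m_ko <- rowMeans(group_values(tpm, design, "T_vs_KO", genes))
  m_cc <- rowMeans(group_values(tpm, design, "T_vs_N", genes))
  fc <- fold_change(m_ko, m_cc, config$pseudocount)
  up <- src == "up"
  dependent <- ifelse(up, fc >= config$cdh_fold, fc <= 1 / config$cdh_fold) &
    p < config$cdh_alpha
  tibble(gene_id = genes, cdh_fc = unname(fc), cdh_p = p,
         cdh_class = ifelse(dependent, "dependent", "independent"))
}

#' Run the full contact-normalization classification cascade
#'
#' Composes the expression filter and the three classification stages on a
#' counts or TPM table with the four-group layered-culture design, assigning
#' every gene to one onion layer: `not_expressed`, `expressed_unaffected`,
#' `src_only`, `cn_cadherin_independent`, or `cn_cadherin_dependent`.
#'
#' @param x Expression tibble. Counts (with a `length` column) are
#'   TPM-normalized first; a table with units attribute `"tpm"` is used as is.
#' @param design Design tibble covering all four groups of [cn_groups()].
#' @param config A [cascade_config()].
#' @return A `cn_cascade` object: list with `genes` (per-gene classification
#'   tibble), `summary` (onion-layer counts tibble), and `config`. The
#'   summary direction convention follows the contact-normalization change:
#'   `reversed_up`/`dependent_up` count genes *increased* by contact (i.e.
#'   originally Src-down), `reversed_down`/`dependent_down` genes decreased
#'   by contact (originally Src-up).
#' @export
#' @examples
#' sim <- simulate_study(n_genes = 60, seed = 42)
#' res <- run_cascade(sim$counts, sim$design)
#' glance(res)
run_cascade <- function(x, design, config = cascade_config()) {
  validate_design(design, x)
  missing_groups <- setdiff(cn_groups(), unique(design$group))
  if (length(missing_groups) > 0) {
    stop(sprintf("design must cover all four groups; missing: %s",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)
  }
  tab <- table(design$group)
  if (any(tab < 2)) {
    stop("every group needs at least 2 replicates", call. = FALSE)
  }
  tpm <- if (identical(expression_units(x), "tpm")) x else tpm_normalize(x)

  filt <- expression_filter(tpm, design, min_tpm = config$min_tpm,
                            scope = config$filter_scope)
  genes <- filt |>
    select("gene_id", all_of(cn_groups())) |>
    rename_with(~ paste0("mean_", .x), all_of(cn_groups())) |>
    mutate(expressed = filt$expressed)

  expressed_ids <- filt$gene_id[filt$expressed]
  src <- classify_src_effect(tpm, design, config, genes = expressed_ids)
  affected <- src |> filter(.data$src_class != "none")

  if (nrow(affected) > 0) {
    rev <- classify_reversal(tpm, design, config, src_classes = affected)
  } else {
    rev <- tibble(gene_id = character(), reversal_change = numeric(),
                  reversal_p = numeric(), reversed = logical())
  }
  reversed <- rev |> filter(.data$reversed)
  if (nrow(reversed) > 0) {
    cdh <- classify_cadherin_dependence(tpm, design, config,
                                        reversed_set = reversed,
                                        src_classes = affected)
  } else {
    cdh <- tibble(gene_id = character(), cdh_fc = numeric(),
                  cdh_p = numeric(), cdh_class = character())
  }

  genes <- genes |>
    left_join(src, by = "gene_id") |>
    left_join(rev, by = "gene_id") |>
    left_join(cdh, by = "gene_id") |>
    mutate(
      src_class = ifelse(.data$expressed & is.na(.data$src_class),
                         "none", .data$src_class),
      reversed = ifelse(.data$src_class %in% c("up", "down") &
                          is.na(.data$reversed), FALSE, .data$reversed),
      cdh_class = ifelse(.data$src_class %in% c("up", "down") &
                           !isTRUE_vec(.data$reversed),
                         "not_applicable", .data$cdh_class),
      layer = dplyr::case_when(
        !.data$expressed ~ "not_expressed",
        .data$src_class == "none" ~ "expressed_unaffected",
        !isTRUE_vec(.data$reversed) ~ "src_only",
        .data$cdh_class == "dependent" ~ "cn_cadherin_dependent",
        TRUE ~ "cn_cadherin_independent"
      ),
      layer = factor(.data$layer, levels = cn_layers())
    )
  # cdh_class for reversed genes that got a verdict stays; non-reversed
  # affected genes keep NA cdh fields; non-expressed genes keep NA throughout.

  structure(
    list(genes = genes, summary = onion_summary(genes), config = config),
    class = "cn_cascade"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

# Onion-layer counts from a per-gene classification tibble.
onion_summary <- function(genes) {
  up <- genes$src_class %in% "up"
  down <- genes$src_class %in% "down"
  reversed <- isTRUE_vec(genes$reversed)
  dependent <- genes$cdh_class %in% "dependent"
  tibble(
    detected = nrow(genes),
    expressed = sum(genes$expressed),
    src_up = sum(up),
    src_down = sum(down),
    # direction of the contact-normalization change:
    reversed_up = sum(reversed & down),
    reversed_down = sum(reversed & up),
    dependent_up = sum(dependent & down),
    dependent_down = sum(dependent & up)
  )
}

#' @export
print.cn_cascade <- function(x, ...) {
  s <- x$summary
  cat("<cn_cascade>\n")
  cat(sprintf("  %d genes detected, %d expressed (TPM >= %g)\n",
              s$detected, s$expressed, x$config$min_tpm))
  cat(sprintf("  Src-affected: %d (%d up, %d down)\n",
              s$src_up + s$src_down, s$src_up, s$src_down))
  cat(sprintf("  contact-reversed: %d (%d induced, %d suppressed by contact)\n",
              s$reversed_up + s$reversed_down, s$reversed_up, s$reversed_down))
  cat(sprintf("  cadherin-dependent: %d (%d induced, %d suppressed)\n",
              s$dependent_up + s$dependent_down, s$dependent_up,
              s$dependent_down))
  invisible(x)
}

#' @rdname run_cascade
#' @param x A `cn_cascade` object.
#' @param ... Unused.
#' @export
tidy.cn_cascade <- function(x, ...) {
  x$genes
}

#' @rdname run_cascade
#' @export
glance.cn_cascade <- function(x, ...) {
  x$summary
}

#' Onion-layer bar chart for a cascade result
#'
#' @param object A `cn_cascade` object.
#' @param ... Unused.
#' @return A ggplot showing gene counts per onion layer.
#' @export
autoplot.cn_cascade <- function(object, ...) {
  counts <- object$genes |>
    count(.data$layer, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$layer, y = .data$n)) +
    ggplot2::geom_col(fill = "#8c2d2d") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Onion layers of the contact-normalization cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
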