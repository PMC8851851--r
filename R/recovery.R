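# Recovery scoring of a cascade classification against planted truth.

# Truth-positive and prediction-positive definitions per cascade stage.
stage_definitions <- function() {
  list(
    expression = list(
      truth = function(cls) cls != "not_expressed",
      pred = function(layer) layer != "not_expressed"
    ),
    src_effect = list(
      truth = function(cls) cls %in% c("src_up", "src_down",
                                       "reversed_independent_up",
                                       "reversed_independent_down",
                                       "reversed_dependent_up",
                                       "reversed_dependent_down"),
      pred = function(layer) layer %in% c("src_only",
                                          "cn_cadherin_independent",
                                          "cn_cadherin_dependent")
    ),
    reversal = list(
      truth = function(cls) grepl("^reversed_", cls),
      pred = function(layer) layer %in% c("cn_cadherin_independent",
                                          "cn_cadherin_dependent")
    ),
    cadherin = list(
      truth = function(cls) grepl("^reversed_dependent", cls),
      pred = function(layer) layer == "cn_cadherin_dependent"
    )
  )
}

#' Score a cascade classification against planted truth
#'
#' Compares per-gene onion layers from [run_cascade()] with the layers
#' implied by the planted classes of a simulation, producing a confusion
#' matrix over layers and, per cascade stage (expression filter, Src effect,
#' reversal, cadherin dependence), sensitivity and specificity. For each
#' stage, truth-positive genes are those whose planted class passes the
#' stage, and prediction-positive genes are those classified at or inside
#' the corresponding onion layer.
#'
#' @param truth Truth tibble from a `cn_simulation` (columns `gene_id`,
#'   `class_label`).
#' @param classification A `cn_cascade` object or its per-gene tibble
#'   (columns `gene_id`, `layer`).
#' @return A `cn_recovery` list: `confusion` (tibble `truth_layer`,
#'   `predicted_layer`, `n`), `stages` (tibble with per-stage tp/fp/tn/fn,
#'   `sensitivity`, `specificity`), and `accuracy` (fraction of genes whose
#'   predicted layer equals the planted layer).
#' @export
#' @examples
#' sim <- simulate_study(n_genes = 200, dispersion = 0.01, seed = 3)
#' res <- run_cascade(sim$counts, sim$design)
#' evaluate_recovery(sim$truth, res)
evaluate_recovery <- function(truth, classification) {
  genes <- if (inherits(classification, "cn_cascade")) {
    classification$genes
  } else {
    classification
  }
  if (!all(c("gene_id", "layer") %in% names(genes))) {
    stop("classification must carry gene_id and layer", call. = FALSE)
  }
  if (!setequal(truth$gene_id, genes$gene_id) ||
      nrow(truth) != nrow(genes)) {
    stop("truth and classification must cover the same gene set",
         call. = FALSE)
  }
  merged <- truth |>
    select("gene_id", "class_label") |>
    mutate(truth_layer = factor(class_to_layer(.data$class_label),
                                levels = cn_layers())) |>
    left_join(genes |> select("gene_id", predicted_layer = "layer"),
              by = "gene_id") |>
    mutate(predicted_layer = factor(.data$predicted_layer,
                                    levels = cn_layers()))

  confusion <- merged |>
    count(.data$truth_layer, .data$predicted_layer, .drop = FALSE)

  defs <- stage_definitions()
  stages <- purrr::imap(defs, function(d, stage) {
    tp_set <- d$truth(merged$class_label)
    pp_set <- d$pred(as.character(merged$predicted_layer))
    tp <- sum(tp_set & pp_set)
    fn <- sum(tp_set & !pp_set)
    fp <- sum(!tp_set & pp_set)
    tn <- sum(!tp_set & !pp_set)
    tibble(stage = stage, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }) |> bind_rows()

  structure(
    list(confusion = confusion, stages = stages,
         accuracy = mean(merged$truth_layer == merged$predicted_layer)),
    class = "cn_recovery"
  )
}

#' @export
print.cn_recovery <- function(x, ...) {
  cat("<cn_recovery>\n")
  cat(sprintf("  layer accuracy: %.4f\n", x$accuracy))
  print(x$stages)
  invisible(x)
}

#' @rdname evaluate_recovery
#' @param x A `cn_recovery` object.
#' @param ... Unused.
#' @export
tidy.cn_recovery <- function(x, ...) {
  x$stages
}

#' @rdname evaluate_recovery
#' @export
glance.cn_recovery <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         min_sensitivity = min(x$stages$sensitivity, na.rm = TRUE),
         min_specificity = min(x$stages$specificity, na.rm = TRUE))
}

#' Confusion-matrix heatmap for a recovery result
#'
#' @param object A `cn_recovery` object.
#' @param ... Unused.
#' @return A ggplot of the truth-versus-predicted layer counts.
#' @export
autoplot.cn_recovery <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$predicted_layer,
                               y = .data$truth_layer, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#8c2d2d") +
    ggplot2::labs(x = "predicted layer", y = "planted layer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
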