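# Cellular-location categorization and interaction-network neighborhoods
# for classified genes. Annotation and edge tables are flat user-supplied
# TSV exports; no web service is queried.

cn_location_tokens <- function() {
  c("extracellular", "plasma_membrane", "cytoplasm", "nucleus")
}

cn_categories <- function() {
  c("extracellular", "plasma_membrane", "cytoplasm", "nucleus",
    "noncoding_rna", "unclassified")
}

#' Interaction-score presets
#'
#' The three standard confidence tiers of protein-protein interaction
#' scoring: `medium` (0.400), `high` (0.700), `highest` (0.900).
#'
#' @return Named numeric vector of minimum interaction scores.
#' @export
#' @examples
#' string_presets()["high"]
string_presets <- function() {
  c(medium = 0.400, high = 0.700, highest = 0.900)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `biotype` (`coding`/`noncoding`), and
#' `locations` (semicolon-separated subset of extracellular,
#' plasma_membrane, cytoplasm, nucleus; may be empty).
#'
#' @param path Path to the TSV file.
#' @return Annotation tibble.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("gene_id", "biotype", "locations") %in% names(ann))) {
    stop("annotation file needs columns gene_id, biotype, locations",
         call. = FALSE)
  }
  ann$locations[is.na(ann$locations)] <- ""
  as_tibble(ann)
}

#' Assign each gene to one cellular-location category
#'
#' Noncoding genes are `noncoding_rna` regardless of locations; coding genes
#' take the first matching location in the precedence extracellular >
#' plasma_membrane > cytoplasm > nucleus; coding genes with no location are
#' `unclassified`.
#'
#' @param annotations Annotation tibble (`gene_id`, `biotype`, `locations`
#'   with semicolon-separated tokens).
#' @return The tibble with an added `category` column.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = "g1", biotype = "coding",
#'                       locations = "plasma_membrane;nucleus")
#' assign_location(ann)$category
assign_location <- function(annotations) {
  if (anyDuplicated(annotations$gene_id)) {
    stop("one row per gene_id required in annotations", call. = FALSE)
  }
  bad_bio <- setdiff(unique(annotations$biotype), c("coding", "noncoding"))
  if (length(bad_bio) > 0) {
    stop(sprintf("unknown biotype token: %s",
                 paste(bad_bio, collapse = ", ")), call. = FALSE)
  }
  loc_list <- strsplit(annotations$locations, ";", fixed = TRUE)
  loc_list <- lapply(loc_list, function(l) trimws(l[nzchar(trimws(l))]))
  bad_loc <- setdiff(unique(unlist(loc_list)), cn_location_tokens())
  if (length(bad_loc) > 0) {
    stop(sprintf("unknown location token: %s",
                 paste(bad_loc, collapse = ", ")), call. = FALSE)
  }
  category <- purrr::map2_chr(annotations$biotype, loc_list,
    function(bio, locs) {
      if (bio == "noncoding") return("noncoding_rna")
      hit <- cn_location_tokens()[cn_location_tokens() %in% locs]
      if (length(hit) == 0) "unclassified" else hit[1]
    })
  annotations |> mutate(category = category)
}

#' Location counts per onion layer
#'
#' Cross-tabulates classified genes by onion layer and cellular-location
#' category. Genes without an annotation row are counted as `unclassified`,
#' so row sums over categories always equal layer sizes.
#'
#' @param classification A `cn_cascade` object or its per-gene tibble.
#' @param annotations Annotation tibble (see [assign_location()]).
#' @return Tibble with `layer`, `category`, `n`, complete over all
#'   layer-category combinations present in the classification.
#' @export
location_summary <- function(classification, annotations) {
  genes <- if (inherits(classification, "cn_cascade")) {
    classification$genes
  } else {
    classification
  }
  if (nrow(genes) == 0) {
    return(tibble(layer = factor(character(), levels = cn_layers()),
                  category = character(), n = integer()))
  }
  ann <- assign_location(annotations)
  genes |>
    select("gene_id", "layer") |>
    left_join(ann |> select("gene_id", "category"), by = "gene_id") |>
    mutate(
      category = factor(
        ifelse(is.na(.data$category), "unclassified", .data$category),
        levels = cn_categories()),
      layer = factor(.data$layer, levels = cn_layers())
    ) |>
    count(.data$layer, .data$category, .drop = FALSE)
}

#' Read a scored interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `score` (confidence in 0-1).
#' Edges are undirected; self-edges are rejected.
#'
#' @param path Path to the TSV file.
#' @return Edge tibble.
#' @export
read_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  validate_edges(edges)
}

validate_edges <- function(edges) {
  if (!all(c("gene_a", "gene_b", "score") %in% names(edges))) {
    stop("edge table needs columns gene_a, gene_b, score", call. = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("edge scores must be in [0, 1]", call. = FALSE)
  }
  as_tibble(edges)
}

#' Score-thresholded interaction neighborhood of a gene
#'
#' All genes sharing an edge with `focus` at confidence at or above
#' `min_score`. Edges are treated as undirected. A focus gene absent from
#' the edge list yields an empty neighborhood with a warning.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`, `score`).
#' @param focus Focal gene identifier.
#' @param min_score Numeric threshold in 0-1, or a preset name from
#'   [string_presets()] (`"medium"`, `"high"`, `"highest"`).
#' @return Character vector of neighbor gene identifiers (sorted, unique).
#' @export
#' @examples
#' edges <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"),
#'                         score = c(0.5, 0.3))
#' neighborhood(edges, "A", "medium")
neighborhood <- function(edges, focus, min_score = "medium") {
  edges <- validate_edges(edges)
  if (is.character(min_score)) {
    min_score <- string_presets()[[match.arg(min_score,
                                             names(string_presets()))]]
  }
  if (min_score < 0 || min_score > 1) {
    stop("min_score must be in [0, 1]", call. = FALSE)
  }
  if (!focus %in% c(edges$gene_a, edges$gene_b)) {
    warning(sprintf("focus gene '%s' absent from edge list", focus),
            call. = FALSE)
    return(character())
  }
  kept <- edges |> filter(.data$score >= min_score)
  sort(unique(c(kept$gene_b[kept$gene_a == focus],
                kept$gene_a[kept$gene_b == focus])))
}
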