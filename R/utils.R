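# Shared building blocks: the four-group layered-culture design, expression
# table helpers, the pooled-variance t-test used by every stage, and the
# pseudocount fold change.

#' Layered-culture group labels
#'
#' The four conditions of the layered-culture design, in canonical order:
#' nontransformed cells over themselves (`N_self`), Src-transformed cells over
#' themselves (`T_self`), transformed cells over cadherin-competent
#' nontransformed cells (`T_vs_N`), and transformed cells over cadherin
#' knockout cells (`T_vs_KO`).
#'
#' @return Character vector of the four group labels.
#' @export
#' @examples
#' cn_groups()
cn_groups <- function() {
  c("N_self", "T_self", "T_vs_N", "T_vs_KO")
}

# The onion layers, innermost last.
cn_layers <- function() {
  c("not_expressed", "expressed_unaffected", "src_only",
    "cn_cadherin_independent", "cn_cadherin_dependent")
}

# Planted gene classes understood by the simulator.
cn_classes <- function() {
  c("not_expressed", "unaffected", "src_up", "src_down",
    "reversed_independent_up", "reversed_independent_down",
    "reversed_dependent_up", "reversed_dependent_down")
}

# Map a planted class to the onion layer a perfect classifier assigns it.
class_to_layer <- function(class_label) {
  map <- c(
    not_expressed = "not_expressed",
    unaffected = "expressed_unaffected",
    src_up = "src_only",
    src_down = "src_only",
    reversed_independent_up = "cn_cadherin_independent",
    reversed_independent_down = "cn_cadherin_independent",
    reversed_dependent_up = "cn_cadherin_dependent",
    reversed_dependent_down = "cn_cadherin_dependent"
  )
  unname(map[class_label])
}

# Columns of an expression tibble that hold sample values.
sample_cols <- function(x) {
  setdiff(names(x), c("gene_id", "length"))
}

expression_units <- function(x) {
  u <- attr(x, "units", exact = TRUE)
  if (is.null(u)) "counts" else u
}

`expression_units<-` <- function(x, value) {
  attr(x, "units") <- value
  x
}

# Validate an expression tibble (gene_id, optional length, sample columns).
validate_expression <- function(x, require_length = FALSE) {
  if (!is.data.frame(x)) {
    stop("expression data must be a data frame", call. = FALSE)
  }
  if (!"gene_id" %in% names(x)) {
    stop("expression data must have a 'gene_id' column", call. = FALSE)
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- x$gene_id[duplicated(x$gene_id)][1]
    stop(sprintf("duplicate gene identifier: '%s'", dup), call. = FALSE)
  }
  sc <- sample_cols(x)
  if (length(sc) == 0) {
    stop("expression data has no sample columns", call. = FALSE)
  }
  if (anyDuplicated(sc)) {
    stop("duplicate sample identifiers in expression data", call. = FALSE)
  }
  vals <- as.matrix(x[sc])
  if (!is.numeric(vals)) {
    bad <- sc[!vapply(x[sc], is.numeric, logical(1))][1]
    stop(sprintf("non-numeric values in sample column '%s'", bad),
         call. = FALSE)
  }
  if (anyNA(vals)) stop("missing values in expression data", call. = FALSE)
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value for gene '%s' in sample '%s'",
                 x$gene_id[idx[1]], sc[idx[2]]), call. = FALSE)
  }
  if (require_length) {
    if (!"length" %in% names(x)) {
      stop("counts data must carry a 'length' column (bases) for TPM",
           call. = FALSE)
    }
    if (anyNA(x$length) || any(x$length <= 0)) {
      stop("all gene lengths must be positive", call. = FALSE)
    }
  }
  invisible(x)
}

# Validate a design tibble (sample_id, group) against an expression tibble.
validate_design <- function(design, x = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "group") %in% names(design))) {
    stop("design must be a data frame with columns sample_id and group",
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  unknown <- setdiff(unique(design$group), cn_groups())
  if (length(unknown) > 0) {
    stop(sprintf("unknown group name(s) in design: %s (expected %s)",
                 paste(unknown, collapse = ", "),
                 paste(cn_groups(), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(x)) {
    sc <- sample_cols(x)
    missing_in_counts <- setdiff(design$sample_id, sc)
    if (length(missing_in_counts) > 0) {
      stop(sprintf("design sample(s) absent from expression data: %s",
                   paste(missing_in_counts, collapse = ", ")), call. = FALSE)
    }
    missing_in_design <- setdiff(sc, design$sample_id)
    if (length(missing_in_design) > 0) {
      stop(sprintf("expression sample(s) missing from design: %s",
                   paste(missing_in_design, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(design)
}

# Samples per group as a named list, canonical group order.
samples_by_group <- function(design) {
  grp <- intersect(cn_groups(), unique(design$group))
  setNames(
    lapply(grp, function(g) design$sample_id[design$group == g]),
    grp
  )
}

# genes x groups matrix of within-group replicate means.
group_mean_matrix <- function(x, design) {
  sbg <- samples_by_group(design)
  m <- as.matrix(x[sample_cols(x)])
  out <- vapply(sbg, function(s) rowMeans(m[, s, drop = FALSE]),
                numeric(nrow(x)))
  if (nrow(x) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(sbg)))
  rownames(out) <- x$gene_id
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' The classical equal-variance two-sample t-test used throughout the
#' classification cascade and the assay statistics: pooled variance,
#' `df = n_a + n_b - 2`, two-tailed p from the t distribution. When both
#' samples have zero variance the test is degenerate: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with a warning (reachable only
#' on noise-free data).
#'
#' @param a,b Numeric vectors of replicate values (each of length >= 2).
#' @return A one-row tibble with columns `statistic` (t), `df`, and `p.value`.
#' @export
#' @examples
#' student_t_test(c(1, 2, 3), c(2, 4, 6))
student_t_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("a and b must be numeric vectors", call. = FALSE)
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  res <- row_t_test(matrix(a, nrow = 1), matrix(b, nrow = 1))
  tibble(statistic = res$t, df = res$df, p.value = res$p)
}

# Vectorized pooled-variance t over matrix rows; A, B: genes x replicates.
row_t_test <- function(A, B) {
  na <- ncol(A)
  nb <- ncol(B)
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  degen <- se == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    tt[eq] <- 0
    p[eq] <- 1
    ne <- degen & (ma != mb)
    if (any(ne)) {
      warning("zero pooled variance with unequal means; p set to 0",
              call. = FALSE)
      tt[ne] <- sign(ma[ne] - mb[ne]) * Inf
      p[ne] <- 0
    }
  }
  list(t = unname(tt), df = df, p = unname(p))
}

#' Pseudocount-stabilized fold change
#'
#' Ratio of two group means with an additive pseudocount in numerator and
#' denominator, bounding ratios for near-zero genes:
#' `(mean_num + pseudocount) / (mean_den + pseudocount)`.
#'
#' @param mean_num,mean_den Non-negative group means (vectorized).
#' @param pseudocount Non-negative additive stabilizer (default 1 TPM).
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' fold_change(10, 0)        # 11
#' fold_change(0, 10)        # 1/11
fold_change <- function(mean_num, mean_den, pseudocount = 1) {
  if (any(mean_num < 0) || any(mean_den < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (any(mean_num + pseudocount == 0 & mean_den + pseudocount == 0)) {
    stop("fold change undefined: both means and pseudocount are zero",
         call. = FALSE)
  }
  (mean_num + pseudocount) / (mean_den + pseudocount)
}
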