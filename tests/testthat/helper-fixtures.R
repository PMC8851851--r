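# Fixtures built in code: small expression tables, random unstructured
# datasets, and a deliberately naive straight-line reimplementation of the
# cascade criteria used as an independent oracle.

make_design <- function(replicates = 3) {
  tibble::tibble(
    sample_id = paste0(rep(cn_groups(), each = replicates), "_",
                       rep(seq_len(replicates), 4)),
    group = rep(cn_groups(), each = replicates)
  )
}

# Expression tibble from a genes x samples matrix.
make_expr <- function(values, lengths = NULL, design = make_design(),
                      units = "counts") {
  n <- nrow(values)
  if (is.null(lengths)) lengths <- rep(1000, n)
  x <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)), length = lengths),
    tibble::as_tibble(as.data.frame(values) |>
                        stats::setNames(design$sample_id))
  )
  attr(x, "units") <- units
  x
}

# Unstructured random dataset: per-gene per-group means drawn independently
# so every cascade branch is exercised by chance.
random_dataset <- function(n_genes = 200, seed = 1, replicates = 3) {
  set.seed(seed)
  design <- make_design(replicates)
  base <- stats::rlnorm(n_genes, log(20), 1.5)
  fac <- matrix(exp(stats::rnorm(n_genes * 4, 0, 1.5)), ncol = 4)
  mu <- base * fac
  counts <- matrix(0, nrow = n_genes, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    g <- match(design$group[j], cn_groups())
    counts[, j] <- stats::rnbinom(n_genes, mu = mu[, g], size = 1 / 0.05)
  }
  make_expr(counts, lengths = round(stats::runif(n_genes, 500, 5000)),
            design = design)
}

# Reference p-value: stats::t.test with the same zero-variance convention.
oracle_p <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

# Straight-line per-gene reimplementation of the three printed criteria:
# >= 3-fold p < 0.05 Src effect; >= 40% inverse change p < 0.08 reversal;
# >= 2-fold direction-consistent p < 0.05 cadherin dependence.
oracle_cascade <- function(tpm, design) {
  sbg <- split(design$sample_id, design$group)
  layers <- character(nrow(tpm))
  for (i in seq_len(nrow(tpm))) {
    vals <- lapply(sbg, function(s) as.numeric(unlist(tpm[i, s])))
    gm <- vapply(vals, mean, 0)
    if (max(gm) < 1) {
      layers[i] <- "not_expressed"
      next
    }
    fc <- (gm[["T_self"]] + 1) / (gm[["N_self"]] + 1)
    p <- oracle_p(vals$T_self, vals$N_self)
    src <- if (fc >= 3 && p < 0.05) "up"
           else if (fc <= 1 / 3 && p < 0.05) "down" else "none"
    if (src == "none") {
      layers[i] <- "expressed_unaffected"
      next
    }
    change <- (gm[["T_vs_N"]] - gm[["T_self"]]) / (gm[["T_self"]] + 1)
    p_rev <- oracle_p(vals$T_self, vals$T_vs_N)
    opposite <- if (src == "up") change < 0 else change > 0
    if (!(opposite && abs(change) >= 0.40 && p_rev < 0.08)) {
      layers[i] <- "src_only"
      next
    }
    fcc <- (gm[["T_vs_KO"]] + 1) / (gm[["T_vs_N"]] + 1)
    p_cdh <- oracle_p(vals$T_vs_N, vals$T_vs_KO)
    dep <- if (src == "up") fcc >= 2 else fcc <= 1 / 2
    layers[i] <- if (dep && p_cdh < 0.05) "cn_cadherin_dependent"
                 else "cn_cadherin_independent"
  }
  layers
}

# Nesting/partition assertions shared by several tests.
expect_onion_invariants <- function(res) {
  g <- res$genes
  expect_false(anyNA(g$layer))
  expect_true(all(as.character(g$layer) %in% cn_layers()))
  expressed <- g$expressed
  affected <- g$src_class %in% c("up", "down")
  reversed <- !is.na(g$reversed) & g$reversed
  dependent <- g$cdh_class %in% "dependent"
  expect_true(all(!affected | expressed))
  expect_true(all(!reversed | affected))
  expect_true(all(!dependent | reversed))
  s <- res$summary
  expect_identical(s$src_up + s$src_down, sum(affected))
  expect_identical(s$reversed_up + s$reversed_down, sum(reversed))
  expect_identical(s$dependent_up + s$dependent_down, sum(dependent))
  expect_identical(s$detected, nrow(g))
  expect_identical(s$expressed, sum(expressed))
  invisible(res)
}
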