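# Gamma-Poisson count simulator for the four-group layered-culture design,
# with planted gene classes carried as ground truth for recovery testing.

#' Planted gene specification
#'
#' One row of a simulation specification: a gene class with its effect sizes.
#' Classes: `unaffected`; `src_up`/`src_down` (Src multiplies expression by
#' `src_fold` up or down, no contact effect); `reversed_independent_up/_down`
#' (contact with cadherin-competent cells removes — or, for `_down` classes,
#' adds — `reversal_fraction` of the transformed-self level; knockout
#' coculture behaves like competent coculture); `reversed_dependent_up/_down`
#' (as above, but knockout coculture moves expression back toward the
#' transformed-self direction by `cdh_fold`); `not_expressed` (constant
#' `base_mean`, intended to sit well below the expression filter).
#' The `_up`/`_down` suffix is the direction of the Src effect.
#'
#' @param class_label One of the classes above.
#' @param n_genes Number of genes drawn from this specification.
#' @param base_mean Expected expression of the normal-self group, on the
#'   relative TPM scale (see [simulate_dataset()]).
#' @param src_fold Multiplicative Src effect (>= 1).
#' @param reversal_fraction Fraction of the transformed-self level removed
#'   (for `_up`) or added (for `_down`) under competent coculture, in (0, 1)
#'   for `_up` classes.
#' @param cdh_fold Fold difference between knockout and competent coculture
#'   for dependent classes (>= 1).
#' @param dispersion Negative-binomial dispersion (>= 0; variance is
#'   `mu + dispersion * mu^2`).
#' @return One-row tibble usable as (part of) the `specs` argument of
#'   [simulate_dataset()].
#' @export
#' @examples
#' dplyr::bind_rows(
#'   planted_spec("unaffected", n_genes = 50),
#'   planted_spec("src_up", n_genes = 5, src_fold = 8)
#' )
planted_spec <- function(class_label, n_genes = 1, base_mean = 50,
                         src_fold = 8, reversal_fraction = 0.6,
                         cdh_fold = 4, dispersion = 0.05) {
  class_label <- match.arg(class_label, cn_classes())
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (base_mean < 0) stop("base_mean must be non-negative", call. = FALSE)
  if (src_fold < 1) stop("src_fold must be >= 1", call. = FALSE)
  if (cdh_fold < 1) stop("cdh_fold must be >= 1", call. = FALSE)
  if (grepl("_up$", class_label) &&
      (reversal_fraction <= 0 || reversal_fraction >= 1)) {
    stop("reversal_fraction must be in (0, 1) for *_up classes",
         call. = FALSE)
  }
  if (reversal_fraction < 0) {
    stop("reversal_fraction must be non-negative", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  tibble(class_label = class_label, n_genes = as.integer(n_genes),
         base_mean = base_mean, src_fold = src_fold,
         reversal_fraction = reversal_fraction, cdh_fold = cdh_fold,
         dispersion = dispersion)
}

# Expected expression per group for one truth row (vectorized over rows).
planted_group_means <- function(truth) {
  up <- grepl("_up$", truth$class_label) | truth$class_label == "src_up"
  down <- grepl("_down$", truth$class_label)
  affected <- up | down
  t_self <- truth$base_mean
  t_self[up] <- truth$base_mean[up] * truth$src_fold[up]
  t_self[down] <- truth$base_mean[down] / truth$src_fold[down]
  rev <- grepl("^reversed_", truth$class_label)
  t_vs_n <- t_self
  rev_up <- rev & up
  rev_down <- rev & down
  t_vs_n[rev_up] <- t_self[rev_up] * (1 - truth$reversal_fraction[rev_up])
  t_vs_n[rev_down] <- t_self[rev_down] * (1 + truth$reversal_fraction[rev_down])
  dep <- grepl("^reversed_dependent", truth$class_label)
  t_vs_ko <- t_vs_n
  t_vs_ko[dep & up] <- t_vs_n[dep & up] * truth$cdh_fold[dep & up]
  t_vs_ko[dep & down] <- t_vs_n[dep & down] / truth$cdh_fold[dep & down]
  m <- cbind(N_self = truth$base_mean, T_self = t_self,
             T_vs_N = t_vs_n, T_vs_KO = t_vs_ko)
  m
}

# Deterministic per-gene seed derived from the root seed; independent of the
# total gene count so extending a spec does not perturb earlier genes.
gene_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 9973) %% 2147483629
}

#' Simulate a layered-culture RNA-seq dataset with planted truth
#'
#' Draws gene-by-sample counts from a gamma-Poisson (negative-binomial)
#' model whose per-group expected TPM follows the planted specification:
#' four groups times `replicates` samples, per-gene dispersion, per-sample
#' library sizes jittered +/-10% around `library_size`, and gene lengths
#' drawn uniformly from 500-5000 bases unless supplied.
#'
#' TPM is compositional (each sample is renormalized to one million), so
#' planted means are interpreted on a relative scale: all planted means are
#' rescaled by one common factor chosen so the normal-self profile sums to
#' 1e6. The common factor preserves every cross-group fold change exactly;
#' realized fold changes in non-reference groups are additionally attenuated
#' by the ratio of group profile sums, which is small when planted effects
#' are balanced between up and down.
#'
#' @param specs Tibble of planted specifications, as built by rows of
#'   [planted_spec()] (columns `class_label`, `n_genes`, `base_mean`,
#'   `src_fold`, `reversal_fraction`, `cdh_fold`, `dispersion`).
#' @param replicates Replicates per group (default 3, the study design).
#' @param library_size Expected reads per sample.
#' @param seed Integer root seed; identical seed and specs give bit-identical
#'   counts.
#' @param lengths Optional vector of per-gene lengths in bases.
#' @return A `cn_simulation` list: `counts` (expression tibble with
#'   `gene_id`, `length`, sample columns; units `"counts"`), `design`,
#'   `truth` (per-gene class, parameters, and expected TPM per group), and
#'   `seed`.
#' @export
#' @examples
#' sim <- simulate_dataset(planted_spec("unaffected", n_genes = 10), seed = 1)
#' sim$counts
simulate_dataset <- function(specs, replicates = 3, library_size = 1e6,
                             seed = 1, lengths = NULL) {
  if (!is.data.frame(specs) || nrow(specs) == 0) {
    stop("specs must be a non-empty data frame (see planted_spec())",
         call. = FALSE)
  }
  needed <- c("class_label", "n_genes", "base_mean", "src_fold",
              "reversal_fraction", "cdh_fold", "dispersion")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols) > 0) {
    stop(sprintf("specs is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(specs$n_genes < 1)) stop("n_genes must be >= 1", call. = FALSE)
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  if (any(specs$dispersion < 0)) {
    stop("dispersion must be >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(specs$class_label), cn_classes())
  if (length(bad) > 0) {
    stop(sprintf("unknown class_label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }

  truth <- specs[rep(seq_len(nrow(specs)), specs$n_genes), needed]
  n_genes <- nrow(truth)
  truth$gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  truth <- as_tibble(truth) |> relocate("gene_id") |> select(-"n_genes")

  groups <- cn_groups()
  design <- tibble(
    sample_id = paste0(rep(groups, each = replicates), "_",
                       rep(seq_len(replicates), times = length(groups))),
    group = rep(groups, each = replicates)
  )

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  # library jitter first (depends on replicates only), then lengths drawn
  # sequentially: extending a spec leaves earlier genes' draws unchanged
  lib <- library_size * runif(nrow(design), 0.9, 1.1)
  if (is.null(lengths)) {
    lengths <- round(runif(n_genes, 500, 5000))
  } else if (length(lengths) != n_genes || any(lengths <= 0)) {
    stop("lengths must be positive, one per gene", call. = FALSE)
  }

  tpm <- planted_group_means(truth)
  scale_factor <- 1e6 / sum(tpm[, "N_self"])
  tpm <- tpm * scale_factor
  colnames_tpm <- paste0("expected_tpm_", colnames(tpm))

  # expected reads: within each sample, proportional to planted TPM x length
  w <- tpm * lengths                 # genes x groups
  group_tot <- colSums(w)
  mu <- matrix(0, nrow = n_genes, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    g <- design$group[j]
    mu[, j] <- lib[j] * w[, g] / group_tot[g]
  }

  counts <- matrix(0L, nrow = n_genes, ncol = nrow(design),
                   dimnames = list(truth$gene_id, design$sample_id))
  for (i in seq_len(n_genes)) {
    set.seed(gene_seed(seed, i))
    d <- truth$dispersion[i]
    lam <- if (d > 0) {
      ifelse(mu[i, ] == 0, 0,
             rgamma(ncol(mu), shape = 1 / d, rate = 1 / (d * mu[i, ])))
    } else {
      mu[i, ]
    }
    counts[i, ] <- rpois(ncol(mu), lam)
  }

  counts_tbl <- bind_cols(
    tibble(gene_id = truth$gene_id, length = lengths),
    as_tibble(as.data.frame(counts))
  )
  expression_units(counts_tbl) <- "counts"
  truth <- bind_cols(truth, as_tibble(as.data.frame(tpm)) |>
                       setNames(colnames_tpm))

  structure(
    list(counts = counts_tbl, design = design, truth = truth, seed = seed),
    class = "cn_simulation"
  )
}

#' @export
print.cn_simulation <- function(x, ...) {
  cat("<cn_simulation>\n")
  cat(sprintf("  %d genes x %d samples (seed %s)\n",
              nrow(x$counts), nrow(x$design), format(x$seed)))
  print(count(x$truth, .data$class_label))
  invisible(x)
}

#' Simulate the study conditions of the layered-culture experiment
#'
#' Builds a full mixed-class dataset emulating the study's design: four
#' groups times three replicates, a lognormal baseline abundance
#' distribution, a silent-gene fraction below the expression filter, and
#' planted Src/reversal/cadherin effects with clear margins over the cascade
#' thresholds. Per 1000 genes the default mixture plants 100 silent genes,
#' 780 unaffected genes, and 20 genes in each of the six affected classes
#' (balanced up/down so compositional renormalization stays mild).
#'
#' @param n_genes Total number of genes.
#' @param replicates Replicates per group.
#' @param library_size Expected reads per sample (default 3e7, the
#'   per-sample depth of a paired-end HiSeq lane shared by twelve
#'   libraries; below ~1e7 the Poisson count floor dominates low-abundance
#'   Src-down genes).
#' @param seed Integer root seed.
#' @param src_fold,reversal_fraction,cdh_fold Planted effect sizes.
#' @param dispersion Negative-binomial dispersion shared by all genes.
#' @param class_props Named numeric vector of mixture proportions over
#'   [cn_classes()]; must sum to 1.
#' @param base_meanlog,base_sdlog Lognormal parameters of the relative
#'   baseline abundance of expressed genes.
#' @param silent_tpm Target TPM of `not_expressed` genes after rescaling
#'   (default 0.001, effectively zero reads).
#' @return A `cn_simulation` (see [simulate_dataset()]).
#' @export
#' @examples
#' sim <- simulate_study(n_genes = 100, seed = 7)
#' table(sim$truth$class_label)
simulate_study <- function(n_genes = 2000, replicates = 3,
                           library_size = 3e7, seed = 1,
                           src_fold = 8, reversal_fraction = 0.6,
                           cdh_fold = 4, dispersion = 0.05,
                           class_props = c(
                             not_expressed = 0.10, unaffected = 0.78,
                             src_up = 0.02, src_down = 0.02,
                             reversed_independent_up = 0.02,
                             reversed_independent_down = 0.02,
                             reversed_dependent_up = 0.02,
                             reversed_dependent_down = 0.02),
                           base_meanlog = log(50), base_sdlog = 1,
                           silent_tpm = 0.001) {
  if (abs(sum(class_props) - 1) > 1e-8) {
    stop("class_props must sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(class_props), cn_classes())
  if (length(bad) > 0) {
    stop(sprintf("unknown class in class_props: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n_per <- round(class_props * n_genes)
  n_per[1] <- n_per[1] + (n_genes - sum(n_per))  # absorb rounding
  n_per <- n_per[n_per > 0]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed + 1L)  # spec-construction stream, distinct from count stream

  specs <- purrr::map2(names(n_per), n_per, function(cls, n) {
    base <- if (cls == "not_expressed") {
      rep(1, n)  # placeholder; set from silent_tpm below
    } else {
      rlnorm(n, meanlog = base_meanlog, sdlog = base_sdlog)
    }
    tibble(class_label = cls, n_genes = 1L, base_mean = base,
           src_fold = src_fold, reversal_fraction = reversal_fraction,
           cdh_fold = cdh_fold, dispersion = dispersion)
  }) |> bind_rows()

  # place silent genes at silent_tpm on the final (rescaled) TPM scale:
  # the rescale factor is 1e6 / sum(N_self), dominated by expressed genes
  expressed_sum <- sum(specs$base_mean[specs$class_label != "not_expressed"])
  n_silent <- sum(specs$class_label == "not_expressed")
  if (n_silent > 0) {
    # solve b so that b * 1e6 / (expressed_sum + n_silent * b) = silent_tpm
    b <- silent_tpm * expressed_sum / (1e6 - silent_tpm * n_silent)
    specs$base_mean[specs$class_label == "not_expressed"] <- b
  }

  simulate_dataset(specs, replicates = replicates,
                   library_size = library_size, seed = seed)
}

#' Write a simulated dataset as TSV files
#'
#' Writes `counts.tsv` (gene_id + one column per sample), `lengths.tsv`,
#' `design.tsv`, and `truth.tsv` into `dir`, in the formats read back by
#' [read_expression()].
#'
#' @param sim A `cn_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cn_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$counts |> select(-"length"), paths["counts"])
  readr::write_tsv(sim$counts |> select("gene_id", "length"),
                   paths["lengths"])
  readr::write_tsv(sim$design, paths["design"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
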