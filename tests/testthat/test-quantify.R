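test_that("TPM normalization matches the hand-evaluated formula", {
  # single gene: forced to 1e6
  x1 <- make_expr(matrix(5, 1, 12))
  t1 <- tpm_normalize(x1)
  expect_true(all(as.matrix(t1[sample_cols(t1)]) == 1e6))

  # equal counts, equal lengths: split evenly
  x2 <- make_expr(matrix(7, 2, 12))
  t2 <- tpm_normalize(x2)
  expect_true(all(as.matrix(t2[sample_cols(t2)]) == 5e5))

  # counts (10, 10), lengths (1000, 2000): rates 0.01 / 0.005
  x3 <- make_expr(matrix(10, 2, 12), lengths = c(1000, 2000))
  t3 <- tpm_normalize(x3)
  expect_equal(unname(unlist(t3[1, sample_cols(t3)])),
               rep(2e6 / 3, 12), tolerance = 1e-12)
  expect_equal(unname(unlist(t3[2, sample_cols(t3)])),
               rep(1e6 / 3, 12), tolerance = 1e-12)
})

test_that("TPM is invariant to per-sample count scaling and flags units", {
  x <- random_dataset(50, seed = 4)
  t1 <- tpm_normalize(x)
  expect_identical(attr(t1, "units"), "tpm")
  expect_error(tpm_normalize(t1), "already TPM")

  x2 <- x
  x2[["T_self_1"]] <- x2[["T_self_1"]] * 13
  t2 <- tpm_normalize(x2)
  expect_equal(t1$T_self_1, t2$T_self_1, tolerance = 1e-12)
})

test_that("TPM rejects all-zero samples and negative or missing input", {
  x <- make_expr(matrix(1, 3, 12))
  x$N_self_1 <- 0
  expect_error(tpm_normalize(x), "all-zero sample.*N_self_1")
  bad <- make_expr(matrix(1, 2, 12))
  bad$T_self_2[1] <- -3
  expect_error(tpm_normalize(bad), "negative value.*g001.*T_self_2")
  nolen <- make_expr(matrix(1, 2, 12))
  nolen$length <- NULL
  expect_error(tpm_normalize(nolen), "length")
})

test_that("expression filter uses inclusive group means and is monotone", {
  design <- make_design()
  # group means (0.5, 0.9, 0.2, 0.8) and (0.5, 1.0, 0.2, 0.1)
  v <- rbind(
    rep(c(0.5, 0.9, 0.2, 0.8), each = 3),
    rep(c(0.5, 1.0, 0.2, 0.1), each = 3),
    rep(c(10, 20, 5, 2), each = 3)
  )
  x <- make_expr(v, units = "tpm")
  f <- expression_filter(x, design, min_tpm = 1)
  expect_identical(f$expressed, c(FALSE, TRUE, TRUE))

  # raising the threshold never adds genes
  kept1 <- f$gene_id[f$expressed]
  for (thr in c(2, 5, 11)) {
    f2 <- expression_filter(x, design, min_tpm = thr)
    expect_true(all(f2$gene_id[f2$expressed] %in% kept1))
    kept1 <- f2$gene_id[f2$expressed]
  }

  # any-sample scope admits a gene whose group means all fall short
  y <- make_expr(matrix(c(1.5, rep(0.1, 11)), 1, 12), units = "tpm")
  expect_false(expression_filter(y, design)$expressed)
  expect_true(expression_filter(y, design, scope = "any_sample")$expressed)
})

test_that("reading counts, lengths and design round-trips writer output", {
  sim <- simulate_study(n_genes = 30, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_expression(paths["counts"], paths["lengths"],
                          paths["design"])
  expect_equal(back$expression$gene_id, sim$counts$gene_id)
  expect_equal(
    as.matrix(back$expression[sample_cols(back$expression)]),
    as.matrix(sim$counts[sample_cols(sim$counts)]),
    ignore_attr = TRUE
  )
  expect_equal(back$design, sim$design)
  expect_identical(table(back$design$group), table(sim$design$group))

  # a design naming a sample absent from the counts header
  bad_design <- sim$design
  bad_design$sample_id[1] <- "ghost_sample"
  readr::write_tsv(bad_design, file.path(dir, "bad_design.tsv"))
  expect_error(
    read_expression(paths["counts"], paths["lengths"],
                    file.path(dir, "bad_design.tsv")),
    "ghost_sample"
  )

  # a negative count is rejected with gene and sample context
  bad_counts <- sim$counts |> dplyr::select(-"length")
  bad_counts[3, 4] <- -1
  readr::write_tsv(bad_counts, file.path(dir, "bad_counts.tsv"))
  expect_error(
    read_expression(file.path(dir, "bad_counts.tsv"), paths["lengths"],
                    paths["design"]),
    sprintf("negative value.*%s", bad_counts$gene_id[3])
  )
})
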