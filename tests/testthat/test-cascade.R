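test_that("pooled t-test reproduces hand-computed and degenerate cases", {
  r <- student_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$statistic, -1.549, tolerance = 1e-3)
  expect_identical(r$df, 4)
  expect_equal(r$p.value, 0.196, tolerance = 1e-2)

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)

  const <- student_t_test(c(5, 5, 5), c(5, 5, 5))
  expect_identical(const$statistic, 0)
  expect_identical(const$p.value, 1)
  expect_warning(bad <- student_t_test(c(5, 5), c(6, 6)), "zero pooled")
  expect_identical(bad$p.value, 0)

  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("swapping t-test samples negates t and preserves p", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), mean = runif(1, 0, 10))
    b <- rnorm(sample(2:6, 1), mean = runif(1, 0, 10))
    f <- student_t_test(a, b)
    r <- student_t_test(b, a)
    expect_equal(f$statistic, -r$statistic, tolerance = 1e-12)
    expect_equal(f$p.value, r$p.value, tolerance = 1e-12)
  }
})

test_that("fold change applies the pseudocount symmetrically", {
  expect_identical(fold_change(7, 7, 0.5), 1)
  expect_identical(fold_change(10, 0, 1), 11)
  expect_equal(fold_change(0, 10, 1), 1 / 11)
  expect_equal(fold_change(10, 0, 1) * fold_change(0, 10, 1), 1)
  expect_error(fold_change(0, 0, 0), "undefined")
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("Src-effect stage applies inclusive fold and p cut-offs", {
  design <- make_design()
  # gene 1: N (10,10,10) vs T (40,41,39) -> up; gene 2: identical -> none
  # gene 3: fold exactly 3.0 with small p -> up (inclusive boundary)
  v <- rbind(
    c(10, 10, 10, 40, 41, 39, rep(10, 6)),
    rep(c(5, 5, 1, 1), each = 3),
    c(9, 10, 11, 31, 32, 33, rep(10, 6))
  )
  x <- make_expr(v, units = "tpm")
  res <- classify_src_effect(x, design)
  expect_identical(res$src_class, c("up", "none", "up"))
  expect_equal(res$src_fc[1], 41 / 11, tolerance = 1e-12)
  expect_lt(res$src_p[1], 0.05)
  expect_identical(res$src_fc[2], 1)
  expect_identical(res$src_p[2], 1)
  expect_identical(res$src_fc[3], 3)  # exactly threefold, still "up"
})

test_that("reversal stage requires an opposite-direction 40% change", {
  design <- make_design()
  # src-up genes; T_self then T_vs_N per column block
  v <- rbind(
    c(10, 10, 10, 100, 98, 102, 55, 54, 56, 55, 54, 56),   # ~45% down
    c(10, 10, 10, 100, 98, 102, 100, 98, 102, 100, 98, 102), # unchanged
    c(10, 10, 10, 100, 98, 102, 150, 148, 152, 150, 148, 152) # 50% UP
  )
  x <- make_expr(v, units = "tpm")
  src <- classify_src_effect(x, design)
  expect_true(all(src$src_class == "up"))
  rev <- classify_reversal(x, design, src_classes = src)
  expect_identical(rev$reversed, c(TRUE, FALSE, FALSE))
  expect_equal(rev$reversal_change[1], (55 - 100) / 101, tolerance = 1e-12)
  expect_lt(rev$reversal_p[1], 0.08)
  expect_identical(rev$reversal_change[2], 0)
  expect_gt(rev$reversal_change[3], 0)  # same direction: fails "inversely"

  none <- src |> dplyr::mutate(src_class = "none")
  expect_error(classify_reversal(x, design, src_classes = none),
               "Src-affected")
})

test_that("cadherin stage demands a direction-consistent differential", {
  design <- make_design()
  # all genes src-up and reversed; vary the knockout response
  base <- c(10, 10, 10, 100, 98, 102, 50, 51, 49)
  v <- rbind(
    c(base, 120, 118, 122),  # back up 2.4x -> dependent
    c(base, 50, 51, 49),     # same as competent coculture -> independent
    c(base, 24, 25, 26)      # 2x LOWER: inconsistent -> independent
  )
  x <- make_expr(v, units = "tpm")
  src <- classify_src_effect(x, design)
  rev <- classify_reversal(x, design, src_classes = src)
  expect_true(all(rev$reversed))
  cdh <- classify_cadherin_dependence(x, design, reversed_set = rev,
                                      src_classes = src)
  expect_identical(cdh$cdh_class, c("dependent", "independent",
                                    "independent"))
  expect_equal(cdh$cdh_fc[1], 121 / 51, tolerance = 1e-12)
  expect_identical(cdh$cdh_fc[2], 1)
  expect_identical(cdh$cdh_p[2], 1)

  not_rev <- rev |> dplyr::mutate(reversed = FALSE)
  expect_error(
    classify_cadherin_dependence(x, design, reversed_set = not_rev,
                                 src_classes = src),
    "reversed"
  )
})

test_that("run_cascade assigns each planted toy gene to its layer", {
  specs <- dplyr::bind_rows(
    planted_spec("not_expressed", base_mean = 1e-4, dispersion = 1e-4),
    planted_spec("unaffected", n_genes = 20, dispersion = 1e-4),
    planted_spec("src_up", dispersion = 1e-4),
    planted_spec("reversed_independent_down", dispersion = 1e-4),
    planted_spec("reversed_dependent_up", dispersion = 1e-4)
  )
  sim <- simulate_dataset(specs, library_size = 3e7, seed = 2)
  res <- run_cascade(sim$counts, sim$design)
  got <- tibble::tibble(gene_id = res$genes$gene_id,
                        layer = as.character(res$genes$layer))
  want <- sim$truth |>
    dplyr::mutate(expected = class_to_layer(class_label)) |>
    dplyr::select(gene_id, expected)
  joined <- dplyr::left_join(want, got, by = "gene_id")
  expect_identical(joined$layer, joined$expected)
  expect_onion_invariants(res)
})

test_that("a dataset without planted effects yields only unaffected genes", {
  sim <- simulate_dataset(planted_spec("unaffected", n_genes = 80,
                                       dispersion = 0.02),
                          seed = 9)
  res <- run_cascade(sim$counts, sim$design)
  expect_true(all(res$genes$layer[res$genes$expressed] ==
                    "expressed_unaffected"))
  expect_onion_invariants(res)
})

test_that("config switches change behaviour as documented", {
  expect_error(cascade_config(src_fold = 0.5), "src_fold")
  expect_error(cascade_config(reversal_fraction = 1.2), "reversal_fraction")
  expect_error(apply_config_overrides(cascade_config(),
                                      list(src_foldd = 4)),
               "unknown cascade config key")

  x <- random_dataset(120, seed = 21)
  design <- make_design()
  base <- run_cascade(x, design)
  expect_onion_invariants(base)

  # restoration mode and log-scale testing run and respect nesting
  alt <- run_cascade(x, design,
                     cascade_config(reversal_mode = "restoration",
                                    log_transform = TRUE))
  expect_onion_invariants(alt)

  # BH adjustment can only shrink the Src-affected set (p-values grow)
  bh <- run_cascade(x, design, cascade_config(p_adjust = "BH"))
  affected <- function(r) r$genes$gene_id[r$genes$src_class %in%
                                            c("up", "down")]
  expect_true(all(affected(bh) %in% affected(base)))

  # missing group is rejected
  expect_error(
    run_cascade(x, design[design$group != "T_vs_KO", ]),
    "missing"
  )
})
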