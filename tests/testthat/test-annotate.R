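test_that("location assignment follows biotype override and precedence", {
  ann <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    biotype = c("coding", "noncoding", "coding", "coding"),
    locations = c("plasma_membrane;nucleus", "cytoplasm", "",
                  "nucleus;extracellular")
  )
  got <- assign_location(ann)
  expect_identical(got$category,
                   c("plasma_membrane", "noncoding_rna", "unclassified",
                     "extracellular"))
  expect_error(assign_location(ann |> dplyr::mutate(biotype = "protein")),
               "unknown biotype token: protein")
  expect_error(
    assign_location(ann |> dplyr::mutate(locations = "mitochondrion")),
    "unknown location token: mitochondrion"
  )
})

test_that("location summary conserves layer sizes", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    layer = rep(c("src_only", "cn_cadherin_dependent"), each = 5)
  )
  ann <- tibble::tibble(
    gene_id = genes$gene_id[1:6],
    biotype = "coding",
    locations = rep(c("nucleus", "cytoplasm"), 3)
  )
  s <- location_summary(genes, ann)
  totals <- s |> dplyr::group_by(layer) |> dplyr::summarise(n = sum(n))
  expect_identical(totals$n[totals$layer == "src_only"], 5L)
  expect_identical(totals$n[totals$layer == "cn_cadherin_dependent"], 5L)
  # unannotated genes land in unclassified
  expect_identical(sum(s$n[s$category == "unclassified"]), 4L)

  # every gene unannotated: all unclassified, sums preserved
  s2 <- location_summary(genes, ann[0, ])
  expect_identical(sum(s2$n[s2$category == "unclassified"]), 10L)

  # empty classification gives an empty table
  expect_identical(nrow(location_summary(genes[0, ], ann)), 0L)
})

test_that("neighborhoods respect score thresholds, presets and symmetry", {
  edges <- tibble::tibble(
    gene_a = c("A", "A", "B"),
    gene_b = c("B", "C", "D"),
    score = c(0.5, 0.3, 0.95)
  )
  expect_identical(neighborhood(edges, "A", 0.4), "B")
  expect_identical(neighborhood(edges, "A", "medium"), "B")
  expect_identical(neighborhood(edges, "A", 0.9), character())
  expect_identical(neighborhood(edges, "A", 0.2), c("B", "C"))
  expect_warning(nb <- neighborhood(edges, "ZZZ", 0.4), "absent")
  expect_identical(nb, character())

  # monotone decreasing in min_score
  prev <- neighborhood(edges, "B", 0)
  for (thr in c(0.3, 0.6, 0.96)) {
    cur <- neighborhood(edges, "B", thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }

  # undirected: flipping endpoints changes nothing
  flipped <- edges |>
    dplyr::rename(gene_a = "gene_b", gene_b = "gene_a") |>
    dplyr::relocate("gene_a")
  for (g in c("A", "B", "C", "D")) {
    expect_identical(neighborhood(edges, g, 0.4),
                     neighborhood(flipped, g, 0.4))
  }

  expect_error(neighborhood(edges |> dplyr::mutate(score = 1.5), "A", 0.4),
               "scores")
  expect_error(
    neighborhood(tibble::tibble(gene_a = "A", gene_b = "A", score = 0.5),
                 "A", 0.4),
    "self-edges"
  )
  expect_identical(unname(string_presets()), c(0.400, 0.700, 0.900))
})

test_that("a planted neighborhood partitions by onion layer as planted", {
  # hub with 6 neighbors: 3 src_only, 2 independent, 1 dependent
  layers <- c(rep("src_only", 3), rep("cn_cadherin_independent", 2),
              "cn_cadherin_dependent")
  genes <- tibble::tibble(gene_id = sprintf("n%d", 1:6), layer = layers)
  edges <- tibble::tibble(gene_a = "hub", gene_b = genes$gene_id,
                          score = 0.8)
  nb <- neighborhood(edges, "hub", "high")
  got <- table(genes$layer[genes$gene_id %in% nb])
  expect_identical(unname(got[["src_only"]]), 3L)
  expect_identical(unname(got[["cn_cadherin_independent"]]), 2L)
  expect_identical(unname(got[["cn_cadherin_dependent"]]), 1L)
})
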