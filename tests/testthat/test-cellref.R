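two_type_norm <- function(seed = 61L, cells = 50, genes = 200) {
  cfg <- sim_config(seed = seed, n_genes = genes, cell_types = c("A", "B"),
                    markers_per_type = 10, sc_cells_per_type = cells)
  truth <- simulate_profiles(cfg)
  scd <- simulate_sc_counts(truth, cfg)
  list(cfg = cfg, truth = truth, scd = scd, norm = normalize_cells(scd$counts))
}

test_that("cell normalization equalizes totals at the median", {
  counts <- matrix(c(60L, 40L, 180L, 120L), 2, 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  norm <- normalize_cells(counts)
  # totals 100 and 300; median 200; both cells scaled to 200
  expect_equal(unname(rowSums(norm$linear)), c(200, 200))
  expect_equal(norm$log10, log10(norm$linear + 1))

  single <- normalize_cells(counts[1, , drop = FALSE])
  expect_equal(unname(rowSums(single$linear)), 100)
})

test_that("non-expressed genes and zero-total cells are removed", {
  counts <- matrix(c(5L, 0L, 3L, 7L, 0L, 2L, 0L, 0L, 0L), 3, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), c("g1", "g2", "g3")))
  expect_warning(norm <- normalize_cells(counts), "1 zero-total cell")
  expect_false("g2" %in% colnames(norm$linear))
  expect_false("c3" %in% rownames(norm$linear))
  expect_identical(norm$dropped_cells, "c3")
})

test_that("clustering recovers well-separated planted types exactly", {
  fx <- two_type_norm()
  labels <- cluster_cells(fx$norm, k = 2, seed = 5)
  truth_lab <- fx$scd$labels[match(names(labels), fx$scd$barcodes)]
  expect_equal(mclust::adjustedRandIndex(labels, truth_lab), 1)
  # determinism
  labels2 <- cluster_cells(fx$norm, k = 2, seed = 5)
  expect_identical(labels, labels2)
})

test_that("clustering edge cases behave sensibly", {
  fx <- two_type_norm(cells = 10, genes = 120)
  n <- nrow(fx$norm$log10)
  singletons <- cluster_cells(fx$norm, k = n, seed = 1)
  expect_equal(length(unique(singletons)), n)
  expect_error(cluster_cells(fx$norm, k = n + 1, seed = 1), "exceeds")
  sub <- rownames(fx$norm$log10)[1:12]
  re <- cluster_cells(fx$norm, k = 2, seed = 2, cells = sub)
  expect_identical(names(re), sub)
})

test_that("cluster typing follows markers and relabels symmetrically", {
  fx <- two_type_norm()
  labels <- cluster_cells(fx$norm, k = 2, seed = 5)
  asg <- assign_cell_types(labels, fx$truth$marker_sets, fx$norm)
  truth_lab <- fx$scd$labels[match(names(labels), fx$scd$barcodes)]
  for (i in seq_len(nrow(asg))) {
    expect_equal(asg$type[i], unique(truth_lab[labels == asg$cluster[i]]))
  }
  expect_true(all(asg$flag == "ok"))
  swapped <- assign_cell_types(labels, setNames(fx$truth$marker_sets,
                                                rev(names(fx$truth$marker_sets))),
                               fx$norm)
  expect_identical(swapped$type, setNames(c(B = "A", A = "B")[asg$type], NULL))
})

test_that("clusters without marker expression are flagged unassigned", {
  counts <- matrix(rpois(60, 5) + 1L, 6, 10,
                   dimnames = list(sprintf("c%d", 1:6), sprintf("g%d", 1:10)))
  counts[1:3, c(1, 2)] <- 0L   # cluster 1 expresses no marker gene
  norm <- normalize_cells(counts)
  labels <- setNames(rep(1:2, each = 3), rownames(counts))
  asg <- assign_cell_types(labels, list(T1 = c("g1", "g2")), norm)
  expect_equal(asg$flag[asg$cluster == 1], "unassigned")
  expect_true(is.na(asg$type[asg$cluster == 1]))
})

test_that("marker definition enforces both thresholds", {
  fx <- two_type_norm()
  labels <- cluster_cells(fx$norm, k = 2, seed = 5)
  asg <- assign_cell_types(labels, fx$truth$marker_sets, fx$norm)
  cl_a <- asg$cluster[asg$type == "A"]
  mk <- define_markers(fx$norm, labels, cl_a)
  expect_gt(mean(fx$truth$marker_sets$A %in% mk$gene), 0.9)
  expect_true(all(mk$log2FC >= 2))
  expect_true(all(mk$padj < 0.05))
  expect_error(define_markers(fx$norm, setNames(rep(c(1, 2),
                                                    c(2, nrow(fx$norm$log10) - 2)),
                                                rownames(fx$norm$log10)), 1),
               "fewer than 3")
})

test_that("high fold change with high variance is still rejected", {
  set.seed(71)
  n_cells <- 40
  counts <- matrix(rpois(n_cells * 30, 20), n_cells, 30,
                   dimnames = list(sprintf("c%02d", 1:n_cells),
                                   sprintf("g%02d", 1:30)))
  # gene g01: enormous spread inside the target cluster, mean ratio > 8
  counts[1:20, 1] <- as.integer(rep(c(0, 700), 10))
  counts[21:40, 1] <- 30L
  norm <- normalize_cells(counts)
  labels <- setNames(rep(1:2, each = 20), rownames(counts))
  mk <- define_markers(norm, labels, 1)
  lfc_g1 <- log2((mean(norm$linear[1:20, "g01"]) + 1) /
                   (mean(norm$linear[21:40, "g01"]) + 1))
  expect_gt(lfc_g1, 2)
  expect_false("g01" %in% mk$gene)
})

test_that("signature building validates inputs and reproduces profiles", {
  fx <- two_type_norm()
  types <- setNames(fx$scd$labels, fx$scd$barcodes)
  markers <- fx$truth$marker_sets
  sig <- build_signature(fx$norm, types, markers)
  expect_equal(dim(sig), c(20, 2))
  expect_identical(colnames(sig), c("A", "B"))
  # single type: signature equals that type's mean profile over its markers
  a_cells <- names(types)[types == "A"]
  solo <- build_signature(fx$norm, types[a_cells], markers["A"])
  expect_equal(unname(solo[, "A"]),
               unname(colMeans(fx$norm$linear[a_cells, markers$A])))
  expect_error(build_signature(fx$norm, types,
                               list(A = c("gene_00001", "gene_00001"))),
               "duplicate")
  expect_error(build_signature(fx$norm, types, list(A = "not_a_gene")),
               "not_a_gene")
})

test_that("the default signature is well conditioned", {
  run <- default_run()
  expect_lt(kappa(unclass(run$cellref$signature), exact = TRUE), 50)
})

test_that("the full reference pipeline recovers planted markers and types", {
  run <- default_run()
  asg <- run$cellref$assignment
  expect_true(all(asg$flag == "ok"))
  expect_setequal(asg$type, run$sim$config$cell_types)   # no false types
  truth_lab <- run$sim$sc_labels[match(names(run$cellref$labels),
                                       rownames(run$sim$sc_counts))]
  expect_equal(mclust::adjustedRandIndex(run$cellref$labels, truth_lab), 1)
  for (ty in names(run$sim$truth$marker_sets)) {
    recovered <- mean(run$sim$truth$marker_sets[[ty]] %in%
                        run$cellref$markers[[ty]])
    expect_gte(recovered, 0.9)
  }
})
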