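toy_sheet <- function(n_levels, reps) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_levels * reps)),
    condition = rep(sprintf("c%d", seq_len(n_levels)), each = reps))
}

test_that("gene filtering applies both rules with a strict boundary", {
  sheet <- toy_sheet(8, 2)
  m <- matrix(0, 4, 16,
              dimnames = list(paste0("g", 1:4), sheet$sample_id))
  m[1, ] <- 50                       # constant: IQR 0, excluded
  m[2, 1:10] <- 1000                 # high in 5 of 8 conditions, bimodal
  m[3, 1:6] <- 1000                  # bimodal but high in exactly 3 conditions
  m[4, ] <- 2                        # low everywhere
  kept <- filter_genes(m, sheet)
  expect_identical(kept, "g2")
  # g3 clears the IQR rule yet "> 3 conditions" is strict, so exactly 3 fails
  lg3 <- log2(m[3, ] + 1)
  expect_gt(diff(quantile(lg3, c(0.25, 0.75), names = FALSE)), 1.5)
  expect_false("g3" %in% kept)
  expect_error(filter_genes(m[1, , drop = FALSE], sheet[0, ][rep(1, 0), ]),
               "aligned")
  expect_error(filter_genes(m[4, , drop = FALSE], sheet), "relax")
})

test_that("PCA matches a brute-force correlation eigendecomposition", {
  set.seed(101)
  for (i in 1:20) {
    m <- matrix(rlnorm(20 * 10, 3, 1), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
    p <- run_pca(m, log2_transform = TRUE)
    x <- log2(m + 1)
    ev <- eigen(cor(t(x)), symmetric = TRUE)$values
    frac_ref <- ev / sum(ev)
    k <- length(p$variance_fraction)
    expect_lt(max(abs(p$variance_fraction[seq_len(min(k, 9))] -
                        frac_ref[seq_len(min(k, 9))])), 1e-10)
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
    expect_true(all(abs(colSums(p$contribution) - 100) < 1e-6))
  }
})

test_that("variance fractions are invariant to sample duplication", {
  set.seed(102)
  m <- matrix(rlnorm(30 * 8, 3, 1), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  dup <- cbind(m, m, m)
  colnames(dup) <- sprintf("s%d", 1:24)
  f1 <- run_pca(m)$variance_fraction
  f2 <- run_pca(dup)$variance_fraction
  # the data span at most 7 directions (8 samples, centered); beyond that
  # the eigenvalues vanish and the components are arbitrary
  expect_equal(unname(f1[1:7]), unname(f2[1:7]), tolerance = 1e-10)
  expect_lt(sum(f2[-(1:7)]), 1e-10)
})

test_that("perfectly correlated genes give a rank-one decomposition", {
  m <- matrix(c(1, 2, 2, 4, 3, 6), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  p <- run_pca(m, log2_transform = FALSE)
  expect_equal(unname(p$variance_fraction[1]), 1, tolerance = 1e-12)
})

test_that("PCA is invariant to gene and sample order", {
  set.seed(103)
  m <- matrix(rlnorm(25 * 10, 3, 1), 25, 10,
              dimnames = list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:10)))
  p1 <- run_pca(m)
  p2 <- run_pca(m[sample(25), sample(10)])
  expect_equal(p1$variance_fraction, p2$variance_fraction, tolerance = 1e-12)
  # compare the well-defined components (rank 9 with 10 centered samples)
  keep <- paste0("PC", 1:9)
  expect_equal(p1$loadings[, keep], p2$loadings[, keep], tolerance = 1e-9)
  s1 <- dplyr::arrange(p1$scores, sample_id)
  s2 <- dplyr::arrange(p2$scores, sample_id)
  expect_equal(as.data.frame(s1[c("sample_id", keep)]),
               as.data.frame(s2[c("sample_id", keep)]), tolerance = 1e-9)
})

test_that("zero-variance genes are dropped with a warning", {
  m <- matrix(rlnorm(40, 3, 1), 4, 10,
              dimnames = list(paste0("g", 1:4), sprintf("s%02d", 1:10)))
  m[2, ] <- 7
  expect_warning(p <- run_pca(m, log2_transform = FALSE), "zero-variance")
  expect_equal(nrow(p$loadings), 3)
})

test_that("PC-factor association finds planted structure and stays calibrated", {
  run <- default_run()
  p_st <- pc_factor_association(run$pca, run$sim$samples, "PC1", "sample_type")
  expect_lt(p_st, 1e-6)

  # permuted labels: p should be uniform
  set.seed(104)
  sheet <- run$sim$samples
  pvals <- replicate(200, {
    sheet$sample_type <- sample(sheet$sample_type)
    pc_factor_association(run$pca, sheet, "PC1", "sample_type")
  })
  expect_gt(median(pvals), 0.3)
  expect_lt(median(pvals), 0.7)
})

test_that("degenerate association inputs behave as specified", {
  scores <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                           PC1 = rep(c(1, 2, 3, 4), 2))
  sheet <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                          grp = rep(c("a", "b"), each = 4))
  expect_equal(pc_factor_association(scores, sheet, "PC1", "grp"), 1)
  sheet$grp <- c("a", rep("b", 7))
  expect_error(pc_factor_association(scores, sheet, "PC1", "grp"), "< 2")
})

test_that("three-level factors use a one-way ANOVA", {
  run <- default_run()
  p_comp <- pc_factor_association(run$pca, run$sim$samples, "PC2",
                                  "compartment")
  expect_lt(p_comp, 1e-6)
})

test_that("contributing-gene selection follows the log2 cutoff closed form", {
  make_uniform_pca <- function(G) {
    load <- matrix(1 / sqrt(G), G, 1,
                   dimnames = list(sprintf("g%04d", seq_len(G)), "PC1"))
    structure(list(loadings = load,
                   contribution = 100 * load^2 / sum(load^2),
                   variance_fraction = c(PC1 = 1)),
              class = "orgretain_pca")
  }
  # 500 uniform genes: contribution 0.2%, log2 = -2.32 >= -3.32, all kept
  expect_equal(nrow(contributing_genes(make_uniform_pca(500), "PC1")), 500)
  # 2000 uniform genes: contribution 0.05%, log2 ~ -4.32, none kept
  expect_equal(nrow(contributing_genes(make_uniform_pca(2000), "PC1")), 0)
  # single dominant gene
  solo <- make_uniform_pca(2)
  solo$contribution[, 1] <- c(100, 0)
  got <- contributing_genes(solo, "PC1")
  expect_equal(got$gene, "g0001")
  expect_equal(got$contribution, 100)
})

test_that("tidy and glance return well-formed PCA summaries", {
  run <- default_run()
  td <- tidy(run$pca)
  expect_tibble(td)
  expect_true(all(c("gene", "component", "contribution") %in% colnames(td)))
  gl <- glance(run$pca)
  expect_equal(sum(gl$variance_fraction), 1, tolerance = 1e-9)
})
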