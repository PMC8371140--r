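fake_deg <- function(genes, lfc, p) {
  tibble::tibble(gene = genes, baseMean = 100, log2FC = lfc,
                 lfcSE = 0.1, stat = lfc / 0.1, pvalue = p,
                 padj = bh_adjust(p), tested = TRUE)
}

test_that("the DEG matrix zero-fills non-significant entries", {
  genes <- sprintf("g%d", 1:5)
  a <- fake_deg(genes, lfc = c(2, 0.1, 0.2, 1, 0.3),
                p = c(1e-6, 0.9, 0.8, 1e-4, 0.7))
  b <- fake_deg(genes, lfc = c(0.5, 3, 0.1, 0.2, 0.4),
                p = c(0.6, 1e-8, 0.9, 0.8, 0.5))
  dm <- build_deg_matrix(list(A = a, B = b))
  expect_setequal(dm$gene, c("g1", "g2", "g4"))
  expect_equal(dm$A[dm$gene == "g1"], 2)
  expect_equal(dm$B[dm$gene == "g1"], 0)   # significant only in A
  expect_equal(dm$A[dm$gene == "g2"], 0)
  expect_equal(dm$B[dm$gene == "g2"], 3)
})

test_that("an all-null DEG matrix is flagged empty", {
  genes <- sprintf("g%d", 1:4)
  a <- fake_deg(genes, lfc = rep(0.1, 4), p = rep(0.9, 4))
  dm <- build_deg_matrix(list(A = a))
  expect_true(attr(dm, "empty"))
  expect_equal(nrow(dm), 0)
})

test_that("relaxing from adjusted to raw p never shrinks the gene set", {
  run <- default_run()
  tabs <- run$deg[c("vivo_compartment", "vivo_gender", "vivo_aging")]
  names(tabs) <- c("compartment", "gender", "aging")
  strict <- build_deg_matrix(tabs, rule = "padj")
  loose <- build_deg_matrix(tabs, rule = "pvalue")
  expect_true(all(strict$gene %in% loose$gene))
})

test_that("duplicate gene rows within one contrast are rejected", {
  genes <- c("g1", "g1", "g2")
  a <- fake_deg(genes, lfc = c(2, 2, 1), p = c(1e-6, 1e-6, 1e-4))
  expect_error(build_deg_matrix(list(A = a)), "duplicate.*g1")
})

test_that("adjusted R-squared matches its closed form exactly", {
  set.seed(108)
  df <- tibble::tibble(y = rnorm(200), x1 = rnorm(200), x2 = rnorm(200))
  df$y <- 0.6 * df$x1 + rnorm(200)
  es <- effect_size(df, "y", c("x1", "x2"))
  fit <- lm(y ~ x1 + x2, data = df)
  r2 <- summary(fit)$r.squared
  n <- nrow(df); k <- 2
  expect_equal(es$adj_r2, 1 - (1 - r2) * (n - 1) / (n - k - 1),
               tolerance = 1e-12)
  expect_equal(es$adj_r2, summary(fit)$adj.r.squared, tolerance = 1e-12)
})

test_that("identity, independence, and noise-mixtures give textbook R2", {
  set.seed(109)
  df <- tibble::tibble(x = rnorm(1000))
  df$same <- df$x
  es_id <- suppressWarnings(effect_size(df, "same", "x"))
  expect_equal(es_id$adj_r2, 1, tolerance = 1e-9)
  expect_lt(es_id$p_value, 1e-100)

  df$indep <- rnorm(1000)
  expect_lt(abs(effect_size(df, "indep", "x")$adj_r2), 0.01)

  # outcome = predictor + equal-variance noise: R2 ~ 0.5
  r2s <- vapply(1:10, function(s) {
    set.seed(200 + s)
    d <- tibble::tibble(x = rnorm(2000))
    d$y <- d$x + rnorm(2000)
    effect_size(d, "y", "x")$adj_r2
  }, numeric(1))
  expect_true(all(r2s > 0.45 & r2s < 0.55))
})

test_that("degenerate model inputs are rejected with names", {
  df <- tibble::tibble(y = rnorm(50), a = rnorm(50))
  df$b <- 2 * df$a
  expect_error(effect_size(df, "y", c("a", "b")), "collinear.*a.*b")
  df$const <- 1
  expect_error(effect_size(df, "const", "a"), "constant")
})

test_that("identical in vivo and in vitro matrices give full retention", {
  run <- default_run()
  tabs <- run$deg[c("vivo_compartment", "vivo_gender", "vivo_aging")]
  names(tabs) <- c("compartment", "gender", "aging")
  dm <- build_deg_matrix(tabs)
  ret <- suppressWarnings(feature_retention(dm, dm))
  expect_true(all(abs(ret$adj_r2 - 1) < 1e-9))
})

test_that("shared compartment and independent gender effects separate", {
  cfg <- sim_config(seed = 23L, effect_spec = list(
    sample_type = list(frac = 0.3, lfc_mean = 2.5, lfc_sd = 0.5),
    compartment = list(frac = 0.15, lfc_mean = 1.5, lfc_sd = 0.4,
                       share_in_vitro = 1),
    gender = list(frac = 0.10, lfc_mean = 1.2, lfc_sd = 0.4,
                  share_in_vitro = 0),
    age = list(frac = 0.08, lfc_mean = 1.0, lfc_sd = 0.3,
               share_in_vitro = 1)))
  run <- run_study(cfg)
  ret <- dplyr::filter(run$effects$retention, model == "simple")
  expect_gt(ret$adj_r2[ret$feature == "compartment"], 0.9)
  expect_lt(ret$adj_r2[ret$feature == "gender"], 0.1)
})

test_that("retention rises monotonically with the planted shared fraction", {
  r2_at <- function(s) {
    cfg <- sim_config(seed = 29L, effect_spec = list(
      sample_type = list(frac = 0.3, lfc_mean = 2.5, lfc_sd = 0.5),
      compartment = list(frac = 0.15, lfc_mean = 1.5, lfc_sd = 0.4,
                         share_in_vitro = s),
      gender = list(frac = 0.10, lfc_mean = 1.2, lfc_sd = 0.4,
                    share_in_vitro = 1),
      age = list(frac = 0.08, lfc_mean = 1.0, lfc_sd = 0.3,
                 share_in_vitro = 1)))
    sim <- simulate_study(cfg, sc = FALSE)
    tabs <- function(st) {
      t <- nb_wald_test(sim$counts, sim$samples,
                        c("compartment", "aboral", "oral"),
                        stratum = list(sample_type = st))
      list(compartment = t)
    }
    dm_vivo <- build_deg_matrix(tabs("crypt"))
    dm_vitro <- build_deg_matrix(tabs("organoid"))
    feature_retention(dm_vivo, dm_vitro, "compartment")$adj_r2[1]
  }
  grid <- vapply(c(0, 0.25, 0.5, 0.75, 1), r2_at, numeric(1))
  expect_true(all(diff(grid) > 0))
  expect_lt(grid[1], 0.1)
  expect_gt(grid[5], 0.9)
})

test_that("strata with identical aging responses yield near-zero modifiers", {
  set.seed(110)
  genes <- sprintf("g%03d", 1:200)
  lfc <- rnorm(200)
  strata <- tidyr::expand_grid(compartment = c("oral", "intermediate",
                                               "aboral"),
                               gender = c("male", "female"))
  strata$contrast <- paste("aging", strata$compartment, strata$gender,
                           sep = "_")
  tabs <- setNames(lapply(strata$contrast, function(x)
    fake_deg(genes, lfc, p = rep(1e-6, 200))), strata$contrast)
  dm <- build_deg_matrix(tabs, rule = "pvalue")
  mods <- aging_modifiers(dm, strata)
  expect_true(all(abs(mods$adj_r2) < 0.01))
  expect_error(aging_modifiers(dm[-2], strata), "missing stratum")
})

test_that("an in-vivo-only gender-aging interaction shows up in vivo only", {
  cfg <- sim_config(seed = 11L, aging_by_gender = list(frac = 1, lfc = 6))
  run <- run_study(cfg)
  mods <- run$effects$modifiers
  gv <- mods$adj_r2[mods$model == "gender" & mods$side == "vivo"]
  gt <- mods$adj_r2[mods$model == "gender" & mods$side == "vitro"]
  expect_gt(gv, gt + 0.05)
  expect_lt(abs(gt), 0.01)
})

test_that("overlap counts match hand-enumerated cases", {
  dj <- deg_overlap(list(A = c("g1", "g2"), B = c("g3", "g4")))
  expect_equal(dj$pairwise$intersection, 0)
  idn <- deg_overlap(list(A = c("g1", "g2"), B = c("g2", "g1")))
  expect_equal(idn$pairwise$jaccard, 1)
  three <- deg_overlap(list(A = c("g1", "g2", "g3"),
                            B = c("g2", "g3", "g4"),
                            C = c("g3", "g4", "g5")))
  pw <- three$pairwise
  expect_equal(pw$intersection[pw$set_a == "A" & pw$set_b == "B"], 2)
  expect_equal(pw$intersection[pw$set_a == "A" & pw$set_b == "C"], 1)
  expect_equal(pw$intersection[pw$set_a == "B" & pw$set_b == "C"], 2)
  expect_equal(pw$only_a[pw$set_a == "A" & pw$set_b == "B"], 1)
  expect_equal(three$full_intersection, 1)
})

test_that("tidy and glance expose the underlying linear model", {
  set.seed(111)
  df <- tibble::tibble(x = rnorm(100))
  df$y <- 2 * df$x + rnorm(100)
  es <- effect_size(df, "y", "x")
  td <- tidy(es)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], 2, tolerance = 0.3)
  expect_equal(glance(es)$adj_r2, es$adj_r2)
})
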