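# Shared fixtures, memoized so expensive simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Effect specification with every factor switched off.
zero_effects <- function() {
  list(sample_type = list(frac = 0, lfc_mean = 0, lfc_sd = 0),
       compartment = list(frac = 0, lfc_mean = 0, lfc_sd = 0),
       gender      = list(frac = 0, lfc_mean = 0, lfc_sd = 0),
       age         = list(frac = 0, lfc_mean = 0, lfc_sd = 0))
}

# Fully null study: no planted effects, one pooled composition.
null_config <- function(seed = 7L, n_genes = 2000) {
  sim_config(seed = seed, n_genes = n_genes, effect_spec = zero_effects(),
             variance_targets = NULL, composition_by_sample_type = FALSE)
}

# Exact planted sample_type log2FC (no variance-target rescaling, pooled
# compositions) so group-mean ratios recover the planted value directly.
planted_lfc_config <- function(lfc, seed = 13L, frac = 0.2, n_genes = 2000) {
  sim_config(seed = seed, n_genes = n_genes,
             effect_spec = list(
               sample_type = list(frac = frac, lfc_mean = lfc, lfc_sd = 0),
               compartment = list(frac = 0, lfc_mean = 0, lfc_sd = 0),
               gender      = list(frac = 0, lfc_mean = 0, lfc_sd = 0),
               age         = list(frac = 0, lfc_mean = 0, lfc_sd = 0)),
             variance_targets = NULL, composition_by_sample_type = FALSE)
}

default_sim <- function() memo("default_sim", simulate_study(sim_config(seed = 1L)))
default_run <- function() memo("default_run", run_study(sim_config(seed = 1L)))
null_sim <- function() memo("null_sim", simulate_study(null_config(), sc = FALSE))

# Vectorized per-gene Welch t-test between two sample groups (independent
# check used against the simulator, not the package's DE engine).
welch_per_gene <- function(mat, in_a) {
  a <- mat[, in_a, drop = FALSE]
  b <- mat[, !in_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA
  p
}

# Brute-force running-sum recomputation over all prefixes (oracle for the
# streaming enrichment score).
brute_force_es <- function(stats, hit, weight_exponent = 1) {
  n <- length(stats)
  w <- abs(stats)^weight_exponent
  step <- ifelse(hit, w / sum(w[hit]), -1 / (n - sum(hit)))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# Ranked-list constructor for enrichment tests.
make_ranked <- function(stats, genes = sprintf("g%04d", seq_along(stats))) {
  rank_genes(tibble::tibble(gene = genes, stat = stats))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# Simplex draws for deconvolution tests.
rdirichlet_test <- function(k, conc = 2) {
  g <- rgamma(k, conc)
  g / sum(g)
}

rdirichlet_rows <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}
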