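#' Rank genes for enrichment analysis
#'
#' Orders genes by a per-gene statistic (default: the Wald statistic of a
#' DEG table), descending, with ties broken lexicographically by gene ID so
#' the ordering is strict and deterministic.
#'
#' @param deg DEG tibble with `gene` and a statistic column.
#' @param stat Column used for ranking (default `"stat"`).
#' @return Tibble `gene`, `stat`, ordered; class `orgretain_ranked`.
#' @export
rank_genes <- function(deg, stat = "stat") {
  assert_that(nrow(deg) > 0, "empty DEG table")
  df <- tibble(gene = deg$gene, stat = deg[[stat]]) |>
    filter(is.finite(.data$stat))
  assert_that(nrow(df) > 0, "no finite ranking statistics")
  assert_that(!anyDuplicated(df$gene), "duplicate gene IDs in ranked list")
  df <- arrange(df, desc(.data$stat), .data$gene)
  structure(df, class = c("orgretain_ranked", class(df)))
}

# Enrichment score from hit positions only: the running sum is piecewise
# linear between hits, so its extrema occur immediately after a hit (local
# max candidates) or immediately before one (local min candidates).
es_from_hits <- function(stats, hit_idx, weight_exponent = 1) {
  n <- length(stats)
  m <- length(hit_idx)
  pos <- sort(hit_idx)
  w <- abs(stats[pos])^weight_exponent
  wsum <- sum(w)
  assert_that(wsum > 0, "all hit weights are zero; cannot normalize")
  miss_step <- 1 / (n - m)
  cum_w <- cumsum(w) / wsum
  miss_before <- (pos - seq_len(m)) * miss_step
  after_hit <- cum_w - miss_before
  before_hit <- c(0, cum_w[-m]) - miss_before
  cand <- c(after_hit, before_hit)
  i <- which.max(abs(cand))
  cand[i]
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list; hitting a set member increments the running
#' sum by that gene's weight `|r|^weight_exponent` (normalized by the total
#' hit weight), a miss decrements by `1/(N - |S|)`. The enrichment score is
#' the deviation of maximum absolute value, signed; with
#' `weight_exponent = 0` and a tie-free list it reduces to the classic
#' Kolmogorov-Smirnov statistic.
#'
#' @param ranked `orgretain_ranked` tibble from [rank_genes()].
#' @param set Character vector of member gene IDs.
#' @param weight_exponent Weighting exponent on `|r|` (default 1).
#' @param return_running Also return the full running-sum curve.
#' @return List: `es`, `hit_index`, and (optionally) `running` tibble.
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1,
                             return_running = FALSE) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% set
  m <- sum(hit)
  assert_that(m > 0 && m < n,
              "gene set must hit some but not all of the ranked list")
  es <- es_from_hits(ranked$stat, which(hit), weight_exponent)
  out <- list(es = es, hit_index = which(hit))
  if (return_running) {
    w <- abs(ranked$stat)^weight_exponent
    step <- ifelse(hit, w / sum(w[hit]), -1 / (n - m))
    out$running <- tibble(position = seq_len(n), gene = ranked$gene,
                          hit = hit, running_sum = cumsum(step))
  }
  out
}

#' Gene-set enrichment with permutation p-values
#'
#' For each set, the observed enrichment score is compared with a null
#' built by redrawing `|S|` random gene labels from the ranked universe
#' `n_permutations` times; `p = (1 + #{|ES_null| >= |ES_obs|}) / (n + 1)`
#' (never zero), BH-adjusted across sets. The leading edge collects the set
#' members at or before (after, for negative scores) the extremum.
#'
#' @param ranked `orgretain_ranked` tibble.
#' @param sets Named list of gene-ID vectors.
#' @param n_permutations Number of label permutations (default 1000; a
#'   warning is issued below 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Tibble `set`, `size`, `es`, `pvalue`, `padj`, `leading_edge`
#'   (list column).
#' @export
gsea <- function(ranked, sets, n_permutations = 1000, seed = 1,
                 weight_exponent = 1) {
  if (n_permutations < 100) {
    warn("fewer than 100 permutations gives a coarse p-value grid")
  }
  n <- nrow(ranked)
  stats_vec <- ranked$stat
  set.seed(seed)
  res <- map_dfr(names(sets), function(nm) {
    members <- intersect(sets[[nm]], ranked$gene)
    m <- length(members)
    assert_that(m > 0 && m < n,
                paste0("set '", nm, "' covers none or all of the universe"))
    obs <- enrichment_score(ranked, members, weight_exponent)
    null_abs <- vapply(seq_len(n_permutations), function(i) {
      abs(es_from_hits(stats_vec, sample.int(n, m), weight_exponent))
    }, numeric(1))
    p <- (1 + sum(null_abs >= abs(obs$es))) / (n_permutations + 1)
    le <- leading_edge(ranked, members, obs$es, weight_exponent)
    tibble(set = nm, size = m, es = obs$es, pvalue = p,
           leading_edge = list(le))
  })
  res$padj <- bh_adjust(res$pvalue)
  res[, c("set", "size", "es", "pvalue", "padj", "leading_edge")]
}

leading_edge <- function(ranked, members, es, weight_exponent) {
  run <- enrichment_score(ranked, members, weight_exponent,
                          return_running = TRUE)$running
  if (es >= 0) {
    peak <- which.max(run$running_sum)
    run$gene[run$hit & run$position <= peak]
  } else {
    trough <- which.min(run$running_sum)
    run$gene[run$hit & run$position >= trough]
  }
}

#' Directional Z-score summary of a gene set
#'
#' Scales each set gene's normalized expression across samples (zero mean,
#' unit variance), multiplies by the gene's direction (+1 up-regulated,
#' -1 down-regulated), averages over the set per sample, and reports the
#' group means. Zero-variance genes are excluded with a warning.
#'
#' @param normalized Genes x samples matrix of normalized counts.
#' @param genes Character vector of set genes.
#' @param directions Numeric +1/-1 per set gene.
#' @param samples Sample sheet tibble.
#' @param group Factor column defining the groups.
#' @return Tibble `group`, `mean_z`, `n`.
#' @export
zscore_signature <- function(normalized, genes, directions, samples,
                             group = "sample_type") {
  assert_that(length(genes) == length(directions),
              "directions must cover all set members")
  assert_that(all(directions %in% c(-1, 1)), "directions must be +1 or -1")
  present <- genes %in% rownames(normalized)
  assert_that(all(present),
              paste0("set gene(s) absent: ",
                     paste(genes[!present], collapse = ", ")))
  x <- normalized[genes, , drop = FALSE]
  v <- row_vars(x)
  if (any(v == 0)) {
    warn(paste0("excluding ", sum(v == 0), " zero-variance gene(s)"))
    directions <- directions[v > 0]
    x <- x[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  z <- (x - rowMeans(x)) / sqrt(v)
  per_sample <- colMeans(z * directions)
  df <- tibble(sample_id = colnames(normalized), z = per_sample) |>
    left_join(samples, by = "sample_id")
  df |>
    group_by(group = .data[[group]]) |>
    summarise(mean_z = mean(.data$z), n = dplyr::n(), .groups = "drop")
}

#' Running-sum plot for one gene set
#'
#' @param ranked `orgretain_ranked` tibble.
#' @param set Character vector of member genes.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A ggplot object showing the running sum and hit positions.
#' @export
plot_running_sum <- function(ranked, set, weight_exponent = 1) {
  es <- enrichment_score(ranked, intersect(set, ranked$gene),
                         weight_exponent, return_running = TRUE)
  ggplot(es$running, aes(x = .data$position, y = .data$running_sum)) +
    geom_line(color = "#2c7fb8") +
    geom_rug(data = filter(es$running, .data$hit), sides = "b") +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    labs(x = "rank in list", y = "running enrichment score",
         subtitle = sprintf("ES = %.3f", es$es)) +
    theme_minimal()
}
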