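#' Deconvolve a bulk sample into cell-type proportions
#'
#' Non-negative least squares on the linear normalized scale: solves
#' `signature %*% p ~ bulk` with `p >= 0`, then renormalizes `p` to sum to
#' one. The residual norm of the (pre-renormalization) fit is reported.
#' Proportion estimates are invariant to the overall scale of the bulk
#' vector.
#'
#' @param bulk Named numeric vector of normalized bulk expression (or a
#'   genes x samples matrix; see [deconvolve_samples()]).
#' @param signature Markers x types signature matrix.
#' @return Tibble with one column per cell type plus `residual`.
#' @export
deconvolve <- function(bulk, signature) {
  genes <- rownames(signature)
  present <- genes %in% names(bulk)
  assert_that(mean(present) >= 0.5,
              paste0("bulk vector is missing ", sum(!present), " of ",
                     length(genes), " signature genes (> 50%)"))
  sig <- signature[present, , drop = FALSE]
  b <- bulk[rownames(sig)]
  assert_that(any(b > 0), "bulk vector has no nonzero signature gene")
  fit <- pracma::lsqnonneg(unclass(sig), as.numeric(b))
  p <- fit$x
  total <- sum(p)
  assert_that(total > 0, "degenerate fit: all proportions zero")
  p <- p / total
  out <- as_tibble(as.list(setNames(p, colnames(signature))))
  out$residual <- sqrt(fit$resid.norm)
  out
}

#' @rdname deconvolve
#' @param counts Genes x samples bulk count matrix (raw counts; size-factor
#'   normalized internally before restriction to signature genes).
#' @export
deconvolve_samples <- function(counts, signature) {
  norm <- normalize_counts(counts)
  res <- map_dfr(colnames(norm), function(s) {
    est <- deconvolve(norm[, s], signature)
    dplyr::bind_cols(tibble(sample_id = s), est)
  })
  res
}

#' Validate deconvolution on simulated mixtures
#'
#' Draws Dirichlet compositions, forms noiseless mixtures of the signature
#' columns, perturbs them with multiplicative log-normal noise of the given
#' coefficient of variation, deconvolves, and reports the squared Pearson
#' correlation between estimated and true proportions pooled over all
#' (mixture, type) pairs, with per-type correlations alongside.
#'
#' @param signature Markers x types signature matrix.
#' @param n_mixtures Number of simulated mixtures (>= 10).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (scalar or per-type vector).
#' @return List: `r2` (pooled), `r2_per_type`, `scatter` tibble
#'   (`mixture`, `type`, `truth`, `estimate`).
#' @export
validate_simulated <- function(signature, n_mixtures = 50, noise_cv = 0.05,
                               seed = 1, concentration = 1) {
  assert_that(n_mixtures >= 10, "n_mixtures must be >= 10")
  k <- ncol(signature)
  alpha <- rep(concentration, length.out = k)
  set.seed(seed)
  truth <- rdirichlet(n_mixtures, alpha)
  sdlog <- sqrt(log(1 + noise_cv^2))
  est <- matrix(NA_real_, n_mixtures, k)
  for (i in seq_len(n_mixtures)) {
    mix <- as.numeric(signature %*% truth[i, ])
    if (noise_cv > 0) {
      mix <- mix * rlnorm(length(mix), -sdlog^2 / 2, sdlog)
    }
    names(mix) <- rownames(signature)
    est[i, ] <- as.numeric(deconvolve(mix, signature)[, colnames(signature)])
  }
  r2 <- stats::cor(as.vector(truth), as.vector(est))^2
  r2_type <- vapply(seq_len(k), function(j) {
    if (sd(truth[, j]) == 0 || sd(est[, j]) == 0) return(NA_real_)
    stats::cor(truth[, j], est[, j])^2
  }, numeric(1))
  scatter <- tibble(
    mixture = rep(seq_len(n_mixtures), k),
    type = rep(colnames(signature), each = n_mixtures),
    truth = as.vector(truth), estimate = as.vector(est))
  list(r2 = r2, r2_per_type = setNames(r2_type, colnames(signature)),
       scatter = scatter)
}

#' Compare estimated compositions across sample groups
#'
#' Per cell type: Welch's two-tailed t-test of crypt vs organoid
#' proportions, and a one-way ANOVA across compartments within each sample
#' type; BH adjustment across cell types within each test family.
#'
#' @param estimates Tibble from [deconvolve_samples()].
#' @param samples Sample sheet tibble.
#' @return Tibble `test`, `sample_type`, `cell_type`, `statistic`, `pvalue`,
#'   `padj`.
#' @export
compare_compositions <- function(estimates, samples) {
  df <- left_join(estimates, samples, by = "sample_id")
  types <- setdiff(colnames(estimates), c("sample_id", "residual"))
  st_levels <- unique(df$sample_type)
  assert_that(length(st_levels) == 2,
              "need both crypt and organoid samples for the Welch test")
  welch <- map_dfr(types, function(ty) {
    a <- df[[ty]][df$sample_type == st_levels[1]]
    b <- df[[ty]][df$sample_type == st_levels[2]]
    assert_that(length(a) >= 2 && length(b) >= 2,
                "each sample-type group needs >= 2 samples")
    tt <- t.test(a, b, var.equal = FALSE)
    tibble(test = "welch_sample_type", sample_type = NA_character_,
           cell_type = ty, statistic = unname(tt$statistic),
           pvalue = tt$p.value)
  }) |> mutate(padj = bh_adjust(.data$pvalue))
  anova_res <- map_dfr(st_levels, function(st) {
    sub <- df[df$sample_type == st, , drop = FALSE]
    n_comp <- length(unique(sub$compartment))
    assert_that(n_comp >= 2,
                paste0("ANOVA across compartments needs >= 2 compartments in '",
                       st, "' (found ", n_comp, ")"))
    map_dfr(types, function(ty) {
      fit <- aov(y ~ g, data = data.frame(y = sub[[ty]],
                                          g = base::factor(sub$compartment)))
      sm <- summary(fit)[[1]]
      tibble(test = "anova_compartment", sample_type = st, cell_type = ty,
             statistic = sm[["F value"]][1], pvalue = sm[["Pr(>F)"]][1])
    }) |> mutate(padj = bh_adjust(.data$pvalue))
  })
  bind_rows(welch, anova_res)
}

#' Composition box plot by group
#'
#' @param estimates Tibble from [deconvolve_samples()].
#' @param samples Sample sheet tibble.
#' @param group Factor column to group by (default `sample_type`).
#' @return A ggplot object.
#' @export
plot_composition <- function(estimates, samples, group = "sample_type") {
  df <- left_join(estimates, samples, by = "sample_id") |>
    pivot_longer(dplyr::all_of(setdiff(colnames(estimates),
                                       c("sample_id", "residual"))),
                 names_to = "cell_type", values_to = "proportion")
  ggplot(df, aes(x = .data$cell_type, y = .data$proportion,
                 fill = .data[[group]])) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "estimated proportion", fill = group) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
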