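#' Filter genes for variance decomposition
#'
#' Keeps highly-variable, robustly expressed genes: (a) the interquartile
#' range of `log2(normalized + 1)` across samples must exceed `iqr_min`,
#' and (b) the mean normalized count must exceed `min_count` in strictly
#' more than `min_conditions` condition groups, a condition being one
#' unique combination of all declared factors (24 groups in the default
#' design).
#'
#' @param normalized Genes x samples matrix of normalized counts.
#' @param samples Sample sheet tibble; every column other than `sample_id`
#'   and `replicate` is treated as a design factor.
#' @param iqr_min IQR threshold on the log2 scale (default 1.5).
#' @param min_count Normalized-count threshold (default 10).
#' @param min_conditions Strict lower bound on the number of qualifying
#'   condition groups (default 3, i.e. > 3 groups required).
#' @return Character vector of retained gene IDs.
#' @export
filter_genes <- function(normalized, samples, iqr_min = 1.5, min_count = 10,
                         min_conditions = 3) {
  assert_that(ncol(normalized) == nrow(samples) &&
                all(colnames(normalized) == samples$sample_id),
              "normalized matrix and sample sheet are not aligned")
  lg <- log2(normalized + 1)
  iqr <- apply(lg, 1, function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE)))
  fac_cols <- setdiff(colnames(samples), c("sample_id", "replicate"))
  cond <- interaction(samples[fac_cols], drop = TRUE)
  cond_means <- vapply(levels(cond), function(lv)
    rowMeans(normalized[, cond == lv, drop = FALSE]), numeric(nrow(normalized)))
  cond_means <- matrix(cond_means, nrow = nrow(normalized))
  n_expressed <- rowSums(cond_means > min_count)
  keep <- iqr > iqr_min & n_expressed > min_conditions
  out <- rownames(normalized)[keep]
  if (length(out) == 0) {
    abort("no gene passes the filters; relax iqr_min or min_count")
  }
  out
}

#' Principal component analysis of the filtered expression matrix
#'
#' Genes are centered and unit-scaled across samples, then decomposed with
#' [stats::prcomp()] on the samples x genes matrix. Per-component variance
#' fractions and per-gene contributions (percent of the squared loading
#' norm) are reported. A deterministic sign convention makes the gene with
#' the largest absolute loading positive on each component, so results are
#' invariant to gene and sample order.
#'
#' @param mat Genes x samples matrix (normalized counts restricted to
#'   filtered genes).
#' @param log2_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return Object of class `orgretain_pca`: `scores` tibble (`sample_id` +
#'   PCs), `loadings` (genes x PCs), `variance_fraction`, `contribution`
#'   (genes x PCs, percent).
#' @export
run_pca <- function(mat, log2_transform = TRUE) {
  assert_that(nrow(mat) >= 2 && ncol(mat) >= 2, "need >= 2 genes and samples")
  x <- if (log2_transform) log2(mat + 1) else mat
  vars <- row_vars(x)
  if (any(vars == 0)) {
    warn(paste0("dropping ", sum(vars == 0), " zero-variance gene(s)"))
    x <- x[vars > 0, , drop = FALSE]
  }
  # order-canonical basis: PCA of the gene-sorted matrix, results re-labelled
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  pc <- prcomp(t(x), center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  contrib <- 100 * sweep(load^2, 2, colSums(load^2), `/`)
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = colnames(x)),
                              as_tibble(scores)),
    loadings = load,
    variance_fraction = setNames(frac, colnames(load)),
    contribution = contrib),
    class = "orgretain_pca")
}

#' @export
print.orgretain_pca <- function(x, ...) {
  cat("PCA on", nrow(x$loadings), "genes x", nrow(x$scores), "samples\n")
  vf <- head(x$variance_fraction, 6)
  cat("variance fractions:",
      paste(sprintf("%s %.1f%%", names(vf), 100 * vf), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn run_pca Long tibble of per-gene contributions.
#' @param x `orgretain_pca` object.
#' @param ... Unused.
#' @method tidy orgretain_pca
#' @export
tidy.orgretain_pca <- function(x, ...) {
  as_tibble(x$contribution, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "component", values_to = "contribution") |>
    mutate(log2_contribution = log2(.data$contribution))
}

#' @describeIn run_pca One-row-per-component summary of variance fractions.
#' @method glance orgretain_pca
#' @export
glance.orgretain_pca <- function(x, ...) {
  tibble(component = names(x$variance_fraction),
         variance_fraction = unname(x$variance_fraction))
}

#' Association between a principal component and a design factor
#'
#' Welch's two-tailed t-test for two-level factors; one-way ANOVA F-test
#' for factors with three or more observed levels.
#'
#' @param pca `orgretain_pca` object (or its `scores` tibble).
#' @param samples Sample sheet tibble.
#' @param component Component name, e.g. `"PC1"`.
#' @param factor Factor column name.
#' @return Two-sided p-value.
#' @export
pc_factor_association <- function(pca, samples, component, factor) {
  scores <- if (inherits(pca, "orgretain_pca")) pca$scores else pca
  assert_that(component %in% colnames(scores),
              paste0("component '", component, "' not found"))
  df <- left_join(scores, samples, by = "sample_id")
  lev <- unique(df[[factor]])
  assert_that(length(lev) >= 2,
              paste0("factor '", factor, "' needs >= 2 observed levels"))
  counts <- table(df[[factor]])
  assert_that(all(counts >= 2),
              paste0("level(s) with < 2 samples in '", factor, "': ",
                     paste(names(counts)[counts < 2], collapse = ", ")))
  y <- df[[component]]
  if (length(lev) == 2) {
    a <- y[df[[factor]] == lev[1]]
    b <- y[df[[factor]] == lev[2]]
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) return(1)
    t.test(a, b, var.equal = FALSE)$p.value
  } else {
    fit <- aov(y ~ g, data = data.frame(y = y, g = base::factor(df[[factor]])))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }
}

#' Highly contributing genes of a principal component
#'
#' Genes whose log2 contribution (contribution in percent of the
#' component's squared loadings) reaches the cutoff, sorted by contribution
#' descending. The default fixed cutoff -3.32 corresponds to about 0.1%
#' contribution; `method = "density"` instead places the cutoff at the knee
#' of the sorted log2-contribution curve.
#'
#' @param pca `orgretain_pca` object.
#' @param component Component name.
#' @param cutoff_log2 Fixed cutoff on `log2(contribution)` (default -3.32).
#' @param method `"fixed"` or `"density"`.
#' @return Tibble `gene`, `contribution`, `log2_contribution`, descending.
#' @export
contributing_genes <- function(pca, component, cutoff_log2 = -3.32,
                               method = c("fixed", "density")) {
  method <- match.arg(method)
  assert_that(component %in% colnames(pca$contribution),
              paste0("component '", component, "' not found"))
  co <- unname(pca$contribution[, component])
  df <- tibble(gene = rownames(pca$contribution), contribution = co,
               log2_contribution = log2(co)) |>
    arrange(desc(.data$contribution), .data$gene)
  if (method == "density") {
    # knee: point of maximum distance below the chord of the sorted curve
    yv <- df$log2_contribution[is.finite(df$log2_contribution)]
    nf <- length(yv)
    if (nf >= 3) {
      xs <- seq_len(nf)
      chord <- yv[1] + (yv[nf] - yv[1]) * (xs - 1) / (nf - 1)
      cutoff_log2 <- yv[which.max(chord - yv)]
    }
  }
  filter(df, .data$log2_contribution >= cutoff_log2)
}
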