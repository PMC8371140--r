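#' Median-of-ratios size factors
#'
#' Computes per-sample scaling constants equalizing sequencing depth: for
#' each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples. Genes with a zero count in any
#' sample are excluded from the median (their geometric mean is zero).
#'
#' @param counts Genes x samples matrix.
#' @param use_pseudo_reference If `TRUE`, the geometric mean of each gene is
#'   computed over its positive counts only, rescuing data sets where every
#'   gene has at least one zero.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, use_pseudo_reference = FALSE) {
  check_count_matrix(counts)
  if (use_pseudo_reference) {
    log_gm <- apply(counts, 1, function(x) {
      pos <- x > 0
      if (!any(pos)) -Inf else mean(log(x[pos]))
    })
    usable <- is.finite(log_gm)
  } else {
    usable <- rowSums(counts == 0) == 0
    log_gm <- rep(NA_real_, nrow(counts))
    log_gm[usable] <- rowMeans(log(counts[usable, , drop = FALSE]))
  }
  if (!any(usable)) {
    abort(paste0("no gene has nonzero counts in every sample; ",
                 "retry with use_pseudo_reference = TRUE"))
  }
  lr <- log(counts[usable, , drop = FALSE]) - log_gm[usable]
  if (use_pseudo_reference) lr[!is.finite(lr)] <- NA
  sf <- exp(apply(lr, 2, median, na.rm = TRUE))
  setNames(sf, colnames(counts))
}

#' Divide counts by their size factors
#'
#' @param counts Genes x samples matrix.
#' @param factors Positive per-sample factors (defaults to
#'   [size_factors()]).
#' @return Real-valued matrix of normalized counts; zeros are preserved.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  assert_that(all(factors > 0), "size factors must be positive")
  assert_that(length(factors) == ncol(counts),
              "one size factor per sample is required")
  sweep(counts, 2, factors, `/`)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; monotone in rank and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs pass through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  assert_that(all(ok), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Method-of-moments NB dispersion on normalized counts, pooled within the
# two groups, shrunk 50% toward a fitted mean-dispersion trend a0 + a1/mu.
estimate_dispersion <- function(norm, group, inv_sf_mean, floor = 1e-8) {
  mu <- rowMeans(norm)
  ss <- 0
  df <- 0
  for (g in unique(group)) {
    sub <- norm[, group == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + ncol(sub) - 1
  }
  s2 <- ss / df
  raw <- (s2 - mu * inv_sf_mean) / mu^2
  raw[!is.finite(raw)] <- floor
  raw <- pmax(raw, floor)
  fit_ok <- mu > 0 & raw > floor
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(lm(raw[fit_ok] ~ I(1 / mu[fit_ok])))
    trend <- pmax(co[1] + co[2] / mu, floor)
  } else {
    trend <- rep(median(raw), length(raw))
  }
  pmax(0.5 * raw + 0.5 * trend, floor)
}

#' Per-gene negative-binomial Wald test
#'
#' A simplified two-group differential-expression engine: per gene, group
#' means of size-factor-normalized counts estimate the NB means, dispersion
#' comes from a trend-shrunk method-of-moments estimator
#' (Var = mu + alpha * mu^2), and a Wald z-statistic on the log ratio of
#' group means gives a two-sided p-value, BH-adjusted within the contrast.
#' All-zero genes are flagged `tested = FALSE` with NA statistics rather
#' than dropped.
#'
#' @param counts Genes x samples matrix.
#' @param samples Sample sheet tibble with `sample_id` and factor columns.
#' @param contrast Character vector `c(factor, level_a, level_b)`: log2 fold
#'   changes are `level_a` relative to `level_b` (e.g. aboral relative to a
#'   reference of oral).
#' @param stratum Optional named list of factor = level filters applied
#'   before testing (stratified contrasts are separate single-factor fits).
#' @return A tibble of class `orgretain_deg`: `gene`, `baseMean`, `log2FC`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`, `tested`; the contrast is stored in
#'   attributes `factor`, `level_a`, `level_b`, `stratum`.
#' @export
nb_wald_test <- function(counts, samples, contrast, stratum = NULL) {
  check_count_matrix(counts)
  assert_that(length(contrast) == 3, "contrast must be c(factor, level_a, level_b)")
  fac <- contrast[1]; la <- contrast[2]; lb <- contrast[3]
  assert_that(fac %in% colnames(samples),
              paste0("factor '", fac, "' not in the sample sheet"))
  keep <- rep(TRUE, nrow(samples))
  for (f in names(stratum)) keep <- keep & samples[[f]] == stratum[[f]]
  sheet <- samples[keep, , drop = FALSE]
  sel <- sheet[[fac]] %in% c(la, lb)
  sheet <- sheet[sel, , drop = FALSE]
  assert_that(sum(sheet[[fac]] == la) >= 2 && sum(sheet[[fac]] == lb) >= 2,
              paste0("both contrast groups need >= 2 samples (",
                     la, ": ", sum(sheet[[fac]] == la), ", ",
                     lb, ": ", sum(sheet[[fac]] == lb), ")"))
  sub <- counts[, sheet$sample_id, drop = FALSE]
  tested <- rowSums(sub) > 0
  sf <- size_factors(sub)
  norm <- normalize_counts(sub, sf)
  grp <- sheet[[fac]]
  alpha <- estimate_dispersion(norm, grp, mean(1 / sf))
  res <- tibble(gene = rownames(sub), baseMean = rowMeans(norm),
                log2FC = NA_real_, lfcSE = NA_real_, stat = NA_real_,
                pvalue = NA_real_, padj = NA_real_, tested = tested)
  ga <- grp == la; gb <- grp == lb
  na <- sum(ga); nb <- sum(gb)
  qa <- rowMeans(norm[, ga, drop = FALSE])
  qb <- rowMeans(norm[, gb, drop = FALSE])
  # symmetric half-count pseudo-mean only when a group mean is zero, so a
  # gene constant across all samples keeps log2FC exactly 0
  zero_pair <- tested & (qa == 0 | qb == 0)
  qa[zero_pair] <- qa[zero_pair] + 0.5 / na
  qb[zero_pair] <- qb[zero_pair] + 0.5 / nb
  # Var(qhat) for mean of normalized NB counts: q * sum(1/s)/n^2 + alpha q^2 / n
  se2 <- function(q, idx, n) (sum(1 / sf[idx]) / n^2) / q + alpha / n
  se_log <- sqrt(se2(qa, ga, na) + se2(qb, gb, nb))
  lfc <- log2(qa / qb)
  z <- (log(qa) - log(qb)) / se_log
  res$log2FC[tested] <- lfc[tested]
  res$lfcSE[tested] <- (se_log / log(2))[tested]
  res$stat[tested] <- z[tested]
  res$pvalue[tested] <- 2 * pnorm(-abs(z[tested]))
  res$padj[tested] <- bh_adjust(res$pvalue[tested])
  structure(res, class = c("orgretain_deg", class(res)),
            factor = fac, level_a = la, level_b = lb, stratum = stratum)
}

#' @export
print.orgretain_deg <- function(x, ...) {
  cat("DEG table: ", attr(x, "level_a"), " vs ", attr(x, "level_b"),
      " (", attr(x, "factor"), ")", sep = "")
  st <- attr(x, "stratum")
  if (length(st)) {
    cat(" | stratum:", paste(names(st), unlist(st), sep = "=", collapse = ", "))
  }
  cat("\n")
  NextMethod()
}
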