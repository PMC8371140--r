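#' Build a DEG matrix from per-contrast tables
#'
#' Genes x contrasts matrix of log2 fold changes in which a gene's entry is
#' its log2FC where it passes the significance rule for that contrast and
#' exactly 0 otherwise; genes significant in no contrast are dropped (the
#' all-zero rows carry no information for the downstream models; set
#' `keep_all = TRUE` to retain the full union).
#'
#' @param deg_tables Named list of DEG tibbles (from [nb_wald_test()]).
#' @param rule `"padj"` (adjusted p, default) or `"pvalue"` (raw p).
#' @param alpha Significance threshold (default 0.05).
#' @param keep_all Keep genes that pass nowhere (default `FALSE`).
#' @return Tibble of class `orgretain_degmatrix`: `gene` plus one log2FC
#'   column per contrast; attributes `rule`, `alpha`, `empty`.
#' @export
build_deg_matrix <- function(deg_tables, rule = c("padj", "pvalue"),
                             alpha = 0.05, keep_all = FALSE) {
  rule <- match.arg(rule)
  assert_that(length(deg_tables) > 0 && !is.null(names(deg_tables)),
              "deg_tables must be a non-empty named list")
  universe <- deg_tables[[1]]$gene
  cols <- imap(deg_tables, function(tab, nm) {
    dup <- tab$gene[duplicated(tab$gene)]
    assert_that(length(dup) == 0,
                paste0("contrast '", nm, "' has duplicate gene entries: ",
                       paste(unique(dup), collapse = ", ")))
    assert_that(setequal(tab$gene, universe),
                paste0("contrast '", nm, "' does not share the gene universe"))
    tab <- tab[match(universe, tab$gene), ]
    pass <- !is.na(tab[[rule]]) & tab[[rule]] < alpha
    ifelse(pass, tab$log2FC, 0)
  })
  mat <- dplyr::bind_cols(tibble(gene = universe), as_tibble(cols))
  if (!keep_all) {
    nz <- rowSums(abs(as.matrix(mat[-1])) > 0) > 0
    mat <- mat[nz, , drop = FALSE]
  }
  structure(mat, class = c("orgretain_degmatrix", class(mat)),
            rule = rule, alpha = alpha, empty = nrow(mat) == 0)
}

#' Effect size of predictors on an outcome DEG vector
#'
#' Ordinary least squares of one log2FC column on one or more others, with
#' intercept. The effect size is the adjusted coefficient of determination
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)`; model quality is the overall F-test.
#'
#' @param data Tibble (e.g. an `orgretain_degmatrix`).
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @return Object of class `orgretain_effect`: tibble row `outcome`,
#'   `predictors`, `adj_r2`, `f_statistic`, `p_value`, `n_genes`, with the
#'   fitted `lm` in attribute `fit`.
#' @export
effect_size <- function(data, outcome, predictors) {
  assert_that(outcome %in% colnames(data),
              paste0("outcome '", outcome, "' not found"))
  missing <- setdiff(predictors, colnames(data))
  assert_that(length(missing) == 0,
              paste0("predictor(s) not found: ", paste(missing, collapse = ", ")))
  n <- nrow(data)
  k <- length(predictors)
  assert_that(n >= k + 2, "need at least predictors + 2 observations")
  y <- data[[outcome]]
  assert_that(sd(y) > 0, paste0("outcome '", outcome, "' is constant"))
  X <- as.matrix(data[predictors])
  if (k > 1) {
    qx <- qr(cbind(1, X))
    if (qx$rank < k + 1) {
      cm <- stats::cor(X)
      diag(cm) <- 0
      idx <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      pair <- sort(predictors[idx])
      abort(paste0("collinear predictors: ", pair[1], " and ", pair[2]))
    }
  } else {
    assert_that(sd(X[, 1]) > 0,
                paste0("predictor '", predictors[1], "' is constant"))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = ".y")
  fit <- lm(fml, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  out <- tibble(outcome = outcome,
                predictors = paste(predictors, collapse = " + "),
                adj_r2 = sm$adj.r.squared,
                f_statistic = unname(fstat[1]),
                p_value = unname(pval),
                n_genes = n)
  structure(out, class = c("orgretain_effect", class(out)), fit = fit)
}

#' @describeIn effect_size Coefficient-level summary of the underlying fit.
#' @param x `orgretain_effect` object.
#' @param ... Unused.
#' @method tidy orgretain_effect
#' @export
tidy.orgretain_effect <- function(x, ...) {
  co <- summary(attr(x, "fit"))$coefficients
  tibble(term = rownames(co), estimate = unname(co[, 1]),
         std_error = unname(co[, 2]), statistic = unname(co[, 3]),
         p_value = unname(co[, 4]))
}

#' @describeIn effect_size One-row model summary (the effect-size row).
#' @method glance orgretain_effect
#' @export
glance.orgretain_effect <- function(x, ...) {
  as_tibble(x)
}

#' How much of each in vivo feature survives in vitro
#'
#' For each biological feature (compartment, gender, aging), regresses the
#' in vivo log2FC vector on the matching in vitro vector (simple model) and
#' on all three in vitro vectors together (combined model), over the union
#' of genes significant anywhere (outer join, zero-filled). The adjusted
#' R-squared of each model is the retained effect size.
#'
#' @param deg_vivo,deg_vitro `orgretain_degmatrix` objects whose columns are
#'   named by feature.
#' @param features Feature columns present in both matrices.
#' @return Tibble: one row per (feature, model), columns of
#'   [effect_size()].
#' @export
feature_retention <- function(deg_vivo, deg_vitro,
                              features = c("compartment", "gender", "aging")) {
  for (f in features) {
    assert_that(f %in% colnames(deg_vivo) && f %in% colnames(deg_vitro),
                paste0("feature '", f, "' absent from a DEG matrix"))
  }
  vivo <- rename_with_prefix(deg_vivo[c("gene", features)], "vivo_", features)
  vitro <- rename_with_prefix(deg_vitro[c("gene", features)], "vitro_", features)
  joined <- dplyr::full_join(vivo, vitro, by = "gene")
  joined[is.na(joined)] <- 0
  map_dfr(features, function(f) {
    bind_rows(
      mutate(as_tibble(effect_size(joined, paste0("vivo_", f),
                                   paste0("vitro_", f))),
             feature = f, model = "simple"),
      mutate(as_tibble(effect_size(joined, paste0("vivo_", f),
                                   paste0("vitro_", features))),
             feature = f, model = "combined"))
  }) |>
    select("feature", "model", dplyr::everything())
}

rename_with_prefix <- function(df, prefix, cols) {
  colnames(df)[match(cols, colnames(df))] <- paste0(prefix, cols)
  df
}

#' Effect of compartment and gender on the aging signature
#'
#' Stacks the per-stratum young-vs-old log2FC columns of an aging DEG
#' matrix into long form (one row per gene x stratum) and regresses the
#' log2FC on the stratum's compartment indicator, its gender indicator, and
#' both together. Gene-to-gene variation stays in the residual, so these
#' effect sizes are small by construction; they measure how much the aging
#' response differs between strata.
#'
#' @param aging_deg `orgretain_degmatrix` whose columns are per-stratum
#'   aging contrasts.
#' @param strata Tibble `contrast`, `compartment`, `gender` describing each
#'   column.
#' @return Tibble: one row per model (`compartment`, `gender`,
#'   `compartment + gender`), columns of [effect_size()].
#' @export
aging_modifiers <- function(aging_deg, strata) {
  missing <- setdiff(strata$contrast, colnames(aging_deg))
  assert_that(length(missing) == 0,
              paste0("missing stratum column(s): ",
                     paste(missing, collapse = ", ")))
  long <- pivot_longer(aging_deg, dplyr::all_of(strata$contrast),
                       names_to = "contrast", values_to = "log2FC") |>
    left_join(strata, by = "contrast")
  wide <- dplyr::bind_cols(
    long["log2FC"],
    as_tibble(stats::model.matrix(~ compartment + gender, data = long)[, -1,
                                                                       drop = FALSE]))
  comp_cols <- grep("^compartment", colnames(wide), value = TRUE)
  gend_cols <- grep("^gender", colnames(wide), value = TRUE)
  bind_rows(
    mutate(as_tibble(effect_size(wide, "log2FC", comp_cols)),
           model = "compartment"),
    mutate(as_tibble(effect_size(wide, "log2FC", gend_cols)),
           model = "gender"),
    mutate(as_tibble(effect_size(wide, "log2FC", c(comp_cols, gend_cols))),
           model = "compartment + gender")) |>
    select("model", dplyr::everything())
}

#' Overlap counts among DEG sets
#'
#' Pairwise intersection, difference and Jaccard statistics plus the size
#' of the full intersection across all sets.
#'
#' @param sets Named list of gene-ID vectors.
#' @return List: `pairwise` tibble (`set_a`, `set_b`, `n_a`, `n_b`,
#'   `intersection`, `only_a`, `only_b`, `jaccard`) and
#'   `full_intersection` count.
#' @export
deg_overlap <- function(sets) {
  assert_that(length(sets) >= 2 && !is.null(names(sets)),
              "need >= 2 named sets")
  nms <- names(sets)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  pw <- map_dfr(pairs, function(p) {
    a <- unique(sets[[p[1]]]); b <- unique(sets[[p[2]]])
    un <- length(union(a, b))
    tibble(set_a = p[1], set_b = p[2], n_a = length(a), n_b = length(b),
           intersection = length(intersect(a, b)),
           only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
           jaccard = if (un == 0) NA_real_ else length(intersect(a, b)) / un)
  })
  list(pairwise = pw,
       full_intersection = length(Reduce(intersect, lapply(sets, unique))))
}
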