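#' Normalize single-cell counts
#'
#' Removes non-expressed genes, drops zero-total cells (with a warning
#' count), rescales every remaining cell so its total equals the median
#' per-cell total, and log10-transforms with a pseudocount of 1. The
#' linear (de-logged) scale is kept alongside because signature building
#' and deconvolution mix linearly.
#'
#' @param counts Cells x genes matrix.
#' @return Object of class `orgretain_cellnorm`: `log10` and `linear`
#'   matrices (cells x genes), `dropped_cells`, `target_total`.
#' @export
normalize_cells <- function(counts) {
  check_count_matrix(counts, "single-cell counts")
  expressed <- colSums(counts) > 0
  counts <- counts[, expressed, drop = FALSE]
  totals <- rowSums(counts)
  dropped <- rownames(counts)[totals == 0]
  if (length(dropped)) {
    warn(paste0("dropped ", length(dropped), " zero-total cell(s)"))
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  target <- median(totals)
  linear <- counts * (target / totals)
  structure(list(log10 = log10(linear + 1), linear = linear,
                 dropped_cells = dropped, target_total = target),
            class = "orgretain_cellnorm")
}

#' k-means clustering of normalized cells
#'
#' Runs k-means (`nstart` restarts, best inertia kept) on the top principal
#' components of the log-normalized matrix. Deterministic given the seed.
#' Passing `cells` restricts clustering to a subset, which supports the
#' targeted re-clustering of one mixed cluster with `k = 2`.
#'
#' @param norm `orgretain_cellnorm` object.
#' @param k Number of clusters (default 9).
#' @param n_starts k-means restarts (default 10).
#' @param seed Integer seed.
#' @param n_pcs Number of principal components fed to k-means (default 20).
#' @param cells Optional character vector of cell IDs to cluster.
#' @return Named integer vector of cluster labels.
#' @export
cluster_cells <- function(norm, k = 9, n_starts = 10, seed = 1, n_pcs = 20,
                          cells = NULL) {
  x <- norm$log10
  if (!is.null(cells)) x <- x[cells, , drop = FALSE]
  assert_that(k <= nrow(x),
              paste0("k = ", k, " exceeds the number of cells (", nrow(x), ")"))
  if (k == nrow(x)) {
    return(setNames(seq_len(nrow(x)), rownames(x)))  # singletons, inertia 0
  }
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  set.seed(seed)
  km <- kmeans(pc$x, centers = k, nstart = n_starts, iter.max = 100)
  setNames(km$cluster, rownames(x))
}

#' Assign cell types to clusters by marker expression
#'
#' Each cluster receives the type whose marker set has the highest mean
#' z-scored expression (genes z-scored across cells) in that cluster. Ties
#' within `1e-9` are flagged ambiguous; clusters with no expression of any
#' marker set are flagged unassigned, never silently broken.
#'
#' @param labels Cluster labels from [cluster_cells()].
#' @param marker_sets Named list of marker gene IDs, one entry per type.
#' @param norm `orgretain_cellnorm` object.
#' @return Tibble `cluster`, `type`, `score`, `runner_up`, `margin`, `flag`.
#' @export
assign_cell_types <- function(labels, marker_sets, norm) {
  x <- norm$log10[names(labels), , drop = FALSE]
  sds <- sqrt(pmax(apply(x, 2, var), 0))
  keep <- sds > 0
  z <- scale(x[, keep, drop = FALSE])
  rows <- lapply(sort(unique(labels)), function(cl) {
    zc <- z[labels == cl, , drop = FALSE]
    score <- vapply(marker_sets, function(gs) {
      gs <- intersect(gs, colnames(zc))
      if (!length(gs)) return(NA_real_)
      mean(zc[, gs, drop = FALSE])
    }, numeric(1))
    raw <- norm$linear[labels == cl, , drop = FALSE]
    any_expr <- any(vapply(marker_sets, function(gs)
      sum(raw[, intersect(gs, colnames(raw)), drop = FALSE]) > 0, logical(1)))
    ord <- order(score, decreasing = TRUE)
    best <- ord[1]; second <- if (length(score) > 1) ord[2] else NA
    margin <- if (!is.na(second)) score[best] - score[second] else Inf
    flag <- if (!any_expr) "unassigned"
            else if (is.finite(margin) && margin < 1e-9) "ambiguous"
            else "ok"
    tibble(cluster = cl,
           type = if (flag == "unassigned") NA_character_
                  else names(marker_sets)[best],
           score = unname(score[best]),
           runner_up = if (!is.na(second)) names(marker_sets)[second]
                       else NA_character_,
           margin = unname(margin), flag = flag)
  })
  bind_rows(rows)
}

#' Define marker genes for one cluster
#'
#' Per gene, the log2 fold change of pseudocounted mean linear-normalized
#' expression (target cluster vs all other cells) and a two-sided Welch
#' t-test on the log-normalized values; p-values are BH-adjusted across
#' genes. Genes with `log2FC >= lfc_min` and adjusted p below `alpha` are
#' markers.
#'
#' @param norm `orgretain_cellnorm` object.
#' @param labels Cluster labels.
#' @param target Target cluster ID.
#' @param lfc_min Log2 fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return Tibble of selected markers: `gene`, `log2FC`, `pvalue`, `padj`,
#'   sorted by decreasing log2FC.
#' @export
define_markers <- function(norm, labels, target, lfc_min = 2, alpha = 0.05,
                           pseudocount = 1) {
  in_t <- names(labels)[labels == target]
  assert_that(length(in_t) >= 3,
              paste0("cluster '", target, "' has fewer than 3 cells"))
  out_t <- setdiff(rownames(norm$linear), in_t)
  lin_a <- norm$linear[in_t, , drop = FALSE]
  lin_b <- norm$linear[out_t, , drop = FALSE]
  lfc <- log2((colMeans(lin_a) + pseudocount) / (colMeans(lin_b) + pseudocount))
  la <- norm$log10[in_t, , drop = FALSE]
  lb <- norm$log10[out_t, , drop = FALSE]
  ma <- colMeans(la); mb <- colMeans(lb)
  va <- row_vars(t(la)); vb <- row_vars(t(lb))
  na <- nrow(la); nb <- nrow(lb)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), dfree)
  p[!is.finite(tstat)] <- 1
  padj <- bh_adjust(p)
  tibble(gene = colnames(norm$linear), log2FC = unname(lfc),
         pvalue = unname(p), padj = unname(padj)) |>
    filter(.data$log2FC >= lfc_min, .data$padj < alpha) |>
    arrange(desc(.data$log2FC))
}

#' Build the cell-type signature matrix
#'
#' Rows are the union of the per-type marker lists; entries are mean
#' linear-normalized expression per cell type, with columns in the declared
#' type order. Markers absent from the matrix or duplicated within one
#' type's list are rejected by name.
#'
#' @param norm `orgretain_cellnorm` object.
#' @param cell_types Per-cell type assignments (named by cell ID), e.g.
#'   cluster labels mapped through [assign_cell_types()].
#' @param markers Named list of marker gene IDs per type (defines column
#'   order).
#' @return Markers x types numeric matrix of class `orgretain_signature`.
#' @export
build_signature <- function(norm, cell_types, markers) {
  assert_that(length(markers) > 0 && !is.null(names(markers)),
              "markers must be a non-empty named list")
  for (nm in names(markers)) {
    dup <- markers[[nm]][duplicated(markers[[nm]])]
    assert_that(length(dup) == 0,
                paste0("duplicate marker(s) in '", nm, "': ",
                       paste(unique(dup), collapse = ", ")))
  }
  all_markers <- unique(unlist(markers))
  assert_that(length(all_markers) > 0, "union of marker lists is empty")
  missing <- setdiff(all_markers, colnames(norm$linear))
  assert_that(length(missing) == 0,
              paste0("marker(s) absent from the matrix: ",
                     paste(missing, collapse = ", ")))
  types <- names(markers)
  cells <- names(cell_types)
  sig <- vapply(types, function(ty) {
    sel <- cells[cell_types == ty]
    assert_that(length(sel) > 0, paste0("no cells assigned to type '", ty, "'"))
    colMeans(norm$linear[sel, all_markers, drop = FALSE])
  }, numeric(length(all_markers)))
  rownames(sig) <- all_markers
  zero_rows <- rownames(sig)[rowSums(sig) == 0]
  assert_that(length(zero_rows) == 0,
              paste0("all-zero marker row(s): ",
                     paste(zero_rows, collapse = ", ")))
  structure(sig, class = c("orgretain_signature", "matrix", "array"))
}
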