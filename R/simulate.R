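#' Simulation configuration for the crypt/organoid factorial study
#'
#' Builds the configuration object consumed by [simulate_study()] and the
#' individual `simulate_*()` stages. Defaults reproduce the study conditions:
#' a 2 (sample type) x 3 (compartment) x 2 (gender) x 2 (age) factorial with
#' 4 replicates (96 bulk samples), eight intestinal epithelial cell types
#' mixed with condition-dependent compositions, and negative-binomial
#' sampling with per-gene dispersion and per-sample library-size variation.
#'
#' @param n_genes Number of genes to simulate.
#' @param factor_levels Named list of ordered level vectors. The first level
#'   of each factor is its reference level for differential expression.
#' @param n_replicates Biological replicates per factor-level combination.
#' @param cell_types Cell-type names; markers and mixing profiles are built
#'   for each.
#' @param markers_per_type Number of high-expression marker genes planted per
#'   cell type (disjoint blocks).
#' @param effect_spec Per-factor list with elements `frac` (fraction of genes
#'   affected), `lfc_mean`, `lfc_sd` (log2 fold-change magnitude
#'   distribution; signs are random) and, for the in-vivo biology factors,
#'   `share_in_vitro` (fraction of the affected genes whose planted effect is
#'   carried over unchanged into organoid samples; the remainder is
#'   re-planted on fresh genes so in-vitro-specific features exist).
#' @param variance_targets Optional named vector of per-factor shares of the
#'   planted signal variance; planted log2FCs are rescaled analytically so
#'   the factors contribute these shares (total planted variance preserved).
#' @param dispersion List with `meanlog`, `sdlog`, `floor` for the log-normal
#'   per-gene NB dispersion (Var = mu + alpha * mu^2).
#' @param library_size Length-2 range of per-sample total counts (bulk).
#' @param sc_library_size Length-2 range of per-cell total counts.
#' @param composition_spec Named list (one entry per sample type) of Dirichlet
#'   concentration vectors over cell types. The default places stem and TA
#'   cells higher in organoids and differentiated types higher in crypts.
#' @param composition_by_sample_type If `FALSE`, a single pooled concentration
#'   vector (the average of the per-type vectors) is used for all samples, so
#'   sample type shifts expression only, not composition.
#' @param sc_cells_per_type Cells per type in the synthetic single-cell data.
#' @param aging_by_gender List with `frac` and `lfc`: optional in-vivo-only
#'   aging-by-gender interaction (extra aging log2FC in male crypts on a
#'   subset of aging-affected genes).
#' @param seed Root seed; all stages draw from named substreams of it.
#' @return A list of class `orgretain_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       factor_levels = list(
                         sample_type = c("crypt", "organoid"),
                         compartment = c("oral", "intermediate", "aboral"),
                         gender      = c("male", "female"),
                         age         = c("young", "old")),
                       n_replicates = 4,
                       cell_types = c("Stem", "TA", "LateEnterocyteProgenitor",
                                      "Enterocyte", "Enteroendocrine",
                                      "Goblet", "Paneth", "Tuft"),
                       markers_per_type = 30,
                       effect_spec = list(
                         sample_type = list(frac = 0.30, lfc_mean = 2.5, lfc_sd = 0.5),
                         compartment = list(frac = 0.15, lfc_mean = 1.5, lfc_sd = 0.4,
                                            share_in_vitro = 1),
                         gender      = list(frac = 0.10, lfc_mean = 1.2, lfc_sd = 0.4,
                                            share_in_vitro = 1),
                         age         = list(frac = 0.08, lfc_mean = 1.0, lfc_sd = 0.3,
                                            share_in_vitro = 1)),
                       variance_targets = c(sample_type = 0.60, compartment = 0.20,
                                            gender = 0.12, age = 0.08),
                       dispersion = list(meanlog = log(0.05), sdlog = 0.5, floor = 1e-4),
                       library_size = c(1e6, 2e6),
                       sc_library_size = c(8000, 15000),
                       composition_spec = NULL,
                       composition_by_sample_type = TRUE,
                       sc_cells_per_type = 60,
                       aging_by_gender = list(frac = 0, lfc = 0),
                       seed = 1L) {
  assert_that(n_genes >= 2, "n_genes must be >= 2")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  assert_that(length(cell_types) >= 2 && !anyDuplicated(cell_types),
              "cell_types must be >= 2 unique names")
  for (f in names(factor_levels)) {
    lv <- factor_levels[[f]]
    assert_that(length(lv) >= 1 && !anyDuplicated(lv),
                paste0("duplicate or empty level names in factor '", f, "'"))
  }
  for (f in names(effect_spec)) {
    fr <- effect_spec[[f]]$frac
    assert_that(fr >= 0 && fr <= 1,
                paste0("effect fraction for '", f, "' must lie in [0, 1]"))
    s <- effect_spec[[f]]$share_in_vitro %||% 1
    assert_that(s >= 0 && s <= 1,
                paste0("share_in_vitro for '", f, "' must lie in [0, 1]"))
  }
  if (is.null(composition_spec)) {
    composition_spec <- default_composition_spec(cell_types)
  }
  for (nm in names(composition_spec)) {
    assert_that(all(composition_spec[[nm]] > 0),
                "Dirichlet concentrations must be > 0")
    assert_that(length(composition_spec[[nm]]) == length(cell_types),
                "composition_spec length must match cell_types")
  }
  assert_that(length(library_size) == 2 && all(library_size > 0),
              "library_size must be a positive range")
  structure(
    list(n_genes = as.integer(n_genes), factor_levels = factor_levels,
         n_replicates = as.integer(n_replicates), cell_types = cell_types,
         markers_per_type = as.integer(markers_per_type),
         effect_spec = effect_spec, variance_targets = variance_targets,
         dispersion = dispersion, library_size = library_size,
         sc_library_size = sc_library_size,
         composition_spec = composition_spec,
         composition_by_sample_type = isTRUE(composition_by_sample_type),
         sc_cells_per_type = as.integer(sc_cells_per_type),
         aging_by_gender = aging_by_gender, seed = as.integer(seed)),
    class = "orgretain_config")
}

default_composition_spec <- function(cell_types) {
  k <- length(cell_types)
  crypt <- rep(2, k)
  organoid <- rep(2, k)
  names(crypt) <- names(organoid) <- cell_types
  undiff <- intersect(c("Stem", "TA"), cell_types)
  diffd <- intersect(c("LateEnterocyteProgenitor", "Enterocyte",
                       "Goblet", "Paneth"), cell_types)
  crypt[undiff] <- 4
  crypt[diffd] <- 8
  organoid[undiff] <- 16
  organoid[diffd] <- 3
  list(crypt = crypt, organoid = organoid)
}

#' Generate the full factorial sample sheet
#'
#' Crosses every factor level with every other and with `1:n_replicates`,
#' in the declared order, and assigns deterministic sample IDs that encode
#' the levels. The default configuration yields 96 samples.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with `sample_id`, one column per factor, and `replicate`.
#' @export
simulate_design <- function(config = sim_config()) {
  lv <- config$factor_levels
  for (f in names(lv)) {
    assert_that(!anyDuplicated(lv[[f]]),
                paste0("duplicate level names in factor '", f, "'"))
  }
  grid <- do.call(expand_grid, c(lv, list(replicate = seq_len(config$n_replicates))))
  id_cols <- do.call(paste, c(grid, list(sep = "_")))
  assert_that(!anyDuplicated(id_cols), "sample IDs are not unique")
  dplyr::bind_cols(tibble(sample_id = id_cols), grid)
}

#' Plant cell-type expression profiles and marker blocks
#'
#' Every cell type receives a disjoint block of high-expression marker genes
#' sitting at least 3 log2 units above the shared baseline of all other
#' types; non-marker genes share one baseline expression drawn per gene.
#' Per-gene NB dispersions are drawn here so bulk and single-cell stages use
#' the same values.
#'
#' @inheritParams simulate_design
#' @return A list of class `orgretain_truth` with `profiles` (genes x types,
#'   strictly positive, linear scale), `marker_sets` (named list of gene IDs
#'   per type), `dispersion` (per gene) and empty slots filled later.
#' @export
simulate_profiles <- function(config = sim_config()) {
  k <- length(config$cell_types)
  m <- config$markers_per_type
  g <- config$n_genes
  assert_that(k >= 2, "need at least 2 cell types")
  assert_that(g >= k * m + 10,
              paste0("n_genes too small to allocate ", k, " x ", m,
                     " marker blocks"))
  gene_ids <- sprintf("gene_%05d", seq_len(g))
  with_substream(config$seed, "profiles", {
    baseline <- rnorm(g, mean = 5, sd = 2)
    marker_idx <- matrix(seq_len(k * m), nrow = m)  # disjoint leading blocks
    # markers are canonical high-expression genes
    baseline[seq_len(k * m)] <- runif(k * m, 6, 9)
    profiles <- matrix(2^baseline, nrow = g, ncol = k,
                       dimnames = list(gene_ids, config$cell_types))
    marker_sets <- list()
    for (j in seq_len(k)) {
      idx <- marker_idx[, j]
      boost <- runif(m, 3, 5)
      profiles[idx, j] <- profiles[idx, j] * 2^boost
      marker_sets[[config$cell_types[j]]] <- gene_ids[idx]
    }
    alpha <- pmax(rlnorm(g, config$dispersion$meanlog, config$dispersion$sdlog),
                  config$dispersion$floor)
    names(alpha) <- gene_ids
    structure(list(gene_ids = gene_ids, profiles = profiles,
                   marker_sets = marker_sets, dispersion = alpha,
                   true_log2fc = NULL, true_log2fc_vitro = NULL,
                   affected_gene_sets = NULL, compositions = NULL),
              class = "orgretain_truth")
  })
}

# Per-sample design codes multiplying the planted log2FC: 0/1 indicators for
# two-level factors, a 0 / 0.5 / 1 gradient for the three compartments, so
# the last-vs-first contrast recovers the planted log2FC exactly.
factor_code <- function(levels_present, values) {
  n <- length(levels_present)
  if (n == 1) return(rep(0, length(values)))
  code <- (match(values, levels_present) - 1) / (n - 1)
  assert_that(!anyNA(code), "sample sheet contains undeclared factor levels")
  code
}

#' Plant per-factor log2 fold-changes
#'
#' For each factor, a random gene subset of the configured fraction receives
#' a log2FC with random sign and magnitude `N(lfc_mean, lfc_sd)` (magnitudes
#' truncated below at 0.1). When `variance_targets` are set, each factor's
#' log2FCs are rescaled so the factors contribute the requested shares of
#' the total planted signal variance across the balanced design; the total
#' planted variance is preserved. In-vitro copies keep a `share_in_vitro`
#' fraction of each factor's effects and re-plant the remainder on fresh
#' genes.
#'
#' @param truth Result of [simulate_profiles()].
#' @inheritParams simulate_design
#' @return The truth object with `true_log2fc` (in vivo), `true_log2fc_vitro`
#'   and `affected_gene_sets` filled in.
#' @export
simulate_effects <- function(truth, config = sim_config()) {
  g <- config$n_genes
  gene_ids <- truth$gene_ids
  factors <- names(config$factor_levels)
  with_substream(config$seed, "effects", {
    lfc_vivo <- matrix(0, g, length(factors),
                       dimnames = list(gene_ids, factors))
    lfc_vitro <- lfc_vivo
    affected <- list()
    for (f in factors) {
      spec <- config$effect_spec[[f]]
      if (is.null(spec) || spec$frac <= 0) {
        affected[[f]] <- character(0)
        next
      }
      n_aff <- round(spec$frac * g)
      idx <- sample.int(g, n_aff)
      mag <- pmax(abs(rnorm(n_aff, spec$lfc_mean, spec$lfc_sd)), 0.1)
      sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
      lfc_vivo[idx, f] <- sgn * mag
      affected[[f]] <- gene_ids[idx]
      if (f == "sample_type") {
        lfc_vitro[, f] <- lfc_vivo[, f]
      } else {
        share <- spec$share_in_vitro %||% 1
        n_keep <- round(share * n_aff)
        keep <- idx[seq_len(n_keep)]
        lfc_vitro[keep, f] <- lfc_vivo[keep, f]
        n_new <- n_aff - n_keep
        if (n_new > 0) {
          pool <- setdiff(seq_len(g), idx)
          fresh <- sample(pool, n_new)
          lfc_vitro[fresh, f] <- sample(c(-1, 1), n_new, replace = TRUE) *
            pmax(abs(rnorm(n_new, spec$lfc_mean, spec$lfc_sd)), 0.1)
        }
      }
    }
    lfc_vivo <- rescale_to_variance_targets(lfc_vivo, config)
    lfc_vitro <- rescale_to_variance_targets(lfc_vitro, config)
    truth$true_log2fc <- lfc_vivo
    truth$true_log2fc_vitro <- lfc_vitro
    truth$affected_gene_sets <- affected
    truth
  })
}

# Across the balanced design the per-gene planted variance is lfc^2 * v_f,
# v = 1/4 for two-level indicators and var({0,.5,1}) = 1/6 for compartment.
planted_variance_weight <- function(n_levels) {
  x <- (seq_len(n_levels) - 1) / (n_levels - 1)
  mean(x^2) - mean(x)^2
}

rescale_to_variance_targets <- function(lfc, config) {
  tg <- config$variance_targets
  if (is.null(tg)) return(lfc)
  factors <- colnames(lfc)
  v <- vapply(factors, function(f) {
    w <- planted_variance_weight(length(config$factor_levels[[f]]))
    sum(lfc[, f]^2) * w
  }, numeric(1))
  total <- sum(v)
  if (total == 0) return(lfc)
  tg <- tg[factors] / sum(tg[factors])
  for (f in factors) {
    if (v[[f]] > 0) lfc[, f] <- lfc[, f] * sqrt(tg[[f]] * total / v[[f]])
  }
  lfc
}

#' Simulate bulk RNA-seq counts for the factorial design
#'
#' Each sample's expected expression mixes the cell-type profiles by a
#' Dirichlet-drawn composition, is shifted multiplicatively by the planted
#' log2 fold-changes matching the sample's factor levels (crypt samples use
#' the in-vivo effect matrix, organoids the in-vitro one), is scaled to the
#' sample's library size, and is read out as NB(mu, alpha) counts.
#'
#' @param design Sample sheet from [simulate_design()].
#' @param truth Truth object from [simulate_effects()].
#' @inheritParams simulate_design
#' @return A list with `counts` (genes x samples integer matrix) and `truth`
#'   updated with the realized `compositions` (samples x cell types).
#' @export
simulate_bulk_counts <- function(design, truth, config = sim_config()) {
  assert_that(!is.null(truth$true_log2fc),
              "truth lacks planted effects; run simulate_effects() first")
  g <- config$n_genes
  assert_that(nrow(truth$profiles) == g, "truth and config dimensions disagree")
  n <- nrow(design)
  factors <- names(config$factor_levels)
  codes <- vapply(factors, function(f)
    factor_code(config$factor_levels[[f]], design[[f]]), numeric(n))
  codes <- matrix(codes, nrow = n, dimnames = list(NULL, factors))
  with_substream(config$seed, "bulk", {
    comp <- matrix(NA_real_, n, length(config$cell_types),
                   dimnames = list(design$sample_id, config$cell_types))
    spec <- config$composition_spec
    if (!config$composition_by_sample_type) {
      pooled <- Reduce(`+`, spec) / length(spec)
      spec <- setNames(lapply(names(spec), function(x) pooled), names(spec))
    }
    for (st in config$factor_levels$sample_type) {
      rows <- which(design$sample_type == st)
      conc <- spec[[st]] %||% spec[[1]]
      comp[rows, ] <- rdirichlet(length(rows), conc)
    }
    lib <- runif(n, config$library_size[1], config$library_size[2])
    counts <- matrix(0L, g, n, dimnames = list(truth$gene_ids, design$sample_id))
    is_org <- design$sample_type == config$factor_levels$sample_type[2]
    abg <- config$aging_by_gender
    abg_genes <- integer(0)
    if ((abg$frac %||% 0) > 0 && length(truth$affected_gene_sets$age)) {
      aged <- match(truth$affected_gene_sets$age, truth$gene_ids)
      abg_genes <- aged[seq_len(round(abg$frac * length(aged)))]
    }
    for (i in seq_len(n)) {
      mix <- as.vector(truth$profiles %*% comp[i, ])
      lfc <- if (is_org[i]) truth$true_log2fc_vitro else truth$true_log2fc
      shift <- as.vector(lfc[, factors, drop = FALSE] %*% codes[i, ])
      if (length(abg_genes) && !is_org[i] &&
          design$gender[i] == "male" && design$age[i] == "old") {
        shift[abg_genes] <- shift[abg_genes] + abg$lfc
      }
      mu <- mix * 2^shift
      mu <- mu / sum(mu) * lib[i]
      counts[, i] <- rnbinom(g, mu = mu, size = 1 / pmax(truth$dispersion, 1e-12))
    }
    storage.mode(counts) <- "integer"
    truth$compositions <- comp
    list(counts = counts, truth = truth)
  })
}

#' Simulate labeled single-cell counts
#'
#' Each cell's expected expression is proportional to its type's planted
#' profile, scaled to a per-cell library size and read out as NB counts with
#' the same per-gene dispersions as the bulk stage.
#'
#' @param truth Truth object from [simulate_profiles()] (effects not needed).
#' @inheritParams simulate_design
#' @return A list with `counts` (cells x genes integer matrix), `labels`
#'   (cell-type per cell) and `barcodes`.
#' @export
simulate_sc_counts <- function(truth, config = sim_config()) {
  assert_that(config$sc_cells_per_type >= 10, "sc_cells_per_type must be >= 10")
  k <- length(config$cell_types)
  g <- config$n_genes
  n_cells <- k * config$sc_cells_per_type
  with_substream(config$seed, "sc", {
    labels <- rep(config$cell_types, each = config$sc_cells_per_type)
    barcodes <- sprintf("cell_%04d", seq_len(n_cells))
    lib <- runif(n_cells, config$sc_library_size[1], config$sc_library_size[2])
    counts <- matrix(0L, n_cells, g, dimnames = list(barcodes, truth$gene_ids))
    size <- 1 / pmax(truth$dispersion, 1e-12)
    for (i in seq_len(n_cells)) {
      pr <- truth$profiles[, labels[i]]
      mu <- pr / sum(pr) * lib[i]
      counts[i, ] <- rnbinom(g, mu = mu, size = size)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, labels = labels, barcodes = barcodes)
  })
}

#' Run the complete synthetic study
#'
#' Convenience wrapper chaining [simulate_design()], [simulate_profiles()],
#' [simulate_effects()], [simulate_bulk_counts()] and [simulate_sc_counts()].
#'
#' @inheritParams simulate_design
#' @param sc Also simulate the single-cell data (default `TRUE`).
#' @return A list of class `orgretain_sim` with `config`, `samples` (tibble),
#'   `counts` (bulk, genes x samples), `sc_counts` (cells x genes),
#'   `sc_labels`, and `truth`.
#' @export
simulate_study <- function(config = sim_config(), sc = TRUE) {
  design <- simulate_design(config)
  truth <- simulate_effects(simulate_profiles(config), config)
  bulk <- simulate_bulk_counts(design, truth, config)
  out <- list(config = config, samples = design, counts = bulk$counts,
              truth = bulk$truth)
  if (sc) {
    scd <- simulate_sc_counts(bulk$truth, config)
    out$sc_counts <- scd$counts
    out$sc_labels <- scd$labels
  }
  structure(out, class = "orgretain_sim")
}

#' @export
print.orgretain_sim <- function(x, ...) {
  cat("Synthetic crypt/organoid study\n")
  cat("  bulk:  ", nrow(x$counts), " genes x ", ncol(x$counts), " samples\n",
      sep = "")
  if (!is.null(x$sc_counts)) {
    cat("  sc:    ", nrow(x$sc_counts), " cells x ", ncol(x$sc_counts),
        " genes (", length(unique(x$sc_labels)), " types)\n", sep = "")
  }
  cat("  seed:  ", x$config$seed, "\n", sep = "")
  invisible(x)
}
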