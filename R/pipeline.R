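#' Run the full synthetic study end to end
#'
#' Orchestrates simulate -> normalize/DE -> variance decomposition ->
#' single-cell reference -> deconvolution -> enrichment -> effect sizes as
#' one reproducible run. All randomness flows from the root seed through
#' named substreams, so identical config + seed reproduce identical stage
#' hashes; with `out_dir` set, every stage artifact is written to disk and
#' the manifest records each file's MD5.
#'
#' @param config [sim_config()] object.
#' @param seed Root seed (defaults to the config's).
#' @param out_dir Optional output directory for stage artifacts.
#' @param n_permutations Permutations for the enrichment stage.
#' @return Object of class `orgretain_run` with elements `sim`, `size_factors`,
#'   `deg` (named list), `pca`, `associations`, `contributing`, `cellref`,
#'   `deconv`, `gsea`, `effects`, `report`, `manifest`.
#' @export
run_study <- function(config = sim_config(), seed = config$seed,
                      out_dir = NULL, n_permutations = 1000) {
  config$seed <- as.integer(seed)
  lv <- config$factor_levels
  run_stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  sim <- run_stage("simulate", simulate_study(config))
  sf <- run_stage("normalize", size_factors(sim$counts))
  norm <- normalize_counts(sim$counts, sf)

  deg <- run_stage("de", {
    d <- list()
    d$sample_type <- nb_wald_test(sim$counts, sim$samples,
                                  c("sample_type", lv$sample_type[2],
                                    lv$sample_type[1]))
    for (st in lv$sample_type) {
      side <- if (st == lv$sample_type[1]) "vivo" else "vitro"
      stratum <- list(sample_type = st)
      d[[paste0(side, "_compartment")]] <- nb_wald_test(
        sim$counts, sim$samples,
        c("compartment", lv$compartment[length(lv$compartment)],
          lv$compartment[1]), stratum)
      d[[paste0(side, "_gender")]] <- nb_wald_test(
        sim$counts, sim$samples, c("gender", lv$gender[2], lv$gender[1]),
        stratum)
      d[[paste0(side, "_aging")]] <- nb_wald_test(
        sim$counts, sim$samples, c("age", lv$age[2], lv$age[1]), stratum)
      for (cp in lv$compartment) {
        for (gd in lv$gender) {
          d[[paste(side, "aging", cp, gd, sep = "_")]] <- nb_wald_test(
            sim$counts, sim$samples, c("age", lv$age[2], lv$age[1]),
            list(sample_type = st, compartment = cp, gender = gd))
        }
      }
    }
    d
  })

  varpart <- run_stage("varpart", {
    genes <- filter_genes(norm, sim$samples)
    pca <- run_pca(norm[genes, , drop = FALSE])
    n_pc <- min(6, length(pca$variance_fraction))
    assoc <- expand_grid(component = paste0("PC", seq_len(n_pc)),
                         factor = names(lv)) |>
      mutate(p_value = map2(.data$component, .data$factor, function(pc, f)
        pc_factor_association(pca, sim$samples, pc, f)) |> unlist())
    contrib <- map_dfr(paste0("PC", seq_len(n_pc)), function(pc)
      tibble(component = pc, n_contributing = nrow(contributing_genes(pca, pc))))
    list(filtered_genes = genes, pca = pca, associations = assoc,
         contributing = contrib)
  })

  cellref <- run_stage("cellref", {
    cn <- normalize_cells(sim$sc_counts)
    k <- length(config$cell_types)
    labels <- cluster_cells(cn, k = k, seed = substream_seed(config$seed,
                                                            "clustering"))
    assignment <- assign_cell_types(labels, sim$truth$marker_sets, cn)
    cell_types <- setNames(
      assignment$type[match(labels, assignment$cluster)], names(labels))
    markers <- list()
    for (i in seq_len(nrow(assignment))) {
      ty <- assignment$type[i]
      if (is.na(ty)) next
      markers[[ty]] <- define_markers(cn, labels, assignment$cluster[i])$gene
    }
    markers <- markers[intersect(config$cell_types, names(markers))]
    sig <- build_signature(cn, cell_types, markers)
    list(norm = cn, labels = labels, assignment = assignment,
         cell_types = cell_types, markers = markers, signature = sig)
  })

  deconv <- run_stage("deconv", {
    est <- deconvolve_samples(sim$counts, cellref$signature)
    tests <- compare_compositions(est, sim$samples)
    val0 <- validate_simulated(cellref$signature, n_mixtures = 50,
                               noise_cv = 0,
                               seed = substream_seed(config$seed, "mixtures"))
    val5 <- validate_simulated(cellref$signature, n_mixtures = 50,
                               noise_cv = 0.05,
                               seed = substream_seed(config$seed, "mixtures"))
    list(estimates = est, tests = tests,
         validation = tibble(noise_cv = c(0, 0.05),
                             r2 = c(val0$r2, val5$r2)),
         scatter = val5$scatter)
  })

  enr <- run_stage("gsea", {
    ranked <- rank_genes(filter(deg$sample_type, .data$tested))
    gsea(ranked, cellref$markers, n_permutations = n_permutations,
         seed = substream_seed(config$seed, "permutations"))
  })

  effects <- run_stage("effects", {
    feat <- c(compartment = "compartment", gender = "gender", aging = "aging")
    vivo_tabs <- setNames(deg[paste0("vivo_", feat)], names(feat))
    vitro_tabs <- setNames(deg[paste0("vitro_", feat)], names(feat))
    deg_vivo <- build_deg_matrix(vivo_tabs, rule = "padj")
    deg_vitro <- build_deg_matrix(vitro_tabs, rule = "padj")
    retention <- feature_retention(deg_vivo, deg_vitro, names(feat))
    strata <- expand_grid(compartment = lv$compartment, gender = lv$gender)
    modifiers <- map_dfr(c(vivo = "vivo", vitro = "vitro"), function(side) {
      cols <- paste(side, "aging", strata$compartment, strata$gender, sep = "_")
      dm <- build_deg_matrix(deg[cols], rule = "pvalue")
      mutate(aging_modifiers(dm, mutate(strata, contrast = cols)),
             side = side)
    })
    sets <- imap(c(vivo_tabs, setNames(vitro_tabs,
                                       paste0("vitro_", names(feat)))),
                 function(tab, nm) {
                   tab$gene[!is.na(tab$padj) & tab$padj < 0.05]
                 })
    names(sets) <- c(paste0("vivo_", names(feat)), paste0("vitro_", names(feat)))
    overlaps <- map_dfr(names(feat), function(f) {
      ov <- deg_overlap(sets[paste0(c("vivo_", "vitro_"), f)])$pairwise
      mutate(ov, feature = f)
    })
    list(deg_vivo = deg_vivo, deg_vitro = deg_vitro, retention = retention,
         modifiers = modifiers, overlaps = overlaps)
  })

  report <- list(
    variance = glance(varpart$pca),
    associations = varpart$associations,
    contributing = varpart$contributing,
    deg_counts = imap(deg, function(tab, nm)
      tibble(contrast = nm,
             n_deg = sum(!is.na(tab$padj) & tab$padj < 0.05))) |> bind_rows(),
    composition_tests = deconv$tests,
    gsea = select(enr, -"leading_edge"),
    effect_sizes = list(retention = effects$retention,
                        modifiers = effects$modifiers))
  stage_hashes <- c(
    simulate = hash(list(sim$counts, sim$sc_counts, sim$truth$compositions)),
    de = hash(lapply(deg, as.data.frame)),
    varpart = hash(list(varpart$pca$variance_fraction, varpart$associations)),
    cellref = hash(list(cellref$labels, unclass(cellref$signature))),
    deconv = hash(as.data.frame(deconv$estimates)),
    gsea = hash(as.data.frame(select(enr, -"leading_edge"))),
    effects = hash(list(as.data.frame(effects$retention),
                        as.data.frame(effects$modifiers))))
  manifest <- list(
    config_hash = hash(unclass(config)),
    seed = config$seed,
    stage_hashes = stage_hashes,
    report_hash = hash(rapply(report, as.data.frame, classes = "data.frame",
                              how = "replace")),
    version = as.character(utils::packageVersion("orgretain")),
    timestamp = format(Sys.time(), tz = "UTC"))

  run <- structure(
    list(sim = sim, size_factors = sf, deg = deg, pca = varpart$pca,
         filtered_genes = varpart$filtered_genes,
         associations = varpart$associations,
         contributing = varpart$contributing, cellref = cellref,
         deconv = deconv, gsea = enr, effects = effects, report = report,
         manifest = manifest),
    class = "orgretain_run")
  if (!is.null(out_dir)) {
    run$manifest$files <- write_run(run, out_dir)
  }
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wr_tsv(data.frame(gene_id = rownames(run$sim$counts), run$sim$counts,
                      check.names = FALSE), "counts.tsv"),
    wr_tsv(run$sim$samples, "samples.tsv"),
    wr_tsv(run$deconv$estimates, "compositions.tsv"),
    wr_tsv(as.data.frame(select(run$gsea, -"leading_edge")), "gsea.tsv"),
    wr_tsv(run$effects$retention, "effect_sizes.tsv"))
  mtx_dir <- file.path(out_dir, "sc")
  write_mtx(run$sim$sc_counts, mtx_dir, run$sim$sc_labels)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    rapply(run$report, function(df) df, classes = "data.frame", how = "replace"),
    report_path, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, report_path,
             file.path(mtx_dir, c("matrix.mtx", "features.tsv",
                                  "barcodes.tsv", "celltypes.tsv")))
  md5 <- tools::md5sum(paths)
  tibble(file = basename(paths), path = paths, md5 = unname(md5))
}

#' @export
print.orgretain_run <- function(x, ...) {
  cat("orgretain pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  PC1 variance fraction: ",
      sprintf("%.1f%%", 100 * x$pca$variance_fraction[1]), "\n", sep = "")
  cat("  DEG contrasts: ", length(x$deg), "\n", sep = "")
  cat("  deconvolution R2 (cv 5%): ",
      sprintf("%.3f", x$deconv$validation$r2[2]), "\n", sep = "")
  cat("  report hash: ", x$manifest$report_hash, "\n", sep = "")
  invisible(x)
}

#' Human-readable study summary
#'
#' Collects the run's headline tables: variance fractions, PC-factor
#' associations, highly-contributing-gene counts, DEG counts per contrast,
#' composition tests, enrichment results, and retained-feature effect
#' sizes.
#'
#' @param run `orgretain_run` object.
#' @return Named list of six tibbles, class `orgretain_summary`.
#' @export
report_summary <- function(run) {
  s <- list(
    variance = run$report$variance,
    pc_associations = run$report$associations,
    deg_counts = run$report$deg_counts,
    compositions = run$report$composition_tests,
    enrichment = run$report$gsea,
    effect_sizes = bind_rows(
      mutate(run$effects$retention, analysis = "retention", side = NA),
      mutate(run$effects$modifiers, analysis = "aging_modifiers",
             feature = NA)))
  structure(s, class = "orgretain_summary")
}

#' @export
print.orgretain_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]], n = 12)
    cat("\n")
  }
  invisible(x)
}

#' Score plot for a PCA result
#'
#' @param object `orgretain_pca` object.
#' @param samples Sample sheet tibble.
#' @param x,y Components to plot.
#' @param colour Factor column mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot orgretain_pca
#' @export
autoplot.orgretain_pca <- function(object, samples, x = "PC1", y = "PC2",
                                   colour = "sample_type", ...) {
  df <- left_join(object$scores, samples, by = "sample_id")
  vf <- 100 * object$variance_fraction
  ggplot(df, aes(x = .data[[x]], y = .data[[y]],
                 colour = .data[[colour]])) +
    geom_point(size = 2) +
    labs(x = sprintf("%s (%.1f%%)", x, vf[[x]]),
         y = sprintf("%s (%.1f%%)", y, vf[[y]]), colour = colour) +
    theme_minimal()
}

#' Bar chart of retained-feature effect sizes
#'
#' @param retention Tibble from [feature_retention()].
#' @return A ggplot object.
#' @export
plot_retention <- function(retention) {
  ggplot(retention, aes(x = .data$feature, y = .data$adj_r2,
                        fill = .data$model)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = expression(adjusted ~ R^2), fill = "model") +
    theme_minimal()
}
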