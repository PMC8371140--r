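#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Validation rejects rather than coerces: ragged rows, negative or
#' non-integer counts, and duplicated IDs all raise errors naming the
#' offending row or column. Ribosomal-RNA genes can be dropped on load by ID
#' prefix, mirroring the pre-filtering applied to the study's count data.
#'
#' @param path TSV file path.
#' @param rrna_prefix Optional character vector; genes whose ID starts with
#'   any of these prefixes are removed.
#' @param rrna_genes Optional explicit gene-ID list to remove.
#' @return Integer matrix, genes as rows, samples as columns.
#' @export
read_counts <- function(path, rrna_prefix = NULL, rrna_genes = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", quote = "", comment.char = ""),
    error = function(e) abort(paste0(path, ": ", conditionMessage(e))))
  assert_that(ncol(df) >= 2, paste0(path, ": need a gene column plus >=1 sample"))
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  assert_that(length(dup) == 0,
              paste0(path, ": duplicated gene ID(s): ",
                     paste(unique(dup), collapse = ", ")))
  sample_ids <- colnames(df)[-1]
  dup_s <- sample_ids[duplicated(sample_ids)]
  assert_that(length(dup_s) == 0,
              paste0(path, ": duplicated sample ID(s): ",
                     paste(unique(dup_s), collapse = ", ")))
  mat <- matrix(NA_real_, nrow(df), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    assert_that(length(bad) == 0,
                paste0(path, ": column '", sample_ids[j],
                       "' has non-count value at gene '",
                       gene_ids[bad[1]], "'"))
    mat[, j] <- v
  }
  if (!is.null(rrna_prefix) || !is.null(rrna_genes)) {
    drop <- rep(FALSE, nrow(mat))
    for (p in rrna_prefix) drop <- drop | startsWith(gene_ids, p)
    drop <- drop | gene_ids %in% rrna_genes
    if (any(drop)) {
      message("removed ", sum(drop), " rRNA-tagged gene(s)")
      mat <- mat[!drop, , drop = FALSE]
    }
  }
  storage.mode(mat) <- "integer"
  mat
}

#' @rdname read_counts
#' @param counts Genes x samples matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample sheet
#'
#' @param path TSV path with a `sample_id` column plus factor columns.
#' @param counts Optional count matrix; if given, sample IDs must match its
#'   columns exactly.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character"))
  assert_that("sample_id" %in% colnames(df),
              paste0(path, ": missing 'sample_id' column"))
  assert_that(!anyDuplicated(df$sample_id),
              paste0(path, ": duplicated sample_id"))
  if (!is.null(counts)) {
    assert_that(setequal(df$sample_id, colnames(counts)) &&
                  length(df$sample_id) == ncol(counts),
                paste0(path, ": sample IDs do not match the count matrix"))
  }
  if ("replicate" %in% colnames(df)) df$replicate <- as.integer(df$replicate)
  df
}

#' @rdname read_sample_sheet
#' @param samples Sample-sheet tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Malformed lines (fewer than 3 fields, i.e. an empty member list) are
#' rejected with their line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (member genes per set), ordered
#'   as in the file.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    assert_that(length(fields) >= 3,
                paste0(path, " line ", i,
                       ": GMT line needs name, description and >=1 gene"))
    sets[[fields[1]]] <- fields[-(1:2)]
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-ID vectors.
#' @param descriptions Optional descriptions (recycled "na" otherwise).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(length(sets) > 0 && !is.null(names(sets)),
              "sets must be a non-empty named list")
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    assert_that(length(sets[[i]]) > 0,
                paste0("gene set '", names(sets)[i], "' is empty"))
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a single-cell MatrixMarket triplet
#'
#' The on-disk layout follows the 10x convention: `matrix.mtx` stores genes
#' as rows and cells as columns, with `features.tsv` and `barcodes.tsv`
#' alongside; in memory the package keeps single-cell counts cells-as-rows.
#' An optional `celltypes.tsv` carries per-cell labels.
#'
#' @param dir Directory holding (or to receive) the triplet.
#' @return `read_mtx`: list with `counts` (cells x genes integer matrix) and
#'   `labels` (or `NULL`).
#' @export
read_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  assert_that(file.exists(mtx), paste0("file not found: ", mtx))
  m <- Matrix::readMM(mtx)
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  assert_that(nrow(m) == length(genes),
              paste0(dir, ": features.tsv length does not match matrix rows"))
  assert_that(ncol(m) == length(cells),
              paste0(dir, ": barcodes.tsv length does not match matrix cols"))
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(cells, genes)
  storage.mode(counts) <- "integer"
  lab_path <- file.path(dir, "celltypes.tsv")
  labels <- if (file.exists(lab_path)) readLines(lab_path)
  list(counts = counts, labels = labels)
}

#' @rdname read_mtx
#' @param counts Cells x genes integer matrix.
#' @param labels Optional per-cell labels.
#' @export
write_mtx <- function(counts, dir, labels = NULL) {
  check_count_matrix(counts, "single-cell counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(labels)) {
    assert_that(length(labels) == nrow(counts),
                "labels length must equal the number of cells")
    writeLines(labels, file.path(dir, "celltypes.tsv"))
  }
  invisible(dir)
}

#' Serialize or restore the simulation ground truth as JSON
#'
#' @param truth `orgretain_truth` object.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    gene_ids = truth$gene_ids,
    profiles = truth$profiles,
    marker_sets = truth$marker_sets,
    dispersion = truth$dispersion,
    true_log2fc = truth$true_log2fc,
    true_log2fc_vitro = truth$true_log2fc_vitro,
    affected_gene_sets = truth$affected_gene_sets,
    compositions = truth$compositions)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("profiles", "true_log2fc", "true_log2fc_vitro", "compositions")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.matrix(x[[nm]])
  }
  if (!is.null(x$profiles)) rownames(x$profiles) <- x$gene_ids
  for (nm in c("true_log2fc", "true_log2fc_vitro")) {
    if (!is.null(x[[nm]])) rownames(x[[nm]]) <- x$gene_ids
  }
  x$dispersion <- setNames(as.numeric(x$dispersion), x$gene_ids)
  structure(x, class = "orgretain_truth")
}

#' Load or save a simulation configuration as YAML
#'
#' @param path YAML path.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("variance_targets")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$composition_spec)) {
    raw$composition_spec <- lapply(raw$composition_spec, unlist)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config `orgretain_config` object.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
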