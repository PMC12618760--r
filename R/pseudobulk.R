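#' Aggregate single-cell counts into per-cell-type pseudo-bulk profiles
#'
#' Counts are summed across the member cells of each cell type, each
#' pseudo-bulk column is scaled to counts per million, and the result is
#' `log2(CPM + 1)` transformed. CPM (rather than TPM) is used because summed
#' UMI-style single-cell counts carry no fragment-length bias, so no gene
#' lengths enter; the output scale is tagged `logCPM1` accordingly.
#'
#' @param sc_counts An `expr_matrix` with `scale = "counts"` whose columns
#'   are cells. A `dgCMatrix` with dimnames is also accepted and densified.
#' @param labels Data frame with columns `cell_id`, `cell_type` assigning
#'   every cell a type.
#' @return An `expr_matrix` (genes x cell types) with `scale = "logCPM1"`.
#' @export
pseudobulk_by_celltype <- function(sc_counts, labels) {
  if (inherits(sc_counts, "Matrix")) {
    sc_counts <- expression_matrix(as.matrix(sc_counts), scale = "counts")
  }
  if (!inherits(sc_counts, "expr_matrix") || sc_counts$scale != "counts") {
    stop_stpheno("`sc_counts` must be counts (expr_matrix or sparse matrix).",
                 "stpheno_scale_mismatch")
  }
  if (ncol(sc_counts$values) == 0 || nrow(sc_counts$values) == 0) {
    stop_stpheno("empty count matrix.", "stpheno_bad_input")
  }
  labels <- as_tibble(labels)
  if (!all(c("cell_id", "cell_type") %in% names(labels))) {
    stop_stpheno("`labels` needs columns cell_id and cell_type.",
                 "stpheno_bad_input")
  }
  cells <- sample_ids(sc_counts)
  unlabeled <- setdiff(cells, labels$cell_id)
  if (length(unlabeled)) {
    stop_stpheno(paste0("cells without a label: ", id_list(unlabeled)),
                 "stpheno_unlabeled_cells")
  }
  type_of <- labels$cell_type[match(cells, labels$cell_id)]

  # genes x types sums via grouped column sums
  sums <- t(rowsum(t(sc_counts$values), group = type_of, reorder = TRUE))
  totals <- colSums(sums)
  if (any(totals == 0)) {
    stop_stpheno(paste0("cell type(s) with all-zero counts: ",
                        id_list(colnames(sums)[totals == 0])),
                 "stpheno_zero_sample")
  }
  cpm <- sweep(sums, 2, totals, "/") * 1e6
  expression_matrix(log2(cpm + 1), scale = "logCPM1")
}

#' Merge top-ranked marker genes across cell types
#'
#' Takes each cell type's `n` top-ranked markers (rank 1 = best) and returns
#' their union as the feature gene set for pseudo-bulk correlation. A type
#' with fewer than `n` markers contributes all it has, with a warning.
#'
#' @param markers Data frame with columns `cell_type`, `gene_id`, `rank`.
#' @param n Markers taken per type (default 50).
#' @return A `feature_set` with provenance recording `n` and the type count.
#' @export
merge_top_markers <- function(markers, n = 50) {
  markers <- as_tibble(markers)
  if (!all(c("cell_type", "gene_id", "rank") %in% names(markers))) {
    stop_stpheno("`markers` needs columns cell_type, gene_id, rank.",
                 "stpheno_bad_input")
  }
  if (any(markers$rank < 1)) {
    stop_stpheno("marker ranks must be >= 1.", "stpheno_bad_input")
  }
  counts <- table(markers$cell_type)
  short <- names(counts)[counts < n]
  if (length(short)) {
    warn_stpheno(paste0("cell type(s) with fewer than ", n, " markers use all available: ",
                        id_list(short)),
                 "stpheno_short_marker_list")
  }
  top <- markers |>
    group_by(.data$cell_type) |>
    slice_min(.data$rank, n = n, with_ties = TRUE) |>
    ungroup()
  feature_gene_set(top$gene_id,
                   provenance = sprintf("top %d markers of %d cell types",
                                        n, length(counts)))
}

#' Spearman correlation of bulk samples against reference columns
#'
#' Rank correlation (average ranks for ties) between every bulk sample and
#' every reference column — typically pseudo-bulk cell-type profiles — over
#' the common gene universe `features` \eqn{\cap} bulk \eqn{\cap} reference.
#' Because only ranks enter, the bulk and reference scales need not match;
#' any monotone transform of either side leaves the value unchanged. Vectors
#' that are constant (so that their ranks carry no information) yield
#' undefined (`NA`) cells with a warning.
#'
#' @param bulk,reference `expr_matrix` objects.
#' @param features A `feature_set` (or character vector of gene ids).
#' @param min_overlap Minimum common-universe size (default 3).
#' @return Tibble with columns `sample_id`, `reference_id`, `rho`,
#'   `n_genes_used`.
#' @export
spearman_correlate <- function(bulk, reference, features, min_overlap = 3) {
  stopifnot(inherits(bulk, "expr_matrix"), inherits(reference, "expr_matrix"))
  if (is.character(features)) features <- feature_gene_set(features)
  universe <- intersect(features$genes,
                        intersect(gene_ids(bulk), gene_ids(reference)))
  if (length(universe) < min_overlap) {
    stop_stpheno(sprintf(
      "common gene universe too small: %d genes (features: %d, in bulk: %d, in reference: %d; min_overlap = %d).",
      length(universe),
      length(features$genes),
      length(intersect(features$genes, gene_ids(bulk))),
      length(intersect(features$genes, gene_ids(reference))),
      min_overlap),
      "stpheno_universe_too_small")
  }
  rank_cols <- function(m) apply(m, 2, rank)   # average ranks for ties
  X <- rank_cols(bulk$values[universe, , drop = FALSE])
  Y <- rank_cols(reference$values[universe, , drop = FALSE])
  rho <- cor_matrix(X, Y)
  if (anyNA(rho)) {
    warn_stpheno(sprintf("%d cell(s) undefined (constant vector after ranking).",
                         sum(is.na(rho))),
                 "stpheno_zero_variance")
  }
  tibble(
    sample_id = rep(rownames(rho), times = ncol(rho)),
    reference_id = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho),
    n_genes_used = length(universe)
  )
}

#' Read a sparse single-cell count matrix (MatrixMarket + sidecar id files)
#'
#' @param mtx_path MatrixMarket file of counts (genes x cells).
#' @param genes_path,cells_path One id per line sidecar files.
#' @return An `expr_matrix` with `scale = "counts"`.
#' @export
read_mtx_counts <- function(mtx_path, genes_path, cells_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- trimws(readr::read_lines(genes_path, progress = FALSE))
  cells <- trimws(readr::read_lines(cells_path, progress = FALSE))
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop_stpheno(sprintf("matrix is %d x %d but sidecars list %d genes / %d cells.",
                         nrow(m), ncol(m), length(genes), length(cells)),
                 "stpheno_bad_input")
  }
  dimnames(m) <- list(genes, cells)
  expression_matrix(as.matrix(m), scale = "counts")
}
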