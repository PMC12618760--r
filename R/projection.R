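#' Pearson correlation coefficient
#'
#' Direct evaluation of `Cov(X, Y) / (sd(X) * sd(Y))`, the similarity used
#' for projecting bulk samples onto atlas positions. The population and
#' sample conventions cancel in the ratio, so either gives the same value.
#' A zero-variance vector makes the coefficient undefined: the function
#' returns `NA` with a warning rather than coercing to a number, so an
#' undefined similarity can never leak into a PDI subtraction unnoticed.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation value in `[-1, 1]`, or `NA` when either
#'   vector has zero variance.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 2, 4))
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop_stpheno("`x` and `y` must have equal length.", "stpheno_bad_input")
  }
  if (length(x) < 3) {
    stop_stpheno("correlation needs vectors of length >= 3.", "stpheno_bad_input")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) {
    warn_stpheno("zero-variance vector: correlation undefined (NA).",
                 "stpheno_zero_variance")
    return(NA_real_)
  }
  r <- sum(xc * yc) / sqrt(ssx * ssy)
  min(1, max(-1, r))
}

#' Map bulk samples onto atlas positions by Pearson correlation
#'
#' For every (bulk sample, atlas position) pair, computes the Pearson
#' correlation over the single common gene universe
#' `features` \eqn{\cap} bulk genes \eqn{\cap} atlas genes. Using one shared
#' universe for all pairs (rather than pairwise-complete subsets) keeps the
#' correlations comparable across positions — which the PDI subtraction
#' downstream assumes. Zero-variance vectors yield undefined (`NA`) cells
#' with a warning, never a numeric placeholder.
#'
#' @param bulk An `expr_matrix` with `scale = "log2TPM1"`.
#' @param atlas An `atlas_ref`.
#' @param features A `feature_set` (or character vector of gene ids).
#' @param min_overlap Minimum size of the common gene universe (default 100);
#'   a small universe makes the correlation unstable.
#' @return A `pcc_map`: samples x positions correlation matrix plus the
#'   universe size (`n_genes_used`, identical for every cell) and the
#'   feature-set provenance.
#' @export
map_samples <- function(bulk, atlas, features, min_overlap = 100) {
  if (!inherits(bulk, "expr_matrix")) {
    stop_stpheno("`bulk` must be an expr_matrix.", "stpheno_bad_input")
  }
  if (bulk$scale != "log2TPM1") {
    stop_stpheno(sprintf("bulk must be on the log2TPM1 scale, got '%s' (run counts_to_tpm() + log_transform() first).",
                         bulk$scale),
                 "stpheno_scale_mismatch")
  }
  if (!inherits(atlas, "atlas_ref")) {
    stop_stpheno("`atlas` must be an atlas_ref.", "stpheno_bad_input")
  }
  if (is.character(features)) features <- feature_gene_set(features)

  universe <- intersect(features$genes, intersect(gene_ids(bulk), gene_ids(atlas$expression)))
  if (length(universe) < min_overlap) {
    stop_stpheno(sprintf(
      "common gene universe too small: %d genes (features: %d, in bulk: %d, in atlas: %d; min_overlap = %d).",
      length(universe),
      length(features$genes),
      length(intersect(features$genes, gene_ids(bulk))),
      length(intersect(features$genes, gene_ids(atlas$expression))),
      min_overlap),
      "stpheno_universe_too_small")
  }

  X <- bulk$values[universe, , drop = FALSE]
  Y <- atlas$expression$values[universe, , drop = FALSE]
  pcc <- cor_matrix(X, Y)

  n_undef <- sum(is.na(pcc))
  if (n_undef > 0) {
    warn_stpheno(sprintf("%d of %d cells undefined (zero-variance vectors over the gene universe).",
                         n_undef, length(pcc)),
                 "stpheno_zero_variance")
  }

  structure(
    list(pcc = pcc,
         n_genes_used = length(universe),
         universe = universe,
         features_provenance = features$provenance,
         min_overlap = min_overlap),
    class = "pcc_map"
  )
}

# column-wise Pearson correlations between two matrices over shared rows;
# zero-variance columns give NA cells
cor_matrix <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  ssx <- colSums(Xc^2)
  ssy <- colSums(Yc^2)
  num <- crossprod(Xc, Yc)
  den <- sqrt(outer(ssx, ssy))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  r[den == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  matrix(r, nrow = ncol(X), ncol = ncol(Y),
         dimnames = list(colnames(X), colnames(Y)))
}

#' @export
print.pcc_map <- function(x, ...) {
  cat(sprintf("<pcc_map> %d samples x %d positions, %d feature genes used (provenance: %s)\n",
              nrow(x$pcc), ncol(x$pcc), x$n_genes_used, x$features_provenance))
  if (anyNA(x$pcc)) cat(sprintf("undefined cells: %d\n", sum(is.na(x$pcc))))
  invisible(x)
}

#' Tidy a correlation map into long format
#'
#' @param x A `pcc_map`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `position_id`, `pcc` (`NA` for
#'   undefined cells).
#' @method tidy pcc_map
#' @export
tidy.pcc_map <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$pcc), times = ncol(x$pcc)),
    position_id = rep(colnames(x$pcc), each = nrow(x$pcc)),
    pcc = as.vector(x$pcc)
  )
}

#' @method glance pcc_map
#' @export
glance.pcc_map <- function(x, ...) {
  tibble(n_samples = nrow(x$pcc), n_positions = ncol(x$pcc),
         n_genes_used = x$n_genes_used,
         n_undefined = sum(is.na(x$pcc)),
         features_provenance = x$features_provenance)
}

#' Rank atlas positions for each sample
#'
#' Per sample, positions sorted by correlation, highest first — the
#' top-ranked position(s) are the inferred embryonic location(s). Exact ties
#' are broken lexicographically by position id, and every member of a tie
#' group straddling the cut-off is reported even when that exceeds `k`.
#' Undefined cells are excluded.
#'
#' @param pcc A `pcc_map`.
#' @param k Number of top positions to report per sample (default 1).
#' @return Tibble with columns `sample_id`, `rank`, `position_id`, `pcc`.
#' @export
rank_positions <- function(pcc, k = 1) {
  stopifnot(inherits(pcc, "pcc_map"))
  if (k < 1) stop_stpheno("`k` must be >= 1.", "stpheno_bad_input")
  rows <- lapply(rownames(pcc$pcc), function(s) {
    v <- pcc$pcc[s, ]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop_stpheno(sprintf("sample '%s' has no defined correlations.", s),
                   "stpheno_all_undefined")
    }
    ord <- order(-v, names(v))
    v <- v[ord]
    kk <- min(k, length(v))
    # extend the cut to include the whole tie group at the boundary
    keep <- kk
    while (keep < length(v) && v[keep + 1] == v[kk]) keep <- keep + 1
    tibble(sample_id = s,
           rank = unname(rank(-v[seq_len(keep)], ties.method = "min")),
           position_id = names(v)[seq_len(keep)],
           pcc = unname(v[seq_len(keep)]))
  })
  bind_rows(rows)
}

#' Write a correlation map and its run metadata
#'
#' Writes the samples x positions correlation matrix as TSV, plus a sidecar
#' `<path>.meta.yaml` recording feature provenance, universe size and
#' `min_overlap`.
#'
#' @param pcc A `pcc_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pcc_map <- function(pcc, path) {
  df <- as_tibble(pcc$pcc, rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(features_provenance = pcc$features_provenance,
               n_genes_used = pcc$n_genes_used,
               min_overlap = pcc$min_overlap)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
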