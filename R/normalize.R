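#' Convert raw counts to transcripts per million
#'
#' Per sample: `rate_g = count_g / length_g(kb)`, then
#' `TPM_g = rate_g / sum(rate) * 1e6`, so every column sums to one million.
#' TPM is scale-invariant in sequencing depth: multiplying a sample's counts
#' by a positive constant leaves its TPM column unchanged.
#'
#' @param counts An `expr_matrix` with `scale = "counts"`.
#' @param lengths Gene length table: data frame with columns `gene_id` and
#'   `length_bp` (effective length in base pairs, >= 1), e.g. from
#'   [gene_lengths_from_gtf()].
#' @return An `expr_matrix` with `scale = "TPM"`.
#' @export
counts_to_tpm <- function(counts, lengths) {
  if (!inherits(counts, "expr_matrix") || counts$scale != "counts") {
    stop_stpheno("`counts` must be an expr_matrix on the counts scale.",
                 "stpheno_scale_mismatch")
  }
  lengths <- validate_gene_lengths(lengths)
  genes <- gene_ids(counts)
  idx <- match(genes, lengths$gene_id)
  if (anyNA(idx)) {
    stop_stpheno(paste0("genes without a length: ", id_list(genes[is.na(idx)])),
                 "stpheno_missing_lengths")
  }
  len_kb <- lengths$length_bp[idx] / 1000

  rate <- counts$values / len_kb
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    stop_stpheno(paste0("all-zero sample(s): ", id_list(colnames(rate)[zero])),
                 "stpheno_zero_sample")
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  expression_matrix(tpm, scale = "TPM",
                    sample_annotations = counts$sample_annotations)
}

validate_gene_lengths <- function(lengths) {
  lengths <- as_tibble(lengths)
  if (!all(c("gene_id", "length_bp") %in% names(lengths))) {
    stop_stpheno("gene length table needs columns `gene_id` and `length_bp`.",
                 "stpheno_bad_input")
  }
  lengths$gene_id <- canonicalize_gene_ids(as.character(lengths$gene_id))
  if (anyDuplicated(lengths$gene_id)) {
    stop_stpheno(paste0("duplicate gene ids in length table: ",
                        id_list(unique(lengths$gene_id[duplicated(lengths$gene_id)]))),
                 "stpheno_bad_input")
  }
  if (any(lengths$length_bp < 1)) {
    stop_stpheno("gene lengths must be >= 1 bp.", "stpheno_bad_input")
  }
  lengths
}

#' Log-transform abundance values
#'
#' Elementwise `log2(v + 1)`. `TPM` becomes `log2TPM1` (the working scale for
#' atlas projection); `CPM`-scaled pseudo-bulk columns declared as `TPM` are
#' not accepted — use [pseudobulk_by_celltype()], which produces `logCPM1`
#' directly. The transform is strictly monotone, so within-sample rank order
#' is preserved.
#'
#' @param tpm An `expr_matrix` with `scale = "TPM"`.
#' @return An `expr_matrix` with `scale = "log2TPM1"`.
#' @export
log_transform <- function(tpm) {
  if (!inherits(tpm, "expr_matrix") || tpm$scale != "TPM") {
    stop_stpheno("`tpm` must be an expr_matrix on the TPM scale.",
                 "stpheno_scale_mismatch")
  }
  if (any(tpm$values < 0)) {
    stop_stpheno("negative values cannot be log-transformed.",
                 "stpheno_negative_values")
  }
  expression_matrix(log2(tpm$values + 1), scale = "log2TPM1",
                    sample_annotations = tpm$sample_annotations)
}

#' Derive gene lengths from a GTF annotation
#'
#' Effective length of a gene is defined as the number of bases covered by
#' the union of its exon intervals (overlapping exons merged, strand
#' ignored; coordinates are 1-based inclusive, so a single-base exon has
#' length 1). This is the simplest deterministic length for gene-level
#' count normalization; no fragment-length modelling is attempted.
#'
#' @param gtf_path Path to a GENCODE-dialect GTF file; exon features must
#'   carry `gene_id` attributes.
#' @return A tibble with columns `gene_id` (canonicalized) and `length_bp`.
#'   Genes present in the GTF but lacking exon features are omitted with a
#'   warning.
#' @export
gene_lengths_from_gtf <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  all_genes <- unique(as.character(gr$gene_id))
  exons <- gr[gr$type == "exon"]
  if (!length(exons)) {
    stop_stpheno(sprintf("no exon features found in '%s'.", gtf_path),
                 "stpheno_bad_input")
  }
  # strand-agnostic union per gene: reduce merged exon intervals, sum widths
  key <- paste(as.character(GenomicRanges::seqnames(exons)),
               as.character(exons$gene_id), sep = "\r")
  by_gene <- IRanges::reduce(S4Vectors::splitAsList(IRanges::ranges(exons), key))
  widths <- sum(IRanges::width(by_gene))
  gene_of <- sub("^[^\r]*\r", "", names(widths))
  len <- tapply(as.numeric(widths), gene_of, sum)

  skipped <- setdiff(all_genes, names(len))
  skipped <- skipped[!is.na(skipped)]
  if (length(skipped)) {
    warn_stpheno(paste0("genes without exon features omitted: ", id_list(skipped)),
                 "stpheno_genes_without_exons")
  }
  tibble(gene_id = canonicalize_gene_ids(names(len)),
         length_bp = as.integer(unname(len)))
}

#' Read a gene length table from a TSV
#'
#' @param path Tab-separated table with columns `gene_id` and `length_bp`.
#' @return A validated tibble.
#' @export
read_gene_lengths <- function(path) {
  validate_gene_lengths(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}
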