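#' Expression matrix with a declared value scale
#'
#' The central container of the package: a genes x samples numeric matrix
#' carrying a declared value scale and optional per-sample annotations.
#' The scale tag makes normalization state explicit, so downstream steps can
#' refuse inputs on the wrong scale instead of silently correlating counts
#' against log abundances.
#'
#' Recognised scales:
#' \describe{
#'   \item{`counts`}{raw (or expected) read counts, non-negative.}
#'   \item{`TPM`}{transcripts per million; every column sums to 1e6.}
#'   \item{`log2TPM1`}{`log2(TPM + 1)`, the working scale for atlas projection.}
#'   \item{`logCPM1`}{`log2(CPM + 1)`, the working scale for pseudo-bulk profiles.}
#' }
#'
#' @param values Numeric matrix (genes x samples) with unique rownames (gene
#'   ids) and colnames (sample ids). Gene ids are canonicalized on
#'   construction (see [canonicalize_gene_ids()]).
#' @param scale One of `"counts"`, `"TPM"`, `"log2TPM1"`, `"logCPM1"`.
#' @param sample_annotations Optional data frame with a `sample_id` column
#'   and, typically, `condition`, `timepoint` and `replicate` columns.
#' @return An object of class `expr_matrix`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m, scale = "counts")
expression_matrix <- function(values, scale, sample_annotations = NULL) {
  scale <- match.arg(scale, expr_scales())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_stpheno("`values` must be a numeric matrix (genes x samples).",
                 "stpheno_bad_input")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_stpheno("`values` must carry gene ids as rownames and sample ids as colnames.",
                 "stpheno_bad_input")
  }
  rownames(values) <- canonicalize_gene_ids(rownames(values))
  colnames(values) <- trimws(colnames(values))

  x <- structure(
    list(values = values, scale = scale,
         sample_annotations = prep_annotations(sample_annotations, colnames(values))),
    class = "expr_matrix"
  )
  validate_expr_matrix(x)
}

expr_scales <- function() c("counts", "TPM", "log2TPM1", "logCPM1")

prep_annotations <- function(ann, sample_ids) {
  if (is.null(ann)) return(NULL)
  ann <- as_tibble(ann)
  if (!"sample_id" %in% names(ann)) {
    stop_stpheno("sample annotations must have a `sample_id` column.",
                 "stpheno_bad_input")
  }
  ann$sample_id <- trimws(as.character(ann$sample_id))
  missing <- setdiff(sample_ids, ann$sample_id)
  if (length(missing)) {
    stop_stpheno(paste0("samples without annotations: ", id_list(missing)),
                 "stpheno_bad_input")
  }
  ann[match(sample_ids, ann$sample_id), , drop = FALSE]
}

validate_expr_matrix <- function(x) {
  v <- x$values
  if (anyDuplicated(rownames(v))) {
    stop_stpheno(paste0("duplicate gene ids after canonicalization: ",
                        id_list(unique(rownames(v)[duplicated(rownames(v))]))),
                 "stpheno_duplicate_genes")
  }
  if (anyDuplicated(colnames(v))) {
    stop_stpheno(paste0("duplicate sample ids: ",
                        id_list(unique(colnames(v)[duplicated(colnames(v))]))),
                 "stpheno_duplicate_samples")
  }
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop_stpheno(sprintf("missing value at gene '%s', sample '%s'.",
                         rownames(v)[bad[1]], colnames(v)[bad[2]]),
                 "stpheno_missing_values")
  }
  if (x$scale %in% c("counts", "TPM") && any(v < 0)) {
    stop_stpheno(sprintf("scale '%s' requires non-negative values.", x$scale),
                 "stpheno_negative_values")
  }
  if (x$scale == "TPM") {
    cs <- colSums(v)
    off <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(off)) {
      stop_stpheno(paste0("TPM columns must sum to 1e6; offending samples: ",
                          id_list(colnames(v)[off])),
                   "stpheno_tpm_sum")
    }
  }
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$sample_annotations)) {
    cat("sample annotations: ",
        paste(setdiff(names(x$sample_annotations), "sample_id"), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value` (and the
#'   sample annotations joined in when present).
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  out <- tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  if (!is.null(x$sample_annotations)) {
    out <- left_join(out, x$sample_annotations, by = "sample_id")
  }
  out
}

#' @method glance expr_matrix
#' @export
glance.expr_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$values), n_samples = ncol(x$values), scale = x$scale)
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table (genes as rows, first column gene ids,
#' header row of sample ids) into an [expression_matrix()]. Gene ids are
#' canonicalized; duplicate gene rows are collapsed by summation when
#' `scale = "counts"` (summing is only meaningful pre-normalization) and
#' rejected on any other scale. Missing or non-numeric cells are errors that
#' name the offending row and column — the correlations downstream assume
#' complete vectors, so nothing is imputed.
#'
#' @param path Path to a delimited text file. `.csv` is read as
#'   comma-separated, anything else as tab-separated.
#' @param scale Declared value scale of the table (see [expression_matrix()]).
#' @param sample_annotations Optional annotation table passed through.
#' @return An `expr_matrix`.
#' @export
read_expression_table <- function(path, scale, sample_annotations = NULL) {
  scale <- match.arg(scale, expr_scales())
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # check the raw header before readr repairs duplicated names
  header <- strsplit(readr::read_lines(path, n_max = 1, progress = FALSE), delim, fixed = TRUE)[[1]]
  header <- trimws(header)[-1]
  if (anyDuplicated(header)) {
    stop_stpheno(paste0("duplicate sample ids in header: ",
                        id_list(unique(header[duplicated(header)]))),
                 "stpheno_duplicate_samples")
  }
  raw <- suppressMessages(
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE))
  if (ncol(raw) < 2) {
    stop_stpheno("expression table needs a gene id column plus at least one sample column.",
                 "stpheno_bad_input")
  }
  sample_names <- trimws(names(raw)[-1])
  if (anyDuplicated(sample_names)) {
    stop_stpheno(paste0("duplicate sample ids in header: ",
                        id_list(unique(sample_names[duplicated(sample_names)]))),
                 "stpheno_duplicate_samples")
  }
  genes <- canonicalize_gene_ids(raw[[1]])

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_names),
                 dimnames = list(NULL, sample_names))
  for (j in seq_along(sample_names)) {
    col <- trimws(raw[[j + 1]])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | is.na(col) | col == "")
    if (length(bad)) {
      stop_stpheno(sprintf("non-numeric or missing cell at gene '%s', sample '%s'.",
                           genes[bad[1]], sample_names[j]),
                   "stpheno_missing_values")
    }
    vals[, j] <- num
  }

  if (anyDuplicated(genes)) {
    if (scale == "counts") {
      vals <- rowsum(vals, group = genes, reorder = FALSE)
      genes <- rownames(vals)
    } else {
      stop_stpheno(paste0("duplicate gene ids on scale '", scale, "' (only counts collapse by sum): ",
                          id_list(unique(genes[duplicated(genes)]))),
                   "stpheno_duplicate_genes")
    }
  }
  rownames(vals) <- genes
  expression_matrix(vals, scale = scale, sample_annotations = sample_annotations)
}

#' Write an expression matrix to a delimited table
#'
#' Inverse of [read_expression_table()]: `read_expression_table(write_expression_table(x))`
#' round-trips values and identifiers.
#'
#' @param x An `expr_matrix`.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  df <- as_tibble(x$values, rownames = "gene_id")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
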