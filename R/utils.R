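# Internal helpers shared across modules.

#' Canonicalize gene identifiers
#'
#' Strips surrounding whitespace and the trailing version suffix (".N") from
#' Ensembl-style identifiers (e.g. `"ENSMUSG00000012345.7"` becomes
#' `"ENSMUSG00000012345"`). Identifiers that do not look like versioned
#' Ensembl ids are returned unchanged apart from whitespace trimming, so
#' gene symbols containing dots are left alone. The operation is idempotent.
#'
#' All joins across bulk, atlas and feature-set gene ids in this package are
#' performed on canonicalized identifiers; no symbol-to-Ensembl translation
#' is ever attempted.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of the same length.
#' @export
#' @examples
#' canonicalize_gene_ids(c(" ENSMUSG00000001.5", "Sox2", "ENSG00000101.12"))
canonicalize_gene_ids <- function(ids) {
  ids <- trimws(ids)
  sub("^(ENS[A-Z]*[0-9]{6,})\\.[0-9]+$", "\\1", ids)
}

# stop with a classed condition so callers/tests can target specific failures
stop_stpheno <- function(msg, class) {
  abort(msg, class = c(class, "stpheno_error"))
}

warn_stpheno <- function(msg, class) {
  warn(msg, class = c(class, "stpheno_warning"))
}

# comma list capped for readable error messages
id_list <- function(ids, max = 10L) {
  ids <- as.character(ids)
  if (length(ids) > max) {
    paste0(paste(head(ids, max), collapse = ", "), ", ... (", length(ids), " total)")
  } else {
    paste(ids, collapse = ", ")
  }
}
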