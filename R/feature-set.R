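#' Feature gene set
#'
#' The restricted, spatially informative gene list over which all projection
#' correlations are computed. Restricting to genes with known domain-specific
#' expression (spatial-domain DEGs, or merged single-cell markers) is what
#' makes the correlation a spatial signal rather than a global
#' library-similarity measure.
#'
#' @param genes Character vector of gene ids; canonicalized and de-duplicated.
#' @param provenance Free-text label recording where the list came from.
#' @return An object of class `feature_set`.
#' @export
feature_gene_set <- function(genes, provenance = "unspecified") {
  genes <- unique(canonicalize_gene_ids(as.character(genes)))
  genes <- genes[genes != ""]
  if (!length(genes)) {
    stop_stpheno("feature gene set is empty.", "stpheno_empty_feature_set")
  }
  structure(list(genes = genes, provenance = provenance), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes (provenance: %s)\n",
              length(x$genes), x$provenance))
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$genes)

#' Load a feature gene set from a plain-text list
#'
#' One gene id per line; blank lines and lines starting with `#` are ignored;
#' duplicates are collapsed. Provenance is recorded as the file name.
#'
#' @param path Path to the gene list.
#' @return A `feature_set`.
#' @export
load_feature_set <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) {
    stop_stpheno(sprintf("no gene ids found in '%s' after dropping blanks and comments.", path),
                 "stpheno_empty_feature_set")
  }
  feature_gene_set(lines, provenance = basename(path))
}
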