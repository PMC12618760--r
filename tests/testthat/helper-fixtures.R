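# In-code fixtures shared across test files. Everything is generated at test
# time; nothing is read from disk except files these helpers write to
# tempdir().

# tiny deterministic atlas: 4 positions, n_genes genes, distinct profiles
tiny_atlas <- function(n_genes = 12) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  set.seed(7)
  vals <- matrix(round(abs(rnorm(n_genes * 4, mean = 4)), 3), nrow = n_genes,
                 dimnames = list(genes, c("P1", "P2", "P3", "P4")))
  positions <- tibble::tibble(
    position_id = c("P1", "P2", "P3", "P4"),
    stage = "E7.5",
    section_index = c(1L, 1L, 2L, 2L),
    domain_code = c("A", "P", "MA", "MP"),
    layout_row = c(1L, 1L, 2L, 2L),
    layout_col = c(1L, 2L, 1L, 2L)
  )
  atlas_reference(expression_matrix(vals, scale = "log2TPM1"), positions)
}

# bulk matrix whose columns are copies of given atlas profiles (+ shift)
bulk_from_atlas <- function(atlas, sample_spec, ann = NULL) {
  vals <- sapply(sample_spec, function(p) atlas$expression$values[, p])
  colnames(vals) <- names(sample_spec)
  expression_matrix(vals, scale = "log2TPM1", sample_annotations = ann)
}

# reflect a profile about its own gene-wise mean: correlation with the
# original is exactly -1
reflect_about_mean <- function(v) 2 * mean(v) - v

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
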