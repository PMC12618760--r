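#' Spatially resolved reference atlas
#'
#' Binds a reference [expression_matrix()] on the `log2TPM1` scale to
#' per-position metadata describing where each profile sits in the embryo:
#' developmental stage, section index along the proximal-to-distal axis,
#' anatomical domain code, and the (row, column) cell it occupies in a
#' corn-plot style layout grid.
#'
#' Domain codes are validated against a per-stage controlled vocabulary.
#' For stage `"E7.5"` the built-in vocabulary is
#' `A, P, L1, R1, L2, R2, EA, EP, MA, MP` (anterior/posterior/lateral
#' epiblast-ectoderm, anterior/posterior endoderm, anterior mesoderm,
#' posterior mesoderm/primitive streak). For other stages the vocabulary is
#' taken from `vocabulary` when supplied, otherwise from the observed codes.
#'
#' @param expression An `expr_matrix` with `scale = "log2TPM1"` whose sample
#'   ids are the position ids.
#' @param positions Data frame with columns `position_id`, `stage`,
#'   `section_index`, `domain_code`, `layout_row`, `layout_col`.
#' @param vocabulary Optional named list of character vectors, one per stage,
#'   giving the allowed domain codes.
#' @return An object of class `atlas_ref`.
#' @export
atlas_reference <- function(expression, positions, vocabulary = NULL) {
  if (!inherits(expression, "expr_matrix")) {
    stop_stpheno("`expression` must be an expr_matrix.", "stpheno_bad_input")
  }
  if (expression$scale != "log2TPM1") {
    stop_stpheno(sprintf("atlas expression must be on the log2TPM1 scale, got '%s'.",
                         expression$scale),
                 "stpheno_scale_mismatch")
  }
  positions <- as_tibble(positions)
  needed <- c("position_id", "stage", "section_index", "domain_code",
              "layout_row", "layout_col")
  missing_cols <- setdiff(needed, names(positions))
  if (length(missing_cols)) {
    stop_stpheno(paste0("position metadata lacks columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "stpheno_bad_input")
  }
  positions$position_id <- trimws(as.character(positions$position_id))

  expr_ids <- sample_ids(expression)
  orphan_meta <- setdiff(positions$position_id, expr_ids)
  orphan_expr <- setdiff(expr_ids, positions$position_id)
  if (length(orphan_meta) || length(orphan_expr)) {
    stop_stpheno(paste0(
      "position ids and expression columns disagree; ",
      "in metadata only: [", id_list(orphan_meta), "]; ",
      "in expression only: [", id_list(orphan_expr), "]"),
      "stpheno_position_mismatch")
  }
  if (anyDuplicated(positions$position_id)) {
    stop_stpheno(paste0("duplicate position ids: ",
                        id_list(unique(positions$position_id[duplicated(positions$position_id)]))),
                 "stpheno_bad_input")
  }
  positions <- positions[match(expr_ids, positions$position_id), , drop = FALSE]

  cell_key <- paste(positions$stage, positions$layout_row, positions$layout_col, sep = "\r")
  if (anyDuplicated(cell_key)) {
    dup <- positions$position_id[cell_key %in% cell_key[duplicated(cell_key)]]
    stop_stpheno(paste0("positions of the same stage share a layout cell: ",
                        id_list(dup)),
                 "stpheno_layout_clash")
  }

  vocab <- stage_vocabulary(positions, vocabulary)
  for (st in names(vocab)) {
    codes <- positions$domain_code[positions$stage == st]
    bad <- setdiff(unique(codes), vocab[[st]])
    if (length(bad)) {
      stop_stpheno(sprintf("stage %s uses domain codes outside its vocabulary: %s",
                           st, id_list(bad)),
                   "stpheno_bad_domain_code")
    }
  }

  structure(list(expression = expression, positions = positions,
                 vocabulary = vocab),
            class = "atlas_ref")
}

builtin_vocabulary <- function() {
  list(`E7.5` = c("A", "P", "L1", "R1", "L2", "R2", "EA", "EP", "MA", "MP"))
}

stage_vocabulary <- function(positions, vocabulary) {
  stages <- unique(positions$stage)
  vocab <- vector("list", length(stages))
  names(vocab) <- stages
  builtin <- builtin_vocabulary()
  for (st in stages) {
    vocab[[st]] <- vocabulary[[st]] %||% builtin[[st]] %||%
      sort(unique(positions$domain_code[positions$stage == st]))
  }
  vocab
}

#' @export
print.atlas_ref <- function(x, ...) {
  cat(sprintf("<atlas_ref> %d positions, %d genes, stages: %s\n",
              nrow(x$positions), nrow(x$expression$values),
              paste(unique(x$positions$stage), collapse = ", ")))
  invisible(x)
}

#' @method tidy atlas_ref
#' @export
tidy.atlas_ref <- function(x, ...) as_tibble(x$positions)

#' @method glance atlas_ref
#' @export
glance.atlas_ref <- function(x, ...) {
  tibble(n_positions = nrow(x$positions),
         n_genes = nrow(x$expression$values),
         n_stages = length(unique(x$positions$stage)))
}

#' Read a reference atlas from expression and metadata tables
#'
#' @param expr_path Delimited expression table on the `log2TPM1` scale
#'   (genes as rows, position ids as columns).
#' @param meta_path Delimited metadata table with columns `position_id`,
#'   `stage`, `section_index`, `domain_code`, `layout_row`, `layout_col`.
#' @param vocabulary Optional per-stage domain-code vocabulary, see
#'   [atlas_reference()].
#' @return An `atlas_ref`.
#' @export
read_atlas <- function(expr_path, meta_path, vocabulary = NULL) {
  expression <- read_expression_table(expr_path, scale = "log2TPM1")
  delim <- if (grepl("\\.csv$", meta_path, ignore.case = TRUE)) "," else "\t"
  meta <- readr::read_delim(meta_path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  atlas_reference(expression, meta, vocabulary = vocabulary)
}

#' Write an atlas to expression and metadata tables
#'
#' @param atlas An `atlas_ref`.
#' @param expr_path,meta_path Output paths (tab-separated).
#' @return `expr_path`, invisibly.
#' @export
write_atlas <- function(atlas, expr_path, meta_path) {
  write_expression_table(atlas$expression, expr_path)
  readr::write_tsv(atlas$positions, meta_path, progress = FALSE)
  invisible(expr_path)
}
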