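#' Run the full projection pipeline from a configuration
#'
#' Executes normalization (when the bulk table is counts), atlas projection,
#' position ranking, PDI computation and rendering, and writes all results
#' plus a run log to `out_dir`. Reruns with an identical configuration
#' produce byte-identical tables.
#'
#' The configuration is a YAML file or named list with fields:
#' \describe{
#'   \item{`bulk`}{path to the bulk expression table (or an `expr_matrix`).}
#'   \item{`bulk_scale`}{its scale: `counts`, `TPM` or `log2TPM1`.}
#'   \item{`gene_lengths` / `gtf`}{for `counts` input, a length TSV or a
#'     GTF to derive exon-union lengths from (exactly one required).}
#'   \item{`atlas_expression`, `atlas_metadata`}{atlas paths (or `atlas` as
#'     an `atlas_ref`).}
#'   \item{`features`}{path to the feature gene list (or a `feature_set`).}
#'   \item{`groups`}{path to the sample table (`sample_id`, `condition`,
#'     `timepoint`, `replicate`) or a data frame.}
#'   \item{`pairs`}{list of `[case, control]` condition pairs.}
#'   \item{`min_overlap`, `top_k`, `aggregation`, `render`}{optional tuning;
#'     defaults 100, 3, `"mean_pcc"`, `TRUE`.}
#' }
#'
#' @param config Path to a YAML configuration or a named list.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly. Side effects: `pcc.tsv` (+
#'   `pcc.tsv.meta.yaml`), `rankings.tsv`, `pdi.tsv`, one `pdi_<label>.svg`
#'   per comparison (when `render`), and `run.log`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    stop_stpheno("`config` must be a YAML path or a named list.", "stpheno_bad_input")
  }
  # validate the contract before touching any data
  if (is.null(config$features)) {
    stop_stpheno("config stage [validate]: no feature gene set supplied.",
                 "stpheno_bad_config")
  }
  if (is.null(config$bulk)) {
    stop_stpheno("config stage [validate]: no bulk expression table supplied.",
                 "stpheno_bad_config")
  }
  if (is.null(config$atlas) && (is.null(config$atlas_expression) || is.null(config$atlas_metadata))) {
    stop_stpheno("config stage [validate]: supply `atlas` or both `atlas_expression` and `atlas_metadata`.",
                 "stpheno_bad_config")
  }
  if (is.null(config$groups) || is.null(config$pairs)) {
    stop_stpheno("config stage [validate]: `groups` and `pairs` are required for PDI.",
                 "stpheno_bad_config")
  }
  min_overlap <- config$min_overlap %||% 100
  top_k <- config$top_k %||% 3
  aggregation <- config$aggregation %||% "mean_pcc"
  render <- config$render %||% TRUE

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("stpheno %s on R %s.%s", as.character(utils::packageVersion("stpheno")),
            R.version$major, R.version$minor),
    sprintf("aggregation=%s min_overlap=%d top_k=%d", aggregation, min_overlap, top_k))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("stage [%s]: %s", stage, conditionMessage(e)),
              class = "stpheno_stage_error", parent = e)
      }),
      warning = function(w) {
        note("warning in stage [%s]: %s", stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  bulk <- run_stage("normalize", {
    b <- config$bulk
    scale <- config$bulk_scale %||% "log2TPM1"
    if (is.character(b)) b <- read_expression_table(b, scale = scale)
    if (b$scale == "counts") {
      lengths <- if (!is.null(config$gene_lengths)) {
        read_gene_lengths(config$gene_lengths)
      } else if (!is.null(config$gtf)) {
        gene_lengths_from_gtf(config$gtf)
      } else {
        stop_stpheno("counts input needs `gene_lengths` or `gtf`.", "stpheno_bad_config")
      }
      b <- log_transform(counts_to_tpm(b, lengths))
      note("normalized counts -> TPM -> log2(TPM+1)")
    } else if (b$scale == "TPM") {
      b <- log_transform(b)
      note("log-transformed declared TPM input")
    }
    b
  })

  atlas <- run_stage("atlas", {
    if (!is.null(config$atlas)) config$atlas
    else read_atlas(config$atlas_expression, config$atlas_metadata)
  })
  features <- run_stage("features", {
    f <- config$features
    if (is.character(f) && length(f) == 1) f <- load_feature_set(f)
    if (is.character(f)) f <- feature_gene_set(f, provenance = "inline config list")
    f
  })
  groups <- run_stage("groups", {
    g <- config$groups
    if (is.character(g)) g <- readr::read_tsv(g, show_col_types = FALSE, progress = FALSE)
    as_tibble(g)
  })
  pairs <- lapply(config$pairs, function(p) c(p[[1]], p[[2]]))

  pcc <- run_stage("map", map_samples(bulk, atlas, features, min_overlap = min_overlap))
  note("gene universe: %d genes (feature provenance: %s)",
       pcc$n_genes_used, pcc$features_provenance)
  rankings <- run_stage("rank", rank_positions(pcc, k = top_k))
  pdi <- run_stage("pdi", compute_pdi(pcc, groups, pairs, aggregation = aggregation,
                                      bulk = bulk, atlas = atlas, features = features))

  run_stage("write", {
    write_pcc_map(pcc, file.path(out_dir, "pcc.tsv"))
    readr::write_tsv(rankings, file.path(out_dir, "rankings.tsv"), progress = FALSE)
    write_pdi_map(pdi, file.path(out_dir, "pdi.tsv"))
  })
  if (isTRUE(render)) {
    run_stage("render", {
      for (label in colnames(pdi$pdi)) {
        render_spatial_map(pdi$pdi[, label], atlas,
                           file.path(out_dir, paste0("pdi_", label, ".svg")),
                           mode = "pdi", title = label)
      }
    })
    note("rendered %d PDI map(s)", ncol(pdi$pdi))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
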