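#' Phenotypic difference index per spatial position
#'
#' The phenotypic difference index (PDI) quantifies how a perturbation
#' changes a cell population's transcriptional resemblance to each position
#' of the embryo atlas: per position, `PDI = PCC_case - PCC_control`. With
#' correlations in `[-1, 1]` the index lies in `[-2, 2]`; 0 means no change
#' in association strength, positive values an enhanced resemblance in the
#' case group, negative values an attenuation. Swapping case and control
#' negates every value.
#'
#' Comparisons are matched within timepoint labels (case D3 vs control D3,
#' and so on), one comparison column per (pair, timepoint).
#'
#' Two aggregation modes are provided because group-level correlation can be
#' defined two ways:
#' \describe{
#'   \item{`mean_pcc` (default)}{per position, mean of the case replicates'
#'     correlations minus mean of the control replicates'. Undefined cells
#'     are excluded from the means, with the exclusion count recorded.}
#'   \item{`pooled_profile`}{average the `log2(TPM+1)` profiles within each
#'     group first, then compute one correlation per group and subtract.
#'     Requires `bulk`, `atlas` and `features` so the group profiles can be
#'     re-mapped.}
#' }
#'
#' @param pcc A `pcc_map` from [map_samples()].
#' @param groups Data frame assigning every sample a group: columns
#'   `sample_id`, `condition`, `timepoint` (a `replicate` column is allowed
#'   and ignored).
#' @param pairs List of `c(case, control)` condition pairs, e.g.
#'   `list(c("KO", "WT"))`.
#' @param aggregation `"mean_pcc"` or `"pooled_profile"`.
#' @param bulk,atlas,features Only for `aggregation = "pooled_profile"`: the
#'   inputs that produced `pcc`.
#' @return A `pdi_map`: positions x comparisons matrix with per-comparison
#'   bookkeeping (group sizes, excluded cells).
#' @export
compute_pdi <- function(pcc, groups, pairs,
                        aggregation = c("mean_pcc", "pooled_profile"),
                        bulk = NULL, atlas = NULL, features = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(pcc, "pcc_map"))
  groups <- as_tibble(groups)
  if (!all(c("sample_id", "condition", "timepoint") %in% names(groups))) {
    stop_stpheno("`groups` needs columns sample_id, condition, timepoint.",
                 "stpheno_bad_input")
  }
  if (is.character(pairs)) pairs <- list(pairs)
  samples <- rownames(pcc$pcc)
  unassigned <- setdiff(samples, groups$sample_id)
  if (length(unassigned)) {
    stop_stpheno(paste0("samples without group assignment: ", id_list(unassigned)),
                 "stpheno_bad_input")
  }
  groups <- groups[groups$sample_id %in% samples, , drop = FALSE]

  comparisons <- list()
  columns <- list()
  for (pair in pairs) {
    case <- pair[[1]]; control <- pair[[2]]
    for (side in c(case, control)) {
      if (!side %in% groups$condition) {
        stop_stpheno(sprintf("condition '%s' has no samples.", side),
                     "stpheno_empty_group")
      }
    }
    tps_case <- unique(groups$timepoint[groups$condition == case])
    tps_ctrl <- unique(groups$timepoint[groups$condition == control])
    skipped <- union(setdiff(tps_case, tps_ctrl), setdiff(tps_ctrl, tps_case))
    if (length(skipped)) {
      warn_stpheno(sprintf("timepoint(s) present in only one of %s/%s skipped: %s",
                           case, control, id_list(skipped)),
                   "stpheno_skipped_timepoint")
    }
    for (tp in sort(intersect(tps_case, tps_ctrl))) {
      ids_case <- groups$sample_id[groups$condition == case & groups$timepoint == tp]
      ids_ctrl <- groups$sample_id[groups$condition == control & groups$timepoint == tp]
      label <- paste0(case, "_", tp, "_vs_", control, "_", tp)
      res <- pdi_column(pcc, ids_case, ids_ctrl, aggregation,
                        bulk = bulk, atlas = atlas, features = features)
      columns[[label]] <- res$pdi
      comparisons[[label]] <- tibble(
        label = label, case = case, control = control, timepoint = tp,
        n_case = length(ids_case), n_control = length(ids_ctrl),
        n_excluded = res$n_excluded)
    }
  }
  if (!length(columns)) {
    stop_stpheno("no comparison had a timepoint shared by both conditions.",
                 "stpheno_empty_group")
  }
  pdi <- do.call(cbind, columns)
  rownames(pdi) <- colnames(pcc$pcc)
  structure(
    list(pdi = pdi,
         comparisons = bind_rows(comparisons),
         aggregation = aggregation),
    class = "pdi_map"
  )
}

pdi_column <- function(pcc, ids_case, ids_ctrl, aggregation, bulk, atlas, features) {
  if (aggregation == "mean_pcc") {
    m_case <- pcc$pcc[ids_case, , drop = FALSE]
    m_ctrl <- pcc$pcc[ids_ctrl, , drop = FALSE]
    n_excluded <- sum(is.na(m_case)) + sum(is.na(m_ctrl))
    if (n_excluded > 0) {
      inform(sprintf("excluded %d undefined correlation cell(s) from group means.",
                     n_excluded))
    }
    pdi <- colMeans(m_case, na.rm = TRUE) - colMeans(m_ctrl, na.rm = TRUE)
    list(pdi = pdi, n_excluded = n_excluded)
  } else {
    if (is.null(bulk) || is.null(atlas) || is.null(features)) {
      stop_stpheno("pooled_profile aggregation needs `bulk`, `atlas` and `features`.",
                   "stpheno_bad_input")
    }
    pool <- function(ids) rowMeans(bulk$values[, ids, drop = FALSE])
    prof <- cbind(case = pool(ids_case), control = pool(ids_ctrl))
    pooled <- expression_matrix(prof, scale = "log2TPM1")
    pm <- map_samples(pooled, atlas, features, min_overlap = pcc$min_overlap)
    list(pdi = pm$pcc["case", ] - pm$pcc["control", ], n_excluded = 0L)
  }
}

#' @export
print.pdi_map <- function(x, ...) {
  cat(sprintf("<pdi_map> %d positions x %d comparisons (aggregation: %s)\n",
              nrow(x$pdi), ncol(x$pdi), x$aggregation))
  print(x$comparisons)
  invisible(x)
}

#' Tidy a PDI map into long format
#'
#' @param x A `pdi_map`.
#' @param ... Unused.
#' @return Tibble with columns `position_id`, `comparison`, `pdi` plus the
#'   per-comparison bookkeeping columns.
#' @method tidy pdi_map
#' @export
tidy.pdi_map <- function(x, ...) {
  out <- tibble(
    position_id = rep(rownames(x$pdi), times = ncol(x$pdi)),
    comparison = rep(colnames(x$pdi), each = nrow(x$pdi)),
    pdi = as.vector(x$pdi)
  )
  left_join(out, x$comparisons, by = c(comparison = "label"))
}

#' @method glance pdi_map
#' @export
glance.pdi_map <- function(x, ...) {
  tibble(n_positions = nrow(x$pdi), n_comparisons = ncol(x$pdi),
         aggregation = x$aggregation,
         max_abs_pdi = max(abs(x$pdi), na.rm = TRUE))
}

#' Classify PDI values as enhanced, attenuated or unchanged
#'
#' Positive index values signify an enhancement of the case group's
#' transcriptional concordance with a position relative to control; negative
#' values an attenuation. The boundary sits at 0; a dead-band `epsilon` may
#' be supplied to label small differences `unchanged`.
#'
#' @param pdimap A `pdi_map`.
#' @param epsilon Non-negative half-width of the `unchanged` band (default 0).
#' @return [tidy.pdi_map()] output plus a `change` factor with levels
#'   `attenuated`, `unchanged`, `enhanced`.
#' @export
classify_pdi <- function(pdimap, epsilon = 0) {
  stopifnot(inherits(pdimap, "pdi_map"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0) {
    stop_stpheno("`epsilon` must be a single non-negative number.",
                 "stpheno_bad_input")
  }
  out <- tidy(pdimap)
  out$change <- factor(
    ifelse(out$pdi > epsilon, "enhanced",
           ifelse(out$pdi < -epsilon, "attenuated", "unchanged")),
    levels = c("attenuated", "unchanged", "enhanced"))
  out
}

#' Write a PDI map as TSV
#'
#' Rows are position ids, one column per comparison label.
#'
#' @param pdimap A `pdi_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdi_map <- function(pdimap, path) {
  df <- as_tibble(pdimap$pdi, rownames = "position_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
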