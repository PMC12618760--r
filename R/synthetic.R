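#' Simulate a spatial reference atlas with known marker structure
#'
#' Builds a ground-truthed atlas on the `log2TPM1` working scale: every
#' position shares a common non-negative baseline expression vector and has
#' a disjoint block of `markers_per_position` marker genes elevated by
#' `effect_size` log2-units — the synthetic analogue of domain-specific
#' marker signatures on a staged corn-plot layout. Positions are assigned
#' section indices and layout cells deterministically on a near-square grid
#' per stage.
#'
#' @param n_stages Number of stages (panels), labelled `S1`, `S2`, ...
#' @param positions_per_stage Positions within each stage.
#' @param n_genes Total genes; must be >= total positions x
#'   `markers_per_position` so marker blocks stay disjoint.
#' @param markers_per_position Marker genes elevated per position.
#' @param effect_size Elevation of a marker over baseline, in log2-units
#'   (default 2, i.e. four-fold).
#' @param baseline_sd Standard deviation of the baseline expression draw
#'   (default 1).
#' @param seed Integer seed; identical seeds give identical atlases.
#' @return A list with elements `atlas` (an `atlas_ref`), `signatures`
#'   (genes x positions matrix equal to the atlas expression), and
#'   `marker_genes` (a `feature_set` of all marker genes, the synthetic
#'   analogue of the spatial-domain DEG list).
#' @export
simulate_atlas <- function(n_stages = 1, positions_per_stage = 10,
                           n_genes = 2000, markers_per_position = 50,
                           effect_size = 2, baseline_sd = 1, seed = 1) {
  n_positions <- n_stages * positions_per_stage
  if (markers_per_position * n_positions > n_genes) {
    stop_stpheno(sprintf(
      "marker budget exceeds gene count: %d positions x %d markers > %d genes.",
      n_positions, markers_per_position, n_genes),
      "stpheno_bad_input")
  }
  if (effect_size <= 0) {
    stop_stpheno("`effect_size` must be > 0.", "stpheno_bad_input")
  }
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    baseline <- pmax(0, rnorm(n_genes, mean = 4, sd = baseline_sd))

    stage <- rep(sprintf("S%d", seq_len(n_stages)), each = positions_per_stage)
    within <- rep(seq_len(positions_per_stage), times = n_stages)
    position_id <- sprintf("%s_P%02d", stage, within)

    sig <- matrix(rep(baseline, n_positions), nrow = n_genes,
                  dimnames = list(genes, position_id))
    for (i in seq_len(n_positions)) {
      block <- ((i - 1) * markers_per_position + 1):(i * markers_per_position)
      sig[block, i] <- sig[block, i] + effect_size
    }

    ncol_grid <- ceiling(sqrt(positions_per_stage))
    layout_row <- (within - 1) %/% ncol_grid + 1L
    layout_col <- (within - 1) %% ncol_grid + 1L
    positions <- tibble(
      position_id = position_id,
      stage = stage,
      section_index = layout_row,
      domain_code = sprintf("D%02d", within),
      layout_row = layout_row,
      layout_col = layout_col
    )
    atlas <- atlas_reference(
      expression_matrix(sig, scale = "log2TPM1"),
      positions
    )
    marker_ids <- genes[seq_len(markers_per_position * n_positions)]
    list(atlas = atlas,
         signatures = sig,
         marker_genes = feature_gene_set(marker_ids, provenance = "synthetic position markers"))
  })
}

#' Simulate bulk replicates drawn from atlas position signatures
#'
#' Each replicate is a mixture of its origin position's signature and,
#' optionally, a perturbation target's signature —
#' `(1 - w) * signature(origin) + w * signature(target)` — plus Gaussian
#' noise on the log scale, clipped at zero. `w = 0` reproduces the origin
#' signature family exactly; `w > 0` emulates a perturbed condition whose
#' transcriptome drifts toward an alternative spatial domain (the knockout
#' fate-shift scenario).
#'
#' @param signatures Genes x positions signature matrix from
#'   [simulate_atlas()].
#' @param design Data frame with one row per (group x origin) cell: columns
#'   `origin` (position id), `condition`, `timepoint`, `n_reps`,
#'   `perturb_target` (position id or `NA`), `w` (mixing weight in `[0, 1]`).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (log2-units, default 0.5).
#' @param seed Integer seed.
#' @return A list with `bulk` (an `expr_matrix` on `log2TPM1` with condition
#'   /timepoint/replicate annotations), `truth` (tibble `sample_id`,
#'   `origin`, `perturb_target`, `w` plus the seed and noise level), and
#'   `groups` (the sample annotation table used downstream).
#' @export
simulate_bulk <- function(signatures, design, noise_sd = 0.5, seed = 1) {
  design <- as_tibble(design)
  needed <- c("origin", "condition", "timepoint", "n_reps", "perturb_target", "w")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop_stpheno(paste0("`design` lacks columns: ", paste(missing_cols, collapse = ", ")),
                 "stpheno_bad_input")
  }
  known <- colnames(signatures)
  refs <- unique(c(design$origin, design$perturb_target[!is.na(design$perturb_target)]))
  bad <- setdiff(refs, known)
  if (length(bad)) {
    stop_stpheno(paste0("unknown position id(s) in design: ", id_list(bad)),
                 "stpheno_bad_input")
  }
  if (any(design$w < 0 | design$w > 1)) {
    stop_stpheno("mixing weight `w` must lie in [0, 1].", "stpheno_bad_input")
  }
  if (any(design$w > 0 & is.na(design$perturb_target))) {
    stop_stpheno("`w` > 0 requires a `perturb_target`.", "stpheno_bad_input")
  }
  if (any(design$n_reps < 1)) {
    stop_stpheno("`n_reps` must be >= 1.", "stpheno_bad_input")
  }

  withr::with_seed(seed, {
    cols <- list(); truth <- list()
    for (i in seq_len(nrow(design))) {
      d <- design[i, ]
      mean_vec <- (1 - d$w) * signatures[, d$origin]
      if (d$w > 0) mean_vec <- mean_vec + d$w * signatures[, d$perturb_target]
      for (r in seq_len(d$n_reps)) {
        sid <- sprintf("%s_%s_%s_r%d", d$condition, d$timepoint, d$origin, r)
        cols[[sid]] <- pmax(0, mean_vec + rnorm(nrow(signatures), sd = noise_sd))
        truth[[sid]] <- tibble(
          sample_id = sid, origin = d$origin, condition = d$condition,
          timepoint = d$timepoint, replicate = r,
          perturb_target = d$perturb_target, w = d$w)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- rownames(signatures)
    truth <- bind_rows(truth)
    if (anyDuplicated(truth$sample_id)) {
      stop_stpheno("design rows generate duplicate sample ids (same condition/timepoint/origin).",
                   "stpheno_bad_input")
    }
    truth$generator_seed <- seed
    truth$noise_sd <- noise_sd
    groups <- truth[, c("sample_id", "condition", "timepoint", "replicate")]
    bulk <- expression_matrix(vals, scale = "log2TPM1",
                              sample_annotations = groups)
    list(bulk = bulk, truth = truth, groups = groups)
  })
}

#' Simulate a complete knockout fate-shift study
#'
#' The canonical end-to-end synthetic study: an atlas of `n_positions`
#' spatial domains, a control condition (`WT`) whose replicates sit exactly
#' on their origin signatures, and a perturbed condition (`KO`) whose
#' replicates drift with weight `w` toward the next position along the
#' layout — emulating a knockout population gaining spatial preference for
#' an adjacent domain. Each origin is observed at its own timepoint so every
#' position contributes one `KO` vs `WT` comparison.
#'
#' @inheritParams simulate_atlas
#' @param n_positions Positions in the single-stage atlas (default 10).
#' @param noise_sd Replicate noise on the log scale (default 0.5).
#' @param n_reps Replicates per condition and timepoint (default 3).
#' @param w Mixing weight of the perturbed condition (default 0.5).
#' @param seed Integer seed (default 42).
#' @return A list with `atlas`, `features` (marker gene set), `bulk`,
#'   `truth`, `groups`, and `pairs` (`list(c("KO", "WT"))`), ready for
#'   [map_samples()] and [compute_pdi()].
#' @export
simulate_fate_shift_study <- function(n_positions = 10, n_genes = 2000,
                                      markers_per_position = 50,
                                      effect_size = 2, noise_sd = 0.5,
                                      n_reps = 3, w = 0.5, seed = 42) {
  sim <- simulate_atlas(n_stages = 1, positions_per_stage = n_positions,
                        n_genes = n_genes,
                        markers_per_position = markers_per_position,
                        effect_size = effect_size, seed = seed)
  pos <- sim$atlas$positions$position_id
  target <- pos[c(seq_len(n_positions)[-1], 1)]  # shift toward the next domain
  design <- bind_rows(
    tibble(origin = pos, condition = "WT",
           timepoint = sprintf("T%02d", seq_len(n_positions)),
           n_reps = n_reps, perturb_target = NA_character_, w = 0),
    tibble(origin = pos, condition = "KO",
           timepoint = sprintf("T%02d", seq_len(n_positions)),
           n_reps = n_reps, perturb_target = target, w = w)
  )
  sb <- simulate_bulk(sim$signatures, design, noise_sd = noise_sd, seed = seed + 1)
  list(atlas = sim$atlas, features = sim$marker_genes,
       bulk = sb$bulk, truth = sb$truth, groups = sb$groups,
       pairs = list(c("KO", "WT")))
}

#' Score recovery of simulated ground truth
#'
#' Two summary rates: \emph{origin recovery} — the fraction of unperturbed
#' samples (`w = 0`) whose top-ranked atlas position is their true origin
#' (a sample whose top rank is tied counts as recovered when the origin is
#' among the tied leaders; perturbed samples are excluded because a mixture
#' has no single true origin) — and, when a `pdi_map` is supplied,
#' \emph{PDI sign agreement} — the fraction of perturbed comparisons whose
#' PDI at the perturbation target is positive, i.e. where the index points
#' toward the domain the perturbation actually drifted to.
#'
#' @param pcc A `pcc_map` over the simulated bulk samples.
#' @param truth Truth table from [simulate_bulk()].
#' @param pdi Optional `pdi_map` over the same positions.
#' @return One-row tibble: `origin_recovery`, `n_samples_scored`, and (with
#'   `pdi`) `sign_agreement`, `n_comparisons_scored`.
#' @export
recovery_report <- function(pcc, truth, pdi = NULL) {
  stopifnot(inherits(pcc, "pcc_map"))
  truth <- as_tibble(truth)
  samples <- rownames(pcc$pcc)
  if (!setequal(samples, truth$sample_id)) {
    stop_stpheno(paste0(
      "sample ids of the correlation map and the truth table disagree; ",
      "only in map: [", id_list(setdiff(samples, truth$sample_id)), "]; ",
      "only in truth: [", id_list(setdiff(truth$sample_id, samples)), "]"),
      "stpheno_bad_input")
  }
  unknown <- setdiff(truth$origin, colnames(pcc$pcc))
  if (length(unknown)) {
    stop_stpheno(paste0("truth origins absent from the map: ", id_list(unknown)),
                 "stpheno_bad_input")
  }

  top <- rank_positions(pcc, k = 1)
  unperturbed <- truth$sample_id[truth$w == 0]
  hit <- vapply(unperturbed, function(s) {
    truth$origin[truth$sample_id == s] %in% top$position_id[top$sample_id == s]
  }, logical(1))
  out <- tibble(origin_recovery = mean(hit), n_samples_scored = length(hit))

  if (!is.null(pdi)) {
    stopifnot(inherits(pdi, "pdi_map"))
    perturbed <- truth[truth$w > 0, , drop = FALSE]
    agree <- logical(0)
    for (j in seq_len(nrow(pdi$comparisons))) {
      cmp <- pdi$comparisons[j, ]
      tgt <- unique(perturbed$perturb_target[
        perturbed$condition == cmp$case & perturbed$timepoint == cmp$timepoint])
      for (t in tgt) {
        agree <- c(agree, pdi$pdi[t, cmp$label] > 0)
      }
    }
    out$sign_agreement <- if (length(agree)) mean(agree) else NA_real_
    out$n_comparisons_scored <- length(agree)
  }
  out
}
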