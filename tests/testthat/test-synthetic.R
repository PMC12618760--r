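test_that("simulated atlases have disjoint elevated marker blocks and deterministic layout", {
  sim <- simulate_atlas(n_stages = 1, positions_per_stage = 2, n_genes = 100,
                        markers_per_position = 10, effect_size = 2, seed = 3)
  sig <- sim$signatures
  expect_equal(dim(sig), c(100, 2))
  delta <- sig[, 1] - sig[, 2]
  # exactly 10 genes up by effect in each position, disjoint blocks
  expect_equal(sum(abs(delta - 2) < 1e-9), 10)
  expect_equal(sum(abs(delta + 2) < 1e-9), 10)
  expect_equal(sum(delta == 0), 80)
  expect_true(all(sig >= 0))
  expect_length(sim$marker_genes, 20)

  sim2 <- simulate_atlas(n_stages = 1, positions_per_stage = 2, n_genes = 100,
                         markers_per_position = 10, effect_size = 2, seed = 3)
  expect_identical(sim2$signatures, sim$signatures)
  expect_equal(as.data.frame(sim2$atlas$positions), as.data.frame(sim$atlas$positions))

  expect_error(simulate_atlas(positions_per_stage = 3, n_genes = 20,
                              markers_per_position = 10),
               class = "stpheno_bad_input")
})

test_that("multi-stage atlases keep one layout cell per position within a stage", {
  sim <- simulate_atlas(n_stages = 2, positions_per_stage = 6, n_genes = 800,
                        markers_per_position = 20, seed = 9)
  pos <- sim$atlas$positions
  expect_equal(nrow(pos), 12)
  expect_equal(anyDuplicated(paste(pos$stage, pos$layout_row, pos$layout_col)), 0)
  expect_equal(unique(pos$stage), c("S1", "S2"))
})

test_that("noise-free unperturbed replicates reproduce their origin signature exactly", {
  sim <- simulate_atlas(positions_per_stage = 4, n_genes = 400,
                        markers_per_position = 25, seed = 5)
  pos <- sim$atlas$positions$position_id
  design <- tibble::tibble(origin = pos[2], condition = "WT", timepoint = "T1",
                           n_reps = 2, perturb_target = NA_character_, w = 0)
  sb <- simulate_bulk(sim$signatures, design, noise_sd = 0, seed = 8)
  expect_equal(unname(sb$bulk$values[, 1]), unname(sim$signatures[, pos[2]]))

  pcc <- map_samples(sb$bulk, sim$atlas, sim$marker_genes)
  expect_equal(unname(pcc$pcc[, pos[2]]), c(1, 1))
  top <- rank_positions(pcc, k = 1)
  expect_true(all(top$position_id == pos[2]))
})

test_that("w = 1 relabels the sample to the perturbation target; w = 0.5 ties symmetric signatures", {
  sim <- simulate_atlas(positions_per_stage = 4, n_genes = 400,
                        markers_per_position = 25, seed = 5)
  pos <- sim$atlas$positions$position_id
  design <- tibble::tibble(origin = pos[1], condition = "KO", timepoint = "T1",
                           n_reps = 1, perturb_target = pos[3],
                           w = c(1))
  sb <- simulate_bulk(sim$signatures, design, noise_sd = 0, seed = 8)
  pcc <- map_samples(sb$bulk, sim$atlas, sim$marker_genes)
  expect_equal(rank_positions(pcc, k = 1)$position_id, pos[3])

  # symmetric signatures (flat baseline): the half mixture ties exactly
  sym <- simulate_atlas(positions_per_stage = 4, n_genes = 400,
                        markers_per_position = 25, baseline_sd = 0, seed = 5)
  half <- simulate_bulk(sym$signatures,
                        dplyr::mutate(design, w = 0.5),
                        noise_sd = 0, seed = 8)
  ph <- map_samples(half$bulk, sym$atlas, sym$marker_genes)
  # equidistant mixture of two equal-sized marker blocks: exact tie
  expect_equal(unname(ph$pcc[1, pos[1]]), unname(ph$pcc[1, pos[3]]), tolerance = 1e-12)
  top <- rank_positions(ph, k = 1)
  expect_setequal(top$position_id, c(pos[1], pos[3]))

  expect_error(simulate_bulk(sim$signatures,
                             dplyr::mutate(design, origin = "nope"),
                             seed = 1),
               class = "stpheno_bad_input")
})

test_that("recovery_report counts top-1 hits and PDI sign agreement", {
  # hand-built map: 3 of 4 unperturbed samples rank their origin first
  m <- matrix(c(0.9, 0.1, 0.1, 0.9,
                0.8, 0.2, 0.3, 0.7), nrow = 4,
              dimnames = list(c("s1", "s2", "s3", "s4"), c("P1", "P2")))
  pcc <- structure(list(pcc = m, n_genes_used = 10L,
                        features_provenance = "test", min_overlap = 3L),
                   class = "pcc_map")
  truth <- tibble::tibble(sample_id = paste0("s", 1:4),
                          origin = c("P1", "P2", "P1", "P1"),
                          condition = "WT", timepoint = "T1",
                          perturb_target = NA_character_, w = 0)
  rep <- recovery_report(pcc, truth)
  expect_equal(rep$origin_recovery, 0.75)
  expect_equal(rep$n_samples_scored, 4)

  truth_bad <- dplyr::mutate(truth, sample_id = paste0("x", 1:4))
  expect_error(recovery_report(pcc, truth_bad), class = "stpheno_bad_input")
})

test_that("the default fate-shift study is recovered: origins found, PDI points at the target", {
  # study conditions: 10 positions, 2000 genes, 50 markers each, effect 2,
  # noise 0.5, 3 replicates, w = 0.5; majority of seeds must pass
  passes <- vapply(42:46, function(s) {
    study <- simulate_fate_shift_study(seed = s)
    pcc <- map_samples(study$bulk, study$atlas, study$features)
    pdi <- compute_pdi(pcc, study$groups, study$pairs)
    rep <- recovery_report(pcc, study$truth, pdi)
    rep$origin_recovery >= 0.95 && rep$sign_agreement >= 0.9
  }, logical(1))
  expect_gte(sum(passes), 3)
})

test_that("origin recovery degrades monotonically with replicate noise", {
  mean_recovery <- vapply(c(0, 0.5, 2, 8), function(ns) {
    mean(vapply(42:44, function(s) {
      study <- simulate_fate_shift_study(noise_sd = ns, seed = s)
      pcc <- map_samples(study$bulk, study$atlas, study$features)
      recovery_report(pcc, study$truth)$origin_recovery
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_recovery) <= 0))
  expect_equal(mean_recovery[1], 1)
})

test_that("truth tables record the generator's seed, noise and mixing weights", {
  study <- simulate_fate_shift_study(n_positions = 4, n_genes = 400,
                                     markers_per_position = 20, seed = 12)
  expect_setequal(unique(study$truth$w), c(0, 0.5))
  expect_true(all(study$truth$generator_seed == 13))
  expect_equal(anyDuplicated(study$truth$sample_id), 0)
  # w = 0 rows carry no perturbation target
  expect_true(all(is.na(study$truth$perturb_target[study$truth$w == 0])))
})
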