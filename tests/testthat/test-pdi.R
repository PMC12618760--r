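# build a pcc_map directly from a matrix, bypassing map_samples
fake_pcc <- function(m) {
  structure(list(pcc = m, n_genes_used = 50L,
                 features_provenance = "test", min_overlap = 3L),
            class = "pcc_map")
}

two_group_table <- function(case_ids, ctrl_ids, tp = "D3") {
  tibble::tibble(
    sample_id = c(case_ids, ctrl_ids),
    condition = rep(c("KO", "WT"), c(length(case_ids), length(ctrl_ids))),
    timepoint = tp)
}

test_that("PDI reaches its analytic extremes at perfectly concordant/anticorrelated groups", {
  # case replicates identical to a >=3-gene domain profile, controls its
  # reflection about the gene-wise mean: PCC +1 vs -1, so PDI = 2 exactly
  atlas <- tiny_atlas(n_genes = 8)
  profile <- atlas$expression$values[, "P3"]
  vals <- cbind(ko1 = profile, ko2 = profile,
                wt1 = reflect_about_mean(profile), wt2 = reflect_about_mean(profile))
  bulk <- expression_matrix(vals, scale = "log2TPM1")
  pcc <- map_samples(bulk, atlas, gene_ids(atlas$expression), min_overlap = 3)
  groups <- two_group_table(c("ko1", "ko2"), c("wt1", "wt2"))

  pdi <- compute_pdi(pcc, groups, list(c("KO", "WT")))
  expect_equal(unname(pdi$pdi["P3", "KO_D3_vs_WT_D3"]), 2)

  # swapping the group roles negates every value, giving -2 at the domain
  swapped <- compute_pdi(pcc, groups, list(c("WT", "KO")))
  expect_equal(unname(swapped$pdi["P3", "WT_D3_vs_KO_D3"]), -2)
  expect_equal(unname(swapped$pdi), -unname(pdi$pdi), tolerance = 1e-15)
})

test_that("identical case and control groups give PDI exactly 0 everywhere", {
  atlas <- tiny_atlas()
  bulk <- bulk_from_atlas(atlas, c(a1 = "P1", a2 = "P2", b1 = "P1", b2 = "P2"))
  pcc <- map_samples(bulk, atlas, gene_ids(atlas$expression), min_overlap = 3)
  # both conditions draw the same profiles
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                           condition = c("KO", "KO", "WT", "WT"),
                           timepoint = "D3")
  pdi <- compute_pdi(pcc, groups, list(c("KO", "WT")))
  expect_equal(unname(pdi$pdi[, 1]), rep(0, 4), tolerance = 1e-15)
})

test_that("mean_pcc aggregation equals a brute-force loop over replicates", {
  set.seed(23)
  m <- matrix(runif(10 * 6, -1, 1), nrow = 10,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("P%d", 1:6)))
  groups <- tibble::tibble(
    sample_id = rownames(m),
    condition = rep(c("KO", "WT"), each = 5),
    timepoint = rep(c("D3", "D5"), times = 5))
  pdi <- compute_pdi(fake_pcc(m), groups, list(c("KO", "WT")))

  for (tp in c("D3", "D5")) {
    ko <- groups$sample_id[groups$condition == "KO" & groups$timepoint == tp]
    wt <- groups$sample_id[groups$condition == "WT" & groups$timepoint == tp]
    for (p in colnames(m)) {
      manual <- mean(vapply(ko, function(s) m[s, p], 0)) -
        mean(vapply(wt, function(s) m[s, p], 0))
      expect_equal(unname(pdi$pdi[p, paste0("KO_", tp, "_vs_WT_", tp)]), manual,
                   tolerance = 1e-12)
    }
  }
  expect_equal(sort(pdi$comparisons$timepoint), c("D3", "D5"))
  expect_equal(pdi$comparisons$n_case, c(3, 2))
})

test_that("PDI stays within [-2, 2] on random correlation maps and reversal negates it", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(8 * 5, -1, 1), nrow = 8,
                dimnames = list(sprintf("s%d", 1:8), sprintf("P%d", 1:5)))
    groups <- tibble::tibble(sample_id = rownames(m),
                             condition = rep(c("KO", "WT"), each = 4),
                             timepoint = "T1")
    fwd <- compute_pdi(fake_pcc(m), groups, list(c("KO", "WT")))
    rev <- compute_pdi(fake_pcc(m), groups, list(c("WT", "KO")))
    expect_true(all(fwd$pdi >= -2 & fwd$pdi <= 2))
    expect_equal(unname(rev$pdi), -unname(fwd$pdi), tolerance = 1e-15)
  }
})

test_that("timepoints present in only one condition are skipped with a warning; empty condition errors", {
  m <- matrix(runif(4 * 3, -1, 1), nrow = 4,
              dimnames = list(c("k1", "k2", "w1", "w2"), c("P1", "P2", "P3")))
  groups <- tibble::tibble(sample_id = rownames(m),
                           condition = c("KO", "KO", "WT", "WT"),
                           timepoint = c("D3", "D4", "D3", "D5"))
  expect_warning(pdi <- compute_pdi(fake_pcc(m), groups, list(c("KO", "WT"))),
                 class = "stpheno_skipped_timepoint")
  expect_equal(colnames(pdi$pdi), "KO_D3_vs_WT_D3")

  expect_error(compute_pdi(fake_pcc(m), groups, list(c("KO", "MUT"))),
               class = "stpheno_empty_group")
})

test_that("undefined correlation cells are excluded from group means and counted", {
  m <- matrix(c(0.8, NA, 0.2, 0.4), nrow = 4,
              dimnames = list(c("k1", "k2", "w1", "w2"), "P1"))
  groups <- two_group_table(c("k1", "k2"), c("w1", "w2"))
  pdi <- suppressMessages(compute_pdi(fake_pcc(m), groups, list(c("KO", "WT"))))
  expect_equal(unname(pdi$pdi["P1", 1]), 0.8 - 0.3, tolerance = 1e-12)
  expect_equal(pdi$comparisons$n_excluded, 1L)
})

test_that("pooled_profile aggregation averages group profiles before one correlation each", {
  atlas <- tiny_atlas(n_genes = 10)
  profile <- atlas$expression$values[, "P2"]
  vals <- cbind(k1 = profile, k2 = profile,
                w1 = reflect_about_mean(profile), w2 = reflect_about_mean(profile))
  bulk <- expression_matrix(vals, scale = "log2TPM1")
  features <- feature_gene_set(gene_ids(atlas$expression))
  pcc <- map_samples(bulk, atlas, features, min_overlap = 3)
  groups <- two_group_table(c("k1", "k2"), c("w1", "w2"))

  pooled <- compute_pdi(pcc, groups, list(c("KO", "WT")),
                        aggregation = "pooled_profile",
                        bulk = bulk, atlas = atlas, features = features)
  # pooled case profile is the domain profile itself; control its reflection
  expect_equal(unname(pooled$pdi["P2", 1]), 2)
  expect_error(compute_pdi(pcc, groups, list(c("KO", "WT")),
                           aggregation = "pooled_profile"),
               class = "stpheno_bad_input")
})

test_that("classification splits at the sign with an optional dead-band", {
  m <- matrix(c(0.4, -0.4, 0), nrow = 1,
              dimnames = list("s1", c("P1", "P2", "P3")))
  # one comparison where KO row is m and WT row is zero everywhere
  mm <- rbind(s1 = m[1, ], s2 = rep(0, 3))
  groups <- tibble::tibble(sample_id = c("s1", "s2"),
                           condition = c("KO", "WT"), timepoint = "D3")
  pdi <- compute_pdi(fake_pcc(mm), groups, list(c("KO", "WT")))
  cls <- classify_pdi(pdi)
  expect_equal(as.character(cls$change[match(c("P1", "P2", "P3"), cls$position_id)]),
               c("enhanced", "attenuated", "unchanged"))
  wide <- classify_pdi(pdi, epsilon = 0.5)
  expect_true(all(wide$change == "unchanged"))
  expect_error(classify_pdi(pdi, epsilon = -1), class = "stpheno_bad_input")
})

test_that("PDI maps tidy to long format and serialize to TSV", {
  m <- matrix(c(0.5, -0.5, 0.1, 0.2), nrow = 4,
              dimnames = list(c("k1", "k2", "w1", "w2"), "P1"))
  groups <- two_group_table(c("k1", "k2"), c("w1", "w2"))
  pdi <- compute_pdi(fake_pcc(m), groups, list(c("KO", "WT")))
  td <- tidy(pdi)
  expect_named(td, c("position_id", "comparison", "pdi", "case", "control",
                     "timepoint", "n_case", "n_control", "n_excluded"))
  path <- tempfile(fileext = ".tsv")
  write_pdi_map(pdi, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back[[2]], unname(pdi$pdi[, 1]))
})
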