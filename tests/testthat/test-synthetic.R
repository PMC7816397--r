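# synthetic multi-donor PBMC generator

test_that("generation is deterministic and respects the lane/mixing design", {
  sim <- small_sim(seed = 7, cells = 100)
  sim2 <- generate_counts(generator_config(cells_per_donor_per_lane = 100,
                                           seed = 7))
  expect_identical(as.matrix(sim$counts), as.matrix(sim2$counts))
  expect_identical(sim$tags, sim2$tags)
  expect_identical(sim$truth$cells, sim2$truth$cells)

  cells <- sim$truth$cells
  # donor A is unmixed in lanes 1 and 4, mixed in lanes 2 and 3
  a <- cells[cells$donor == "A", ]
  expect_true(all(!a$mixed[a$lane %in% c("1", "4")]))
  expect_true(all(a$mixed[a$lane %in% c("2", "3")]))
  # lane membership matches the design
  expect_setequal(unique(cells$donor[cells$lane == "2"]), c("A", "B", "C", "D"))
  expect_setequal(unique(cells$donor[cells$lane == "3"]), LETTERS[1:8])
  expect_setequal(unique(cells$donor[cells$lane %in% c("1", "4")]), "A")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(celltype_proportions = c("CD4 T" = 0.7)),
               "sum to 1")
  expect_error(generator_config(lane_design = list("1" = "Z")), "donors")
  expect_error(generator_config(n_genes = 10), "too small")
})

test_that("noiseless tags put every cell's modal tag on its donor", {
  cfg <- generator_config(
    cells_per_donor_per_lane = 50, n_genes = 40,
    tag_params = tag_params(background_fraction = 0, sequencing_error_rate = 0),
    seed = 3)
  sim <- generate_counts(cfg)
  modal <- rownames(sim$tags)[apply(sim$tags, 2, which.max)]
  expect_identical(modal, sim$truth$cells$donor)
  # off-donor tags are exactly zero without background or errors
  own <- sim$tags[cbind(match(sim$truth$cells$donor, rownames(sim$tags)),
                        seq_len(ncol(sim$tags)))]
  expect_identical(sum(sim$tags) - sum(own), 0L)
})

test_that("counts approach Poisson-limit moments as dispersion grows", {
  # flat single-population configuration with fixed library size; expected
  # gene means are computed analytically from the generative weights and
  # compared against the Poisson-limit tolerance mu +/- 4*sqrt(mu/n)*1.2
  n_cells <- 5000
  cfg <- generator_config(
    n_genes = 30, donors = "A", lane_design = list("1" = "A"),
    cells_per_donor_per_lane = n_cells,
    celltype_proportions = c("CD14 Mono" = 1),
    n_marker_genes_per_type = 1, marker_fold_change = 1,
    donor_effect_sd = 0, dispersion = 1e9,
    library_size_log_mean = log(600), library_size_log_sd = 0, seed = 5)
  sim <- generate_counts(cfg)
  w <- sim$truth$model$base_w
  mu <- 600 * w / sum(w)
  obs <- Matrix::rowMeans(sim$counts)
  tol <- 4 * sqrt(mu / n_cells) * 1.2
  expect_true(all(abs(obs - mu) <= tol))
})

test_that("realized cell-type frequencies match the configured proportions", {
  cfg <- generator_config(cells_per_donor_per_lane = 1430, n_genes = 40,
                          seed = 42)  # 14 donor/lane blocks -> 20,020 cells
  sim <- generate_counts(cfg)
  tab <- table(factor(sim$truth$cells$celltype,
                      levels = names(cfg$celltype_proportions)))
  gof <- stats::chisq.test(tab, p = cfg$celltype_proportions)
  expect_gt(gof$p.value, 0.01)
})

test_that("marker genes separate their own cell type by at least half the fold", {
  sim <- small_sim(seed = 7, cells = 200)
  cells <- sim$truth$cells
  genes <- sim$truth$genes
  fold <- sim$truth$config$marker_fold_change
  markers <- genes[!is.na(genes$marker_of), ]
  for (ty in unique(markers$marker_of)) {
    own <- cells$celltype == ty
    expect_gte(sum(own), 200)
    for (g in markers$gene[markers$marker_of == ty]) {
      m_own <- mean(sim$counts[g, own])
      m_other <- mean(sim$counts[g, !own])
      expect_gte(m_own, m_other * fold / 2)
    }
  }
})

test_that("default-noise tags identify the donor for at least 99% of cells", {
  sim <- small_sim(seed = 7, cells = 200)
  argmax <- rownames(sim$tags)[apply(sim$tags, 2, which.max)]
  expect_gte(mean(argmax == sim$truth$cells$donor), 0.99)
})

test_that("inject_allo_effect with zero affected fraction is the identity", {
  sim <- small_sim(seed = 7, cells = 100)
  sp <- allo_effect_spec(affected_fraction = 0)
  out <- inject_allo_effect(sim$counts, sim$truth, sp, seed = 1)
  expect_identical(as.matrix(out$counts), as.matrix(sim$counts))
  expect_false(any(out$truth$cells$allo_affected))
})

test_that("injected fold change shifts affected-cell means by the stated factor", {
  # one fully-mixed lane of CD4 T cells, fixed library size; every cell is
  # affected, so the sample mean must land within 5% of fold x analytic mean
  cfg <- generator_config(
    n_genes = 60, donors = c("A", "B"), lane_design = list("1" = c("A", "B")),
    cells_per_donor_per_lane = 5000, celltype_proportions = c("CD4 T" = 1),
    donor_effect_sd = 0, library_size_log_mean = log(100),
    library_size_log_sd = 0, seed = 11)
  sim <- generate_counts(cfg)
  sp <- allo_effect_spec(up_genes = "IFNG", down_genes = "DUSP1",
                         fold_change_up = 2, fold_change_down = 2,
                         affected_fraction = 1)
  out <- inject_allo_effect(sim$counts, sim$truth, sp, seed = 2)
  expect_true(all(out$truth$cells$allo_affected))
  mu <- allomix:::cell_gene_means(sim$truth$model, sim$truth$cells[1, ],
                                  c("IFNG", "DUSP1"))
  m_up <- mean(out$counts["IFNG", ])
  m_dn <- mean(out$counts["DUSP1", ])
  expect_gte(m_up, 1.9 * mu["IFNG", 1])
  expect_lte(m_up, 2.1 * mu["IFNG", 1])
  expect_gte(m_dn, (1 / 2.1) * mu["DUSP1", 1])
  expect_lte(m_dn, (1 / 1.9) * mu["DUSP1", 1])
  # untouched genes and unaffected flags unchanged
  other <- setdiff(rownames(sim$counts), c("IFNG", "DUSP1"))
  expect_identical(as.matrix(out$counts[other, ]), as.matrix(sim$counts[other, ]))
})

test_that("the allo effect never touches unmixed lanes and errors on unknown genes", {
  sim <- small_sim(seed = 7, cells = 100)
  sp <- allo_effect_spec(affected_fraction = 1)
  out <- inject_allo_effect(sim$counts, sim$truth, sp, seed = 1)
  cells <- out$truth$cells
  expect_false(any(cells$allo_affected & !cells$mixed))
  expect_true(all(cells$allo_affected[cells$celltype == "CD4 T" & cells$mixed]))
  expect_error(
    inject_allo_effect(sim$counts, sim$truth,
                       allo_effect_spec(up_genes = "NOT_A_GENE"), seed = 1),
    "NOT_A_GENE")
})

test_that("generation with an allo config flags only mixed-lane target cells", {
  cfg <- generator_config(cells_per_donor_per_lane = 100, seed = 9,
                          allo_effect = allo_effect_spec(affected_fraction = 0.5))
  sim <- generate_counts(cfg)
  cells <- sim$truth$cells
  expect_false(any(cells$allo_affected & !cells$mixed))
  expect_false(any(cells$allo_affected & cells$celltype != "CD4 T"))
  frac <- mean(cells$allo_affected[cells$celltype == "CD4 T" & cells$mixed])
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
})
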